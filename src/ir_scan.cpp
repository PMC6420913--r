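#include <Rcpp.h>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, T=3, anything else (incl. N) = -1.
// Watson-Crick pair <=> both codes >= 0 and codes sum to 3.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

//' @noRd
// [[Rcpp::export(name = ".scan_ir_candidates")]]
DataFrame scan_ir_candidates(const std::string& seq, int min_arm, int max_spacer,
                             int min_total) {
  const int L = (int) seq.size();
  std::vector<int> enc(L);
  for (int i = 0; i < L; ++i) enc[i] = base_code(seq[i]);

  std::vector<int> out_start, out_arm, out_sp;
  // For every spacer size S and every spacer placement [i, i+S), extend the
  // two arms outward while the flanking bases are complementary. Extension is
  // maximal by construction; thresholds are applied afterwards.
  for (int S = 0; S <= max_spacer; ++S) {
    for (int i = 0; i + S <= L; ++i) {
      int l = i - 1, r = i + S;
      while (l >= 0 && r < L && enc[l] >= 0 && enc[r] >= 0 && enc[l] + enc[r] == 3) {
        --l; ++r;
      }
      int arm = i - 1 - l;
      if (arm >= min_arm && 2 * arm + S >= min_total) {
        out_start.push_back(l + 2);   // 1-based start of the left arm
        out_arm.push_back(arm);
        out_sp.push_back(S);
      }
    }
  }
  return DataFrame::create(_["start"] = out_start,
                           _["arm_len"] = out_arm,
                           _["spacer_len"] = out_sp);
}
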