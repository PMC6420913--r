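# small gene-model tables and genomes used across test files

toyGene <- function(id = "g1", chrom = "chrI", strand = "+", tss = 101,
                    sc = 121, stc = 400, pa = 470) {
  data.frame(gene_id = id, chrom = chrom, strand = strand, tss = tss,
             start_codon = sc, stop_codon = stc, polya_site = pa,
             stringsAsFactors = FALSE)
}

# a fast small synthetic config for unit tests (full default stays for the
# acceptance suite)
smallSynthConfig <- function(seed = 42L, ...) {
  synthConfig(nChromosomes = 1L, nGenes = 30L, orfMean = 900, orfSd = 150,
              seed = seed, ...)
}

revcompStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
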