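#' Sequence features of IR repeat units (arms)
#'
#' Computes, for each 5' arm sequence, the three quantities that drive the
#' seven-type classification:
#'
#' * `atContent` — fraction of A+T bases,
#' * `tractOcc` — length of the longest run of A's or of T's with run length
#'   >= `minTract` (default 3), divided by the arm length; 0 when no such run
#'   exists,
#' * `altOcc` — length of the longest substring of the exact form `(AT)n` or
#'   `(TA)n` with n >= 1, divided by the arm length; 0 when none exists.
#'   Alternating stretches are counted in complete dinucleotide units only,
#'   so `"ATA"` scores 2, not 3.
#'
#' @param arms character vector of arm sequences over `A,C,G,T` (an arm can
#'   never contain `N`, since `N` pairs with nothing; such input is an error).
#' @param minTract minimum run length for an A/T-tract.
#' @return `data.frame` with columns `atContent`, `tractOcc`, `altOcc`.
#' @examples
#' armFeatures(c("AAAAATT", "GCGCG", "AAAATATA"))
#' @export
armFeatures <- function(arms, minTract = 3L) {
  if (!length(arms)) {
    return(data.frame(atContent = numeric(), tractOcc = numeric(),
                      altOcc = numeric()))
  }
  arms <- toupper(arms)
  if (any(!nzchar(arms))) stop("empty arm sequence")
  if (any(grepl("[^ACGT]", arms)))
    stop("arm sequences must be over {A,C,G,T}; an arm containing 'N' ",
         "cannot come from a perfect inverted repeat")
  len <- nchar(arms)
  at <- nchar(gsub("[^AT]", "", arms)) / len

  longest_match <- function(pattern) {
    vapply(gregexpr(pattern, arms), function(m) {
      ml <- attr(m, "match.length")
      if (m[1] == -1L) 0L else max(ml)
    }, integer(1))
  }
  tract_re <- sprintf("A{%d,}|T{%d,}", minTract, minTract)
  tract <- longest_match(tract_re)
  # maximal alternating A/T stretches; regex matching is anchored at the
  # start of each alternating run, so the greedy match has the full even
  # length 2*floor(run/2)
  alt <- longest_match("(AT)+|(TA)+")
  data.frame(atContent = at, tractOcc = tract / len, altOcc = alt / len)
}

.IR_TYPES <- c("I", "II", "III", "IV", "V", "VI", "VII")

#' Map arm features to the seven IR sequence types
#'
#' The three binary predicates — AT-rich (`atContent >= atRich`), tract-rich
#' (`tractOcc >= tractRich`) and alternating-rich (`altOcc >= altRich`) — map
#' deterministically onto seven types:
#'
#' | AT-rich | tract-rich | alt-rich | type |
#' |---------|------------|----------|------|
#' | yes | yes | yes | I   |
#' | yes | yes | no  | II  |
#' | yes | no  | yes | III |
#' | yes | no  | no  | IV  |
#' | no  | yes | no  | V   |
#' | no  | any | yes | VI  |
#' | no  | no  | no  | VII |
#'
#' Types II (A/T-tract-rich), III (alternating-AT-rich), I (both), V and VII
#' (the "neither ... nor" types) follow their published verbal definitions;
#' the assignments for IV and VI complete the eight boolean combinations into
#' exactly seven exclusive types (VI absorbs the two non-AT-rich,
#' alternating-rich combinations). The AT threshold default 0.6 reflects the
#' genome-wide AT content of *S. cerevisiae* (0.62).
#'
#' @param features `data.frame` from [armFeatures()] (columns `atContent`,
#'   `tractOcc`, `altOcc`).
#' @param atRich,tractRich,altRich predicate thresholds.
#' @return factor of type labels with levels `I`..`VII`.
#' @export
classifyArmFeatures <- function(features, atRich = 0.6, tractRich = 0.5,
                                altRich = 0.5) {
  a <- features$atContent >= atRich
  t <- features$tractOcc >= tractRich
  p <- features$altOcc >= altRich
  type <- ifelse(a,
                 ifelse(t, ifelse(p, "I", "II"), ifelse(p, "III", "IV")),
                 ifelse(p, "VI", ifelse(t, "V", "VII")))
  factor(type, levels = .IR_TYPES)
}

#' Classify every IR in an IRSet into the seven sequence types
#'
#' Computes [armFeatures()] on each 5' arm (spacer bases are ignored) and
#' appends `atContent`, `tractOcc`, `altOcc` and `typeId` metadata columns.
#' Classification is symmetric in the two arms: the right arm is the reverse
#' complement of the left, which swaps A-tracts with T-tracts and `(AT)n`
#' with `(TA)n` but never changes the label.
#'
#' @param x an [IRSet].
#' @param atRich,tractRich,altRich predicate thresholds (see
#'   [classifyArmFeatures()]).
#' @param minTract minimum A/T-tract run length.
#' @return `x` with classification columns added.
#' @export
classifyIRs <- function(x, atRich = 0.6, tractRich = 0.5, altRich = 0.5,
                        minTract = 3L) {
  stopifnot(is(x, "IRSet"))
  if (length(x) == 0L) {
    mcols(x)$atContent <- numeric()
    mcols(x)$tractOcc <- numeric()
    mcols(x)$altOcc <- numeric()
    mcols(x)$typeId <- factor(character(), levels = .IR_TYPES)
    return(x)
  }
  f <- armFeatures(leftArm(x), minTract = minTract)
  mcols(x)$atContent <- f$atContent
  mcols(x)$tractOcc <- f$tractOcc
  mcols(x)$altOcc <- f$altOcc
  mcols(x)$typeId <- classifyArmFeatures(f, atRich = atRich,
                                         tractRich = tractRich,
                                         altRich = altRich)
  x
}
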