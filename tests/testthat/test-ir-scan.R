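test_that("textbook inverted repeats are found with maximal arms", {
  x <- findMaximalIRs("AAAAAAATTTTTTT")
  expect_s4_class(x, "IRSet")
  expect_equal(length(x), 1L)
  expect_equal(start(x), 1L)
  expect_equal(end(x), 14L)
  expect_equal(armLength(x), 7L)
  expect_equal(spacerLength(x), 0L)
  expect_equal(irCenter(x), 7L)   # left-of-middle base of the 14-mer
  expect_equal(leftArm(x), "AAAAAAA")
  expect_equal(irName(x), "R7S0")

  # A pairs only with T: a homopolymer has no inverted repeat
  expect_equal(length(findMaximalIRs("AAAAAAAAAAAAAAA")), 0L)

  # arms extend through a self-complementary core; the R6S6 reading of the
  # same interval is pruned in favor of the longer arm
  y <- findMaximalIRs("TTTTTTGCATGCAAAAAA")
  expect_equal(length(y), 1L)
  expect_equal(c(start(y), end(y)), c(1L, 18L))
  expect_equal(armLength(y), 9L)
  expect_equal(spacerLength(y), 0L)
  expect_equal(irCenter(y), 9L)
})

test_that("containment pruning keeps outer IRs and resolves equal intervals", {
  # strict containment
  d <- data.frame(start = c(1L, 2L), end = c(14L, 13L),
                  arm_len = c(7L, 5L), spacer_len = c(0L, 2L))
  expect_equal(pruneContained(d)$start, 1L)

  # equal interval: max arm wins, then min spacer
  d2 <- data.frame(start = c(1L, 1L), end = c(18L, 18L),
                   arm_len = c(9L, 6L), spacer_len = c(0L, 6L))
  expect_equal(pruneContained(d2)$arm_len, 9L)
  d3 <- data.frame(start = c(1L, 1L), end = c(15L, 15L),
                   arm_len = c(6L, 6L), spacer_len = c(5L, 3L))
  expect_equal(pruneContained(d3)$spacer_len, 3L)

  # disjoint intervals both kept
  d4 <- data.frame(start = c(1L, 21L), end = c(14L, 35L),
                   arm_len = c(7L, 6L), spacer_len = c(0L, 3L))
  expect_equal(nrow(pruneContained(d4)), 2L)
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(7)
  for (i in 1:60) {
    at <- sample(c(0.3, 0.5, 0.62, 0.8), 1)
    len <- sample(13:150, 1)
    expect_matches_oracle(randomSeq(len, at))
  }
  # with N bases sprinkled in
  for (i in 1:15)
    expect_matches_oracle(randomSeq(100, 0.62, nProb = 0.05))
  # non-default thresholds
  for (i in 1:10)
    expect_matches_oracle(randomSeq(80, 0.7), minArm = 4L, maxSpacer = 4L,
                          minTotal = 10L)
})

test_that("every reported IR is maximal and satisfies the thresholds", {
  set.seed(11)
  s <- randomSeq(4000, 0.62)
  x <- findMaximalIRs(s)
  expect_gt(length(x), 0L)
  expect_true(all(armLength(x) >= 5L))
  expect_true(all(spacerLength(x) <= 8L & spacerLength(x) >= 0L))
  expect_true(all(width(x) >= 13L))
  expect_true(all(width(x) == 2L * armLength(x) + spacerLength(x)))
  ch <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_along(x)) {
    st <- start(x)[i]; en <- end(x)[i]; R <- armLength(x)[i]
    # left arm pairs the right arm base for base
    expect_true(all(comp[ch[st:(st + R - 1L)]] == ch[en:(en - R + 1L)]))
    # one-base outward extension impossible
    if (st > 1L && en < length(ch))
      expect_false(isTRUE(comp[ch[st - 1L]] == ch[en + 1L]))
  }
})

test_that("scanning the reverse complement mirrors the intervals", {
  set.seed(3)
  for (i in 1:10) {
    s <- randomSeq(200, 0.6)
    fwd <- findMaximalIRs(s)
    rev <- findMaximalIRs(revcompStr(s))
    L <- nchar(s)
    mirrored <- sort(IRanges(L - end(rev) + 1L, L - start(rev) + 1L))
    expect_equal(as.data.frame(sort(ranges(fwd))), as.data.frame(mirrored))
    expect_equal(sort(armLength(fwd)), sort(armLength(rev)))
  }
})

test_that("input handling: case folding, multi-record input, bad characters", {
  expect_equal(length(findMaximalIRs("aaaaaaattttttt")), 1L)
  g <- Biostrings::DNAStringSet(c(c1 = "AAAAAAATTTTTTT",
                                  c2 = "TTTTTTGCATGCAAAAAA"))
  x <- findMaximalIRs(g)
  expect_equal(as.character(seqnames(x)), c("c1", "c2"))
  expect_equal(unname(seqlengths(x)), c(14L, 18L))
  expect_error(findMaximalIRs("AAAAXAAATTTTTTT"), "outside")
  # N never pairs: an N in one arm truncates it below threshold
  expect_equal(length(findMaximalIRs("AAANAAATTTTTTT")), 0L)
  # with a longer flank the arm re-forms up to (but never across) the N
  expect_equal(armLength(findMaximalIRs("GGNAAAAAAATTTTTTTGG")), 7L)
})

test_that("IR TSV round-trips through writeIRs/readIRs and BED export works", {
  x <- classifyIRs(findMaximalIRs(c(chrA = "TTTTTTGCATGCAAAAAA")))
  tsv <- tempfile(fileext = ".tsv")
  writeIRs(x, tsv, "tsv")
  y <- readIRs(tsv)
  expect_equal(start(y), start(x))
  expect_equal(leftArm(y), leftArm(x))
  expect_equal(as.character(irType(y)), as.character(irType(x)))

  bed <- tempfile(fileext = ".bed")
  writeIRs(x, bed, "bed")
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(fields[1:3], c("chrA", "0", "18"))   # 0-based half-open
  expect_equal(fields[4], "R9S0")
})
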