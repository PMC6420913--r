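test_that("gene models validate anchors and flag unclear ends", {
  g <- readGeneModels(toyGene())
  expect_equal(g$clearEnds, TRUE)
  # UTR lengths implied by the anchors
  r <- partitionGenome(g)
  utr5 <- r[regionKind(r) == "UTR5"]
  utr3 <- r[regionKind(r) == "UTR3"]
  expect_equal(width(utr5), 20L)   # [101, 120]
  expect_equal(width(utr3), 70L)   # [401, 470]

  # ordering violation: polya before stop on + strand
  expect_error(readGeneModels(toyGene(pa = 390)), "row")
  # duplicate ids
  expect_error(readGeneModels(rbind(toyGene(), toyGene())), "duplicate")
  # missing tss: kept, flagged, no UTR5 emitted
  g2 <- readGeneModels(toyGene(tss = NA))
  expect_false(g2$clearEnds)
  r2 <- partitionGenome(g2)
  expect_equal(as.character(regionKind(r2)), "ORF")

  # minus-strand gene mirrors the anchor order
  gm <- readGeneModels(toyGene(strand = "-", tss = 470, sc = 450, stc = 151,
                               pa = 101))
  rm_ <- partitionGenome(gm)
  expect_equal(width(rm_[regionKind(rm_) == "UTR5"]), 20L)
  expect_equal(width(rm_[regionKind(rm_) == "UTR3"]), 50L)
})

test_that("genic regions tile the transcript with no gaps or overlaps", {
  set.seed(21)
  for (i in 1:20) {
    u5 <- sample(10:100, 1); orf <- 3 * sample(100:600, 1)
    u3 <- sample(20:200, 1); tss <- sample(1:1000, 1)
    strand <- sample(c("+", "-"), 1)
    g <- if (strand == "+")
      toyGene(strand = "+", tss = tss, sc = tss + u5,
              stc = tss + u5 + orf - 1, pa = tss + u5 + orf + u3 - 1)
    else
      toyGene(strand = "-", pa = tss, stc = tss + u3, sc = tss + u3 + orf - 1,
              tss = tss + u3 + orf + u5 - 1)
    r <- partitionGenome(readGeneModels(g))
    expect_equal(sum(width(r)), u5 + orf + u3)
    expect_equal(length(reduce(granges(r))), 1L)  # contiguous, no overlap
    expect_equal(min(start(r)), tss)
  }
})

test_that("intergenic regions get the orientation label and exact bounds", {
  # convergent: two poly(A) sites face the gap; both anchor bases excluded
  g <- readGeneModels(rbind(
    toyGene("g1", strand = "+", tss = 101, sc = 121, stc = 400, pa = 470),
    toyGene("g2", strand = "-", tss = 900, sc = 880, stc = 601, pa = 530)))
  r <- partitionGenome(g)
  con <- r[regionKind(r) == "CON"]
  expect_equal(length(con), 1L)
  expect_equal(c(start(con), end(con)), c(471L, 529L))
  expect_equal(width(con), 59L)
  expect_equal(mcols(con)$geneId, "g1,g2")

  # tandem: same strands
  g2 <- readGeneModels(rbind(
    toyGene("g1", strand = "+", tss = 101, sc = 121, stc = 400, pa = 470),
    toyGene("g2", strand = "+", tss = 550, sc = 580, stc = 880, pa = 940)))
  r2 <- partitionGenome(g2)
  tan <- r2[regionKind(r2) == "TAN"]
  expect_equal(c(start(tan), end(tan)), c(471L, 549L))

  # divergent: two TSSs face the gap
  g3 <- readGeneModels(rbind(
    toyGene("g1", strand = "-", tss = 470, sc = 450, stc = 151, pa = 101),
    toyGene("g2", strand = "+", tss = 550, sc = 580, stc = 880, pa = 940)))
  r3 <- partitionGenome(g3)
  expect_equal(as.character(regionKind(r3)[start(r3) == 471]), "DIV")

  # an excluded feature voids the whole intergenic region
  excl <- GRanges("chrI", IRanges(500, 510))
  r4 <- partitionGenome(g, excluded = excl)
  expect_equal(sum(regionKind(r4) == "CON"), 0L)

  # unclear-ended neighbor blocks intergenic construction
  g5 <- g; g5$tss[2] <- NA; g5$clearEnds[2] <- FALSE
  r5 <- partitionGenome(g5)
  expect_equal(sum(regionKind(r5) %in% c("TAN", "DIV", "CON")), 0L)
})

test_that("overlapping UTRs collapse into OUR regions", {
  # convergent overlap: 3'-UTRs share bases -> one OUR3 replaces both UTR3s
  g <- readGeneModels(rbind(
    toyGene("g1", strand = "+", tss = 101, sc = 121, stc = 400, pa = 470),
    toyGene("g2", strand = "-", tss = 800, sc = 780, stc = 501, pa = 440)))
  r <- partitionGenome(g)
  expect_equal(sum(regionKind(r) == "UTR3"), 0L)
  our <- r[regionKind(r) == "OUR3"]
  expect_equal(length(our), 1L)
  expect_equal(c(start(our), end(our)), c(401L, 500L))  # union of both UTR3s
  expect_equal(sum(regionKind(r) == "CON"), 0L)

  # tandem overlap: 3'-UTR over 5'-UTR -> OUR2
  g2 <- readGeneModels(rbind(
    toyGene("g1", strand = "+", tss = 101, sc = 121, stc = 400, pa = 470),
    toyGene("g2", strand = "+", tss = 450, sc = 500, stc = 800, pa = 860)))
  r2 <- partitionGenome(g2)
  expect_equal(sum(regionKind(r2) == "OUR2"), 1L)
})

test_that("relative offsets are anchored, oriented and bijective", {
  g <- readGeneModels(toyGene())
  expect_equal(relativeOffset(410, "stop_codon", g), 10L)
  expect_equal(relativeOffset(400, "stop_codon", g), 0L)
  gm <- readGeneModels(toyGene(strand = "-", tss = 900, sc = 880, stc = 601,
                               pa = 530))
  expect_equal(relativeOffset(520, "polya_site", gm), 10L)
  # bijection over a window
  pos <- 100:200
  off <- relativeOffset(pos, "tss", g)
  expect_equal(length(unique(off)), length(pos))
  expect_equal(pos[match(0L, off)], g$tss)
})

test_that("length groups split equal counts, drop the shortest, report bounds", {
  r <- GRanges("c", IRanges(1, width = seq(10, 100, 10)))
  lg <- lengthGroups(r, k = 5)
  expect_equal(names(lg$groups), c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(sort(width(r)[lg$discarded]), c(10, 20))
  expect_equal(lg$bounds$min, c(30, 50, 70, 90))
  expect_equal(lg$bounds$max, c(40, 60, 80, 100))

  # remainder spreads over the shortest groups
  r2 <- GRanges("c", IRanges(1, width = 1:12))
  lg2 <- lengthGroups(r2, k = 5)
  expect_equal(length(lg2$discarded), 3L)
  expect_equal(unname(lengths(lg2$groups)), c(3L, 2L, 2L, 2L))

  # all lengths equal: equal-size groups, identical bounds
  r3 <- GRanges("c", IRanges(1, width = rep(50, 10)))
  lg3 <- lengthGroups(r3, k = 5)
  expect_true(all(lg3$bounds$min == 50 & lg3$bounds$max == 50))

  expect_error(lengthGroups(r[1:3], k = 5), "fewer")
})
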