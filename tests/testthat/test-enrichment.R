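test_that("randomization conserves per-segment composition and is seeded", {
  set.seed(17)
  s <- randomSeq(600, 0.62)
  genome <- Biostrings::DNAStringSet(c(chrI = s))
  genes <- readGeneModels(toyGene(tss = 101, sc = 121, stc = 400, pa = 470))
  seg <- codingSegments(genes, c(chrI = 600L))
  expect_equal(sum(width(seg)), 600L)

  r1 <- randomizeGenome(genome, seg, seed = 5)
  r2 <- randomizeGenome(genome, seg, seed = 5)
  r3 <- randomizeGenome(genome, seg, seed = 6)
  expect_identical(as.character(r1), as.character(r2))  # deterministic
  expect_false(identical(as.character(r1), as.character(r3)))

  # composition of every segment conserved exactly
  for (i in seq_along(seg)) {
    a <- substring(s, start(seg)[i], end(seg)[i])
    b <- substring(as.character(r1[[1]]), start(seg)[i], end(seg)[i])
    expect_equal(sort(strsplit(a, "")[[1]]), sort(strsplit(b, "")[[1]]))
  }

  # pooled-noncoding mode conserves chromosome composition
  rp <- randomizeGenome(genome, seg, seed = 5, pool = "noncoding")
  expect_equal(sort(strsplit(as.character(rp[[1]]), "")[[1]]),
               sort(strsplit(s, "")[[1]]))

  # segments must tile the chromosome
  expect_error(randomizeGenome(genome, seg[-1], seed = 1), "tile")
})

test_that("IR centers land in the right anchored bins", {
  genes <- readGeneModels(toyGene())        # + strand, polya 470
  sl <- c(chrI = 600L)
  regions <- partitionGenome(genes, seqlengths = sl)
  # one IR with center at offset -5 from the poly(A) site
  irs <- new("IRSet", GRanges("chrI", IRanges(458, 472),
                              armLen = 7L, spacerLen = 1L, center = 465L,
                              leftArm = "AAAAAAA"))
  p <- binIRCenters(irs, regions, genes, "UTR3", "polya_site",
                    span = c(-19L, 0L), retain = "all")
  expect_equal(binStarts(p), c(-19L, -9L))
  expect_equal(binCounts(p), c(0L, 1L))

  # outside the span: not counted
  p2 <- binIRCenters(irs, regions, genes, "UTR3", "polya_site",
                     span = c(-69L, -50L), retain = "all")
  expect_equal(sum(binCounts(p2)), 0L)

  # span not a multiple of the bin width widens with a warning
  expect_warning(binIRCenters(irs, regions, genes, "UTR3", "polya_site",
                              span = c(-14L, 0L), retain = "all"), "widened")
})

test_that("short convergent regions are profiled once per flanking window", {
  genes <- readGeneModels(rbind(
    toyGene("g1", strand = "+", tss = 1, sc = 31, stc = 330, pa = 400),
    toyGene("g2", strand = "-", tss = 950, sc = 920, stc = 621, pa = 551)))
  sl <- c(chrI = 1000L)
  regions <- partitionGenome(genes, seqlengths = sl)  # CON = [401, 550]
  irs <- new("IRSet", GRanges("chrI", IRanges(468, 482),
                              armLen = 7L, spacerLen = 1L, center = 475L,
                              leftArm = "AAAAAAA"))
  p <- binIRCenters(irs, regions, genes, "CON", "polya_site",
                    span = c(1L, 200L))
  expect_equal(p@nSamples, 2L)            # two poly(A) windows
  expect_equal(sum(binCounts(p)), 2L)     # counted once per window
  # offsets: +75 from g1's poly(A), +76 from g2's
  expect_equal(which(binCounts(p) > 0), 8L)
})

test_that("profiles are invariant to chromosome processing order", {
  set.seed(23)
  g1 <- randomSeq(800, 0.62); g2 <- randomSeq(700, 0.62)
  a <- findMaximalIRs(Biostrings::DNAStringSet(c(c1 = g1, c2 = g2)))
  b <- findMaximalIRs(Biostrings::DNAStringSet(c(c2 = g2, c1 = g1)))
  expect_equal(sort(paste(seqnames(a), start(a), armLength(a))),
               sort(paste(seqnames(b), start(b), armLength(b))))
})

test_that("planted enrichment is flagged and controls destroy the signal", {
  cfg <- synthConfig(nChromosomes = 1L, nGenes = 60L, orfMean = 600,
                     orfSd = 100, orfMin = 300,
                     plantedIRs = list(list(type = "III", armLen = 8L,
                                            spacerLen = 0L,
                                            anchorKind = "polya_site",
                                            window = c(-60L, -30L),
                                            prob = 0.9)),
                     seed = 99L)
  sg <- generateSyntheticGenome(cfg)
  prof <- profileWithControls(sg@genome, sg@genes, "UTR3", "polya_site",
                              nControls = 30L, seed = 7L)
  calls <- significanceCalls(prof)
  bins <- binStarts(prof)
  planted <- bins >= -60L & bins <= -40L  # bins fully inside the window
  expect_true(all(calls$direction[planted] == "enrichment"))
  expect_true(all(calls$pLevel[planted] <= 0.01))
  # control counts in the planted bins sit far below the test counts
  expect_gt(min(binCounts(prof)[planted]),
            max(rowMeans(controlCounts(prof))[planted]) * 2)
  # reproducibility metadata records the control seeds
  expect_equal(prof@meta$controlSeeds, 7L + 1:30)
})
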