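test_that("generation is seed-deterministic", {
  cfg <- smallSynthConfig(seed = 4L)
  a <- generateSyntheticGenome(cfg)
  b <- generateSyntheticGenome(cfg)
  expect_identical(as.character(a@genome), as.character(b@genome))
  expect_identical(a@truth, b@truth)
  expect_identical(as.data.frame(a@nucleosomes$mnase),
                   as.data.frame(b@nucleosomes$mnase))
  c_ <- generateSyntheticGenome(smallSynthConfig(seed = 5L))
  expect_false(identical(as.character(a@genome), as.character(c_@genome)))
})

test_that("planted IRs are recovered exactly and classify as declared", {
  sg <- generateSyntheticGenome(smallSynthConfig(seed = 8L))
  expect_gt(nrow(sg@truth), 20)
  irs <- classifyIRs(findMaximalIRs(sg@genome))
  found <- paste(seqnames(irs), start(irs), end(irs), armLength(irs),
                 spacerLength(irs), irType(irs))
  want <- paste(sg@truth$chrom, sg@truth$start, sg@truth$end, sg@truth$armLen,
                sg@truth$spacerLen, sg@truth$typeId)
  expect_true(all(want %in% found))
  # truth offsets point at the recorded anchor
  g <- sg@genes[sg@truth$geneId, ]
  off <- ifelse(g$strand == "+",
                sg@truth$center - mapply(function(i, a) g[[a]][i],
                                         seq_len(nrow(g)), sg@truth$anchorKind),
                mapply(function(i, a) g[[a]][i], seq_len(nrow(g)),
                       sg@truth$anchorKind) - sg@truth$center)
  expect_equal(unname(off), sg@truth$offset)
})

test_that("generated annotations and nucleosome calls satisfy the invariants", {
  sg <- generateSyntheticGenome(smallSynthConfig(seed = 12L))
  g <- readGeneModels(sg@genes[, 1:7])   # must validate cleanly
  expect_true(all(g$clearEnds))
  sl <- setNames(width(sg@genome), names(sg@genome))
  for (cond in names(sg@nucleosomes)) {
    nuc <- sg@nucleosomes[[cond]]
    expect_true(all(start(nuc) >= 1))
    expect_true(all(end(nuc) <= sl[as.character(seqnames(nuc))]))
    expect_true(all(width(nuc) == sg@config$nucWidth))
  }
  # genome-wide AT content close to the configured fraction
  at <- sum(Biostrings::letterFrequency(sg@genome, "AT")) /
    sum(width(sg@genome))
  expect_lt(abs(at - sg@config$atFraction), 0.03)
})

test_that("depletion windows carry less occupancy than their flanks", {
  sg <- generateSyntheticGenome(smallSynthConfig(seed = 19L))
  sl <- setNames(width(sg@genome), names(sg@genome))
  tracks <- occupancyTracks(sg@nucleosomes$mnase, sl)
  chrom <- names(sl)[1]
  v <- as.integer(tracks[[chrom]]$values)
  dep <- sg@depletion[seqnames(sg@depletion) == chrom]
  inside <- unlist(lapply(seq_along(dep), function(i)
    v[start(dep)[i]:end(dep)[i]]))
  expect_lt(mean(inside), 0.5 * mean(v))
})

test_that("infeasible planted types are rejected at config time", {
  expect_error(synthConfig(plantedIRs = list(
    list(type = "V", armLen = 5L, spacerLen = 3L,
         anchorKind = "polya_site", window = c(-40L, -20L), prob = 0.5))),
    "length >= 6")
  # planted IRs must pass the scanner thresholds
  expect_error(synthConfig(plantedIRs = list(
    list(type = "II", armLen = 5L, spacerLen = 2L,
         anchorKind = "polya_site", window = c(-40L, -20L), prob = 0.5))))
})

test_that("written synthetic data round-trips through the readers", {
  sg <- generateSyntheticGenome(smallSynthConfig(seed = 23L))
  dir <- tempfile()
  writeSyntheticData(sg, dir)
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fasta"))
  names(genome) <- sub(" .*", "", names(genome))
  expect_identical(as.character(genome), as.character(sg@genome))
  genes <- readGeneModels(file.path(dir, "genes.tsv"))
  expect_equal(genes$polya_site, sg@genes$polya_site)
  nuc <- readNucleosomeCalls(file.path(dir, "nucleosomes_mnase.bed"))
  expect_equal(length(nuc), length(sg@nucleosomes$mnase))
  expect_equal(start(nuc), start(sg@nucleosomes$mnase))  # 1-based restored
})
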