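#' Recipe for a synthetic genome with planted IRs and nucleosome calls
#'
#' The defaults emulate the study conditions of the yeast analysis: regional
#' mean lengths near the genome-wide averages (ORF 1536 bp, 3'-UTR 120 bp,
#' intergenic means by orientation), background AT fraction 0.62, and three
#' planted-IR populations at the anchored offset windows where the three
#' enriched sequence types occur (type III at offsets -60..-31 of the
#' poly(A) site, type II at -20..-11, type VII at +30..+59 of the start
#' codon). Offset windows are half-open integer sets `[lo, hi)` written as
#' `c(lo, hi)` so that 10-bp analysis bins tile them exactly.
#'
#' Nucleosomes of `nucWidth` bp are laid down with jittered linkers; calls
#' overlapping a depletion window (anchored like the planted IRs, default
#' covering the 3'-UTR IR neighborhood) are dropped with probability
#' `depletionProb`. Two conditions (`"mnase"`, `"chemical"`) are sampled
#' independently from the one depletion layout, emulating two independent
#' nucleosome maps of the same chromatin.
#'
#' @param nChromosomes number of chromosomes.
#' @param nGenes total gene count, split evenly across chromosomes.
#' @param atFraction background AT fraction.
#' @param utr5Mean,utr5Sd,utr5Min 5'-UTR length distribution (bp; truncated
#'   normal, rounded).
#' @param orfMean,orfSd,orfMin ORF length distribution (rounded to codons).
#' @param utr3Mean,utr3Sd,utr3Min 3'-UTR length distribution.
#' @param intergenicMean,intergenicSd,intergenicMin intergenic gap
#'   distribution.
#' @param strandProb probability that a gene lies on the `+` strand
#'   (independent strands give tandem/divergent/convergent neighbor mixes of
#'   about 1/2, 1/4, 1/4).
#' @param plantedIRs list of plant specifications; each a list with elements
#'   `type` (`"I"`..`"VII"`), `armLen`, `spacerLen`, `anchorKind`, `window`
#'   (half-open offset window `c(lo, hi)`), `prob` (per-gene planting
#'   probability).
#' @param nucWidth nucleosome width (bp).
#' @param linkerMean,linkerSd linker length distribution (bp).
#' @param depletionAnchor,depletionWindow,depletionProb nucleosome depletion
#'   windows: anchored half-open offset window realized per clear-ended
#'   gene; calls overlapping one are dropped with `depletionProb`.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a validated config list of class `synth_config`.
#' @export
synthConfig <- function(nChromosomes = 2L,
                        nGenes = 200L,
                        atFraction = 0.62,
                        utr5Mean = 70, utr5Sd = 20, utr5Min = 20,
                        orfMean = 1536, orfSd = 300, orfMin = 300,
                        utr3Mean = 120, utr3Sd = 30, utr3Min = 75,
                        intergenicMean = 300, intergenicSd = 80,
                        intergenicMin = 60,
                        strandProb = 0.5,
                        plantedIRs = list(
                          list(type = "III", armLen = 8L, spacerLen = 0L,
                               anchorKind = "polya_site",
                               window = c(-60L, -30L), prob = 0.7),
                          list(type = "II", armLen = 5L, spacerLen = 3L,
                               anchorKind = "polya_site",
                               window = c(-20L, -10L), prob = 0.5),
                          list(type = "VII", armLen = 6L, spacerLen = 1L,
                               anchorKind = "start_codon",
                               window = c(30L, 60L), prob = 0.5)),
                        nucWidth = 147L,
                        linkerMean = 18, linkerSd = 6,
                        depletionAnchor = "polya_site",
                        depletionWindow = c(-60L, -30L),
                        depletionProb = 0.9,
                        seed = 1L) {
  cfg <- list(nChromosomes = as.integer(nChromosomes),
              nGenes = as.integer(nGenes), atFraction = atFraction,
              utr5Mean = utr5Mean, utr5Sd = utr5Sd, utr5Min = utr5Min,
              orfMean = orfMean, orfSd = orfSd, orfMin = orfMin,
              utr3Mean = utr3Mean, utr3Sd = utr3Sd, utr3Min = utr3Min,
              intergenicMean = intergenicMean, intergenicSd = intergenicSd,
              intergenicMin = intergenicMin, strandProb = strandProb,
              plantedIRs = plantedIRs, nucWidth = as.integer(nucWidth),
              linkerMean = linkerMean, linkerSd = linkerSd,
              depletionAnchor = depletionAnchor,
              depletionWindow = as.integer(depletionWindow),
              depletionProb = depletionProb, seed = as.integer(seed))
  .validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

.validate_synth_config <- function(cfg) {
  stopifnot(cfg$nChromosomes >= 1L, cfg$nGenes >= 1L,
            cfg$atFraction >= 0, cfg$atFraction <= 1,
            cfg$strandProb >= 0, cfg$strandProb <= 1,
            cfg$depletionProb >= 0, cfg$depletionProb <= 1,
            cfg$utr5Min > 0, cfg$orfMin > 0, cfg$utr3Min > 0,
            cfg$intergenicMin > 0, cfg$nucWidth > 0)
  for (ps in cfg$plantedIRs) {
    stopifnot(is.list(ps),
              all(c("type", "armLen", "spacerLen", "anchorKind", "window",
                    "prob") %in% names(ps)),
              ps$prob >= 0, ps$prob <= 1, ps$window[1] < ps$window[2])
    # planted IRs must satisfy the scanner's detection thresholds
    stopifnot(ps$armLen >= 5L, ps$spacerLen >= 0L, ps$spacerLen <= 8L,
              2L * ps$armLen + ps$spacerLen >= 13L)
    arm <- .planted_arm(ps$type, ps$armLen)
    got <- as.character(classifyArmFeatures(armFeatures(arm)))
    if (got != ps$type)
      stop("planted arm for type ", ps$type, " of length ", ps$armLen,
           " classifies as type ", got,
           " (type/length combination infeasible)")
  }
  invisible(cfg)
}

# Deterministic arm constructors per type. The all-C spacer used alongside
# them never base-pairs with itself, so the planted (armLen, spacerLen)
# decomposition is the unique maximal reading of its interval.
.planted_arm <- function(type, armLen) {
  L <- as.integer(armLen)
  alt <- function(n, first = "A") {
    chars <- if (first == "A") c("A", "T") else c("T", "A")
    paste(rep_len(chars, n), collapse = "")
  }
  switch(type,
    "III" = alt(L),
    "II"  = strrep("A", L),
    "I"   = {  # an A-tract and an alternating stretch sharing one base
      if (L < 6L) stop("type I arms need length >= 6")
      k <- max(3L, as.integer(ceiling(L / 2)))
      paste0(strrep("A", k), substring(alt(L - k + 1L, "T"), 2L))
    },
    "IV"  = paste(rep_len(c("A", "A", "T", "T"), L), collapse = ""),
    "V"   = {  # tract-rich but not AT-rich
      if (L < 6L) stop("type V arms need length >= 6")
      k <- max(3L, as.integer(ceiling(L / 2)))
      if (k / L >= 0.6) stop("type V arms need length >= 6")
      paste0(strrep("A", k), paste(rep_len(c("G", "C"), L - k), collapse = ""))
    },
    "VI"  = {  # alternating-rich but not AT-rich
      if (L < 7L) stop("type VI arms need length >= 7")
      k <- 2L * as.integer(ceiling(L / 4))
      paste0(alt(k), paste(rep_len(c("G", "C"), L - k), collapse = ""))
    },
    "VII" = paste(rep_len(c("G", "G", "C", "A", "C"), L), collapse = ""),
    stop("unknown IR type: ", type)
  )
}

.revcomp_chr <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

#' Generate a synthetic genome with annotations, nucleosome calls and truth
#'
#' Lays genes out non-overlapping along each chromosome with background
#' bases drawn i.i.d. at the configured AT fraction, plants IR sequences of
#' the configured types at offsets sampled from their anchored windows
#' (flanked by non-pairing guard bases so each planted IR is a maximal
#' repeat, and verified against the scanner and classifier at generation
#' time), and places two independently sampled nucleosome-call conditions
#' that share one depletion layout. Identical configs (including the seed)
#' give byte-identical output.
#'
#' Plant placements that would collide with an already planted IR in the
#' same gene are re-drawn a few times and then skipped; only realized plants
#' enter the truth table, so scanning the genome recovers every truth row
#' with exact coordinates and declared type.
#'
#' @param config a [synthConfig()].
#' @return a [SyntheticGenome].
#' @export
generateSyntheticGenome <- function(config = synthConfig()) {
  if (!inherits(config, "synth_config")) config <- do.call(synthConfig, config)
  set.seed(config$seed)

  rlen <- function(n, mean, sd, min) pmax(as.integer(min),
                                          as.integer(round(rnorm(n, mean, sd))))
  n_per <- rep(config$nGenes %/% config$nChromosomes, config$nChromosomes)
  extra <- config$nGenes %% config$nChromosomes
  if (extra > 0L) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L

  genes <- list()
  truth <- list()
  chrom_seqs <- character(config$nChromosomes)
  chrom_names <- paste0("synth_chr", utils::as.roman(seq_len(config$nChromosomes)))
  bases <- c("A", "T", "G", "C")
  probs <- c(config$atFraction / 2, config$atFraction / 2,
             (1 - config$atFraction) / 2, (1 - config$atFraction) / 2)
  gene_counter <- 0L

  for (ci in seq_len(config$nChromosomes)) {
    ng <- n_per[ci]
    gaps <- rlen(ng + 1L, config$intergenicMean, config$intergenicSd,
                 config$intergenicMin)
    u5 <- rlen(ng, config$utr5Mean, config$utr5Sd, config$utr5Min)
    orf <- rlen(ng, config$orfMean, config$orfSd, config$orfMin)
    orf <- 3L * pmax(as.integer(config$orfMin) %/% 3L, orf %/% 3L)
    u3 <- rlen(ng, config$utr3Mean, config$utr3Sd, config$utr3Min)
    strands <- ifelse(runif(ng) < config$strandProb, "+", "-")

    cur <- 0L
    rows <- vector("list", ng)
    for (gi in seq_len(ng)) {
      cur <- cur + gaps[gi]
      glen <- u5[gi] + orf[gi] + u3[gi]
      lo <- cur + 1L
      hi <- cur + glen
      gene_counter <- gene_counter + 1L
      if (strands[gi] == "+") {
        tss <- lo; sc <- tss + u5[gi]; stc <- sc + orf[gi] - 1L; pa <- hi
      } else {
        pa <- lo; stc <- pa + u3[gi]; sc <- stc + orf[gi] - 1L; tss <- hi
      }
      rows[[gi]] <- data.frame(
        gene_id = sprintf("g%04d", gene_counter), chrom = chrom_names[ci],
        strand = strands[gi], tss = tss, start_codon = sc, stop_codon = stc,
        polya_site = pa, stringsAsFactors = FALSE)
      cur <- hi
    }
    L <- cur + gaps[ng + 1L]
    seq_chars <- sample(bases, L, replace = TRUE, prob = probs)
    g <- do.call(rbind, rows)

    # plant IRs
    for (gi in seq_len(nrow(g))) {
      planted_iv <- NULL  # occupied intervals (incl. guards) in this gene
      for (ps in config$plantedIRs) {
        if (runif(1) >= ps$prob) next
        total <- 2L * ps$armLen + ps$spacerLen
        half <- (total - 1L) %/% 2L
        anchor <- g[[ps$anchorKind]][gi]
        strand <- g$strand[gi]
        placed <- FALSE
        for (try in 1:20) {
          off <- sample(seq.int(ps$window[1], ps$window[2] - 1L), 1L)
          center <- if (strand == "+") anchor + off else anchor - off
          s0 <- center - half
          e0 <- s0 + total - 1L
          if (s0 < 2L || e0 > L - 1L) next
          iv <- c(s0 - 1L, e0 + 1L)
          clash <- !is.null(planted_iv) &&
            any(planted_iv[, 1] <= iv[2] & planted_iv[, 2] >= iv[1])
          if (clash) next
          arm <- .planted_arm(ps$type, ps$armLen)
          irseq <- paste0(arm, strrep("C", ps$spacerLen), .revcomp_chr(arm))
          seq_chars[s0:e0] <- strsplit(irseq, "")[[1]]
          seq_chars[s0 - 1L] <- "C"   # guard: C never pairs with C
          seq_chars[e0 + 1L] <- "C"
          planted_iv <- rbind(planted_iv, iv)
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = chrom_names[ci], start = s0, end = e0,
            armLen = ps$armLen, spacerLen = ps$spacerLen,
            center = s0 + (total - 1L) %/% 2L, typeId = ps$type,
            geneId = g$gene_id[gi], anchorKind = ps$anchorKind,
            offset = off, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
    }
    chrom_seqs[ci] <- paste(seq_chars, collapse = "")
    genes[[ci]] <- g
  }

  genes <- do.call(rbind, genes)
  rownames(genes) <- genes$gene_id
  genes$clearEnds <- TRUE
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(chrom = character(), start = integer(),
                           end = integer(), armLen = integer(),
                           spacerLen = integer(), center = integer(),
                           typeId = character(), geneId = character(),
                           anchorKind = character(), offset = integer())
  genome <- DNAStringSet(chrom_seqs)
  names(genome) <- chrom_names

  # repair rare background collisions so every truth row is a maximal IR
  genome <- .verify_planted(genome, truth, bases, probs)

  # depletion windows (anchored, realized per gene in gene orientation)
  dw <- config$depletionWindow
  anchor <- genes[[config$depletionAnchor]]
  plus <- genes$strand == "+"
  dep_start <- ifelse(plus, anchor + dw[1], anchor - dw[2] + 1L)
  dep_end <- ifelse(plus, anchor + dw[2] - 1L, anchor - dw[1])
  sl <- setNames(width(genome), names(genome))
  dep <- GRanges(genes$chrom,
                 IRanges(pmax(1L, as.integer(dep_start)),
                         pmin(sl[genes$chrom], as.integer(dep_end))))
  seqlevels(dep) <- names(sl)
  seqlengths(dep) <- sl
  mcols(dep)$geneId <- genes$gene_id

  nucs <- list(
    mnase = .sample_nucleosomes(sl, config, dep),
    chemical = .sample_nucleosomes(sl, config, dep))

  new("SyntheticGenome", genome = genome, genes = genes,
      nucleosomes = nucs, truth = truth, depletion = dep,
      config = unclass(config))
}

# Scan the neighborhood of each planted IR; if the planted interval is not
# recovered exactly (a chance background IR properly contains it, or an
# equal-interval reading with a larger arm exists), re-draw the background
# bases around it and re-check.
.verify_planted <- function(genome, truth, bases, probs) {
  if (nrow(truth) == 0L) return(genome)
  margin <- 60L
  chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  planted <- GRanges(truth$chrom, IRanges(truth$start - 1L, truth$end + 1L))
  for (i in seq_len(nrow(truth))) {
    chrom <- truth$chrom[i]
    L <- length(chars[[chrom]])
    lo <- max(1L, truth$start[i] - margin)
    hi <- min(L, truth$end[i] + margin)
    for (try in 1:25) {
      win <- paste(chars[[chrom]][lo:hi], collapse = "")
      found <- findMaximalIRs(win, chrom = "w")
      ok <- any(start(found) == truth$start[i] - lo + 1L &
                  end(found) == truth$end[i] - lo + 1L &
                  armLength(found) == truth$armLen[i] &
                  spacerLength(found) == truth$spacerLen[i])
      if (ok) break
      # resample background bases in the window that belong to no plant
      pos <- lo:hi
      free <- !overlapsAny(GRanges(chrom, IRanges(pos, width = 1L)), planted)
      if (!any(free)) stop("cannot isolate planted IR ", i)
      chars[[chrom]][pos[free]] <- sample(bases, sum(free), replace = TRUE,
                                          prob = probs)
      if (try == 25L) stop("failed to isolate planted IR ", i)
    }
  }
  out <- DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
  names(out) <- names(genome)
  out
}

.sample_nucleosomes <- function(seqlengths, config, depletion) {
  grs <- lapply(names(seqlengths), function(chrom) {
    L <- seqlengths[[chrom]]
    starts <- integer()
    pos <- sample.int(80L, 1L)
    while (pos + config$nucWidth - 1L <= L) {
      starts <- c(starts, pos)
      linker <- max(2L, as.integer(round(rnorm(1, config$linkerMean,
                                               config$linkerSd))))
      pos <- pos + config$nucWidth + linker
    }
    GRanges(chrom, IRanges(starts, width = config$nucWidth))
  })
  gr <- suppressWarnings(do.call(c, grs))
  seqlevels(gr) <- names(seqlengths)
  seqlengths(gr) <- seqlengths
  hit <- overlapsAny(gr, depletion)
  drop <- hit & (runif(length(gr)) < config$depletionProb)
  gr[!drop]
}

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome:", length(object@genome), "chromosome(s),",
      sum(width(object@genome)), "bp,", nrow(object@genes), "genes\n",
      " planted IRs:", nrow(object@truth), "(",
      paste(names(table(object@truth$typeId)), table(object@truth$typeId),
            sep = ":", collapse = " "), ")\n",
      " nucleosome calls:",
      paste(names(object@nucleosomes), lengths(object@nucleosomes),
            sep = ":", collapse = " "), "\n")
})

#' Write a synthetic data set in the formats the pipeline consumes
#'
#' Writes `genome.fasta`, `genes.tsv` (1-based annotation table),
#' `nucleosomes_<condition>.bed` per condition, `truth_irs.tsv` and
#' `truth_depletion.bed`.
#'
#' @param x a [SyntheticGenome].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticData <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(x@genome, file.path(dir, "genome.fasta"))
  write.table(x@genes[, c("gene_id", "chrom", "strand", "tss", "start_codon",
                          "stop_codon", "polya_site")],
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (cond in names(x@nucleosomes))
    rtracklayer::export(x@nucleosomes[[cond]],
                        file.path(dir, paste0("nucleosomes_", cond, ".bed")),
                        format = "BED")
  write.table(x@truth, file.path(dir, "truth_irs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rtracklayer::export(x@depletion, file.path(dir, "truth_depletion.bed"),
                      format = "BED")
  invisible(dir)
}
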