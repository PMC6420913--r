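#' @rdname BinnedProfile-class
#' @export
setMethod("binStarts", "BinnedProfile", function(x) x@binStarts)

#' @rdname BinnedProfile-class
#' @export
setMethod("binCounts", "BinnedProfile", function(x) x@counts)

#' @rdname BinnedProfile-class
#' @export
setMethod("controlCounts", "BinnedProfile", function(x) x@controls)

#' @rdname BinnedProfile-class
#' @export
setMethod("significanceCalls", "BinnedProfile", function(x) x@calls)

setMethod("show", "BinnedProfile", function(object) {
  cat("BinnedProfile:", object@regionKind, "anchored at", object@anchorKind,
      "\n  ", length(object@binStarts), "bins of", object@binWidth,
      "bp spanning offsets", min(object@binStarts), "..",
      max(object@binStarts) + object@binWidth - 1L, "\n  ",
      sum(object@counts), "IR centers in", object@nSamples,
      "region windows;", ncol(object@controls), "control genomes\n")
  if (nrow(object@calls)) {
    sig <- !is.na(object@calls$pLevel)
    cat("  ", sum(sig), "significant bin(s)\n")
  }
})

#' @describeIn BinnedProfile-class flatten to a `data.frame` (one row per
#'   bin; control mean/sd and Grubbs calls included when present).
#' @export
setMethod("as.data.frame", "BinnedProfile", function(x, ...) {
  df <- data.frame(bin_start = x@binStarts,
                   bin_end = x@binStarts + x@binWidth - 1L,
                   count = x@counts)
  if (ncol(x@controls)) {
    df$control_mean <- rowMeans(x@controls)
    df$control_sd <- apply(x@controls, 1L, sd)
  }
  if (nrow(x@calls)) df <- cbind(df, x@calls)
  df
})

#' Write a binned profile (with any control summary and Grubbs calls) as TSV
#' @param x a [BinnedProfile].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- window construction -------------------------------------------------

.FIXED_KINDS <- c("ORF", "TAN", "DIV", "CON")

# One row per (region, anchoring gene) window: the region interval plus the
# anchor position and the anchoring gene's strand. Intergenic regions yield
# up to two windows, one per flanking gene whose anchor of the requested
# kind faces the region.
.build_windows <- function(regions, genes, kind, anchorKind,
                           retain = c("auto", "aboveMean", "all")) {
  retain <- match.arg(retain)
  stopifnot(is(regions, "RegionSet"))
  rs <- regions[as.character(regionKind(regions)) == kind]
  if (length(rs) == 0L) stop("no regions of kind ", kind)
  mean_len <- mean(width(rs))
  if (retain == "auto")
    retain <- if (kind %in% .FIXED_KINDS) "all" else "aboveMean"
  if (retain == "aboveMean") rs <- rs[width(rs) > mean_len]
  if (length(rs) == 0L) stop("no regions of kind ", kind, " retained")

  gid <- mcols(rs)$geneId
  if (kind %in% c("TAN", "DIV", "CON", "OUR1", "OUR2", "OUR3")) {
    pair <- strsplit(gid, ",", fixed = TRUE)
    rows <- list()
    for (i in seq_along(rs)) {
      lg <- genes[pair[[i]][1], ]; rg <- genes[pair[[i]][2], ]
      # which flanking genes present an anchor of this kind to the region
      use <- list()
      if (anchorKind == "polya_site") {
        if (lg$strand == "+") use <- c(use, list(lg))
        if (rg$strand == "-") use <- c(use, list(rg))
      } else if (anchorKind == "tss") {
        if (lg$strand == "-") use <- c(use, list(lg))
        if (rg$strand == "+") use <- c(use, list(rg))
      } else {
        stop("intergenic regions are anchored at 'polya_site' or 'tss'")
      }
      for (g in use)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = as.character(seqnames(rs))[i], rstart = start(rs)[i],
          rend = end(rs)[i], anchor = g[[anchorKind]], strand = g$strand,
          stringsAsFactors = FALSE)
    }
    win <- do.call(rbind, rows)
  } else {
    g <- genes[gid, ]
    ok <- rep(TRUE, length(rs))
    if (anchorKind %in% c("tss", "polya_site")) ok <- g$clearEnds
    win <- data.frame(chrom = as.character(seqnames(rs))[ok],
                      rstart = start(rs)[ok], rend = end(rs)[ok],
                      anchor = g[[anchorKind]][ok], strand = g$strand[ok],
                      stringsAsFactors = FALSE)
  }
  if (is.null(win) || nrow(win) == 0L)
    stop("no anchored windows for kind ", kind, " at ", anchorKind)
  list(windows = win, meanLen = mean_len)
}

# Default offset span [lo, hi] (closed) for a kind/anchor pair: fixed 200-bp
# windows for ORF/TAN/DIV/CON, mean-length spans for the UTR kinds.
.default_span <- function(kind, anchorKind, meanLen, binWidth, window = 200L) {
  m <- max(binWidth, (floor(meanLen) %/% binWidth) * binWidth)
  switch(paste(kind, anchorKind),
    "ORF start_codon" = c(0L, window - 1L),
    "ORF stop_codon"  = c(-(window - 1L), 0L),
    "TAN polya_site"  = ,
    "CON polya_site"  = c(1L, window),
    "TAN tss"         = ,
    "DIV tss"         = c(-window, -1L),
    "UTR3 polya_site" = c(-(m - 1L), 0L),
    "UTR3 stop_codon" = c(1L, m),
    "UTR5 tss"        = c(0L, m - 1L),
    "UTR5 start_codon" = c(-m, -1L),
    stop("no default span for ", kind, " anchored at ", anchorKind,
         "; supply 'span'")
  )
}

.make_bins <- function(span, binWidth) {
  lo <- as.integer(span[1]); hi <- as.integer(span[2])
  if (binWidth <= 0L) stop("'binWidth' must be positive")
  if (hi < lo) stop("invalid span")
  n <- (hi - lo + 1L) %/% binWidth
  if (n * binWidth != hi - lo + 1L) {
    n <- n + 1L
    warning("span is not a multiple of binWidth; widened to ",
            lo + n * binWidth - 1L)
  }
  seq.int(lo, by = binWidth, length.out = n)
}

# Count anchored offsets of IR centers into bins. centers: data.frame with
# chrom, pos. Returns integer vector over bins.
.count_in_windows <- function(centers, windows, bin_starts, binWidth) {
  counts <- integer(length(bin_starts))
  if (nrow(centers) == 0L) return(counts)
  lo <- bin_starts[1]
  hi <- bin_starts[length(bin_starts)] + binWidth - 1L
  cgr <- GRanges(centers$chrom, IRanges(centers$pos, width = 1L))
  wgr <- GRanges(windows$chrom, IRanges(windows$rstart, windows$rend))
  hits <- findOverlaps(cgr, wgr, ignore.strand = TRUE)
  if (length(hits) == 0L) return(counts)
  ci <- queryHits(hits); wi <- subjectHits(hits)
  off <- ifelse(windows$strand[wi] == "+",
                centers$pos[ci] - windows$anchor[wi],
                windows$anchor[wi] - centers$pos[ci])
  off <- off[off >= lo & off <= hi]
  if (!length(off)) return(counts)
  tab <- tabulate((off - lo) %/% binWidth + 1L, nbins = length(bin_starts))
  as.integer(tab)
}

#' Bin IR centers by anchored offset within a region class
#'
#' Maps each IR center that falls inside a region of the requested kind to
#' its signed offset from the requested gene anchor (positive downstream in
#' the anchoring gene's orientation; see [relativeOffset()]) and counts
#' centers per `binWidth`-bp bin across the offset span.
#'
#' Retention (`retain = "auto"`): for the variable-span kinds (`UTR5`,
#' `UTR3`, `OUR*`) only regions longer than the kind's mean length are used,
#' so that every retained region covers the whole profiled span; for the
#' fixed-window kinds (`ORF`, `TAN`, `DIV`, `CON`) all regions are used with
#' 200-bp anchor windows. Intergenic regions are profiled from each flanking
#' gene whose anchor of the requested kind faces the region (both poly(A)
#' sites of a convergent pair, both TSSs of a divergent pair, one of each
#' for a tandem pair), so an IR center in a short region can contribute once
#' per window.
#'
#' @param irs an [IRSet] (optionally classified/filtered beforehand).
#' @param regions a [RegionSet] from [partitionGenome()].
#' @param genes gene-model table from [readGeneModels()].
#' @param kind region kind to profile.
#' @param anchorKind anchor defining offset 0.
#' @param span closed integer offset interval `c(lo, hi)`; default per
#'   kind/anchor (200-bp windows or the floor-to-bin mean region length).
#' @param binWidth bin width in bp.
#' @param retain `"auto"`, `"aboveMean"` or `"all"`.
#' @return a [BinnedProfile] (no controls attached).
#' @export
binIRCenters <- function(irs, regions, genes, kind, anchorKind, span = NULL,
                         binWidth = 10L, retain = "auto") {
  binWidth <- as.integer(binWidth)
  bw <- .build_windows(regions, genes, kind, anchorKind, retain = retain)
  if (is.null(span))
    span <- .default_span(kind, anchorKind, bw$meanLen, binWidth)
  bins <- .make_bins(span, binWidth)
  centers <- data.frame(chrom = as.character(seqnames(irs)),
                        pos = irCenter(irs))
  counts <- .count_in_windows(centers, bw$windows, bins, binWidth)
  new("BinnedProfile", regionKind = kind, anchorKind = anchorKind,
      binWidth = binWidth, binStarts = bins, counts = counts,
      nSamples = nrow(bw$windows), controls = matrix(0L, length(bins), 0L),
      calls = data.frame(),
      meta = list(meanLen = bw$meanLen, retain = retain, span = span))
}

#' Positional IR enrichment against randomized control genomes
#'
#' `profilePanelsWithControls()` runs the complete profiling computation for
#' any number of panels against one shared control ensemble: it scans the
#' real genome for IRs (classifying them when any panel filters on a
#' sequence type), bins their centers by anchored offset within each panel's
#' region class, generates `nControls` composition-preserving randomized
#' control genomes (seeds `seed + 1 .. seed + nControls`, each scanned
#' once and binned for every panel), and calls per-bin enrichment or
#' deficiency with the Grubbs test ([grubbsCall()]). No multiple-testing
#' correction is applied; calls are per-bin at the fixed `alphas`.
#'
#' `profileWithControls()` is the single-panel convenience wrapper.
#'
#' The randomization segmentation shuffles coding (merged ORF) and noncoding
#' sequence separately (see [codingSegments()], [randomizeGenome()]).
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param genes gene-model table ([readGeneModels()]).
#' @param panels named list; each element a list with `kind`, `anchorKind`
#'   and optionally `span`, `retain`, `irType`, `regions` (see
#'   [binIRCenters()]; `regions` overrides the shared partition, e.g. for a
#'   Q-group subset).
#' @param kind,anchorKind,span,retain,irType single-panel equivalents.
#' @param binWidth bin width in bp.
#' @param regions optional pre-built [RegionSet]; defaults to
#'   `partitionGenome(genes, excluded)`.
#' @param excluded features voiding intergenic regions ([partitionGenome()]).
#' @param nControls number of control genomes (>= 3; the study design uses
#'   100).
#' @param seed base seed for the control randomizations.
#' @param alphas Grubbs significance levels.
#' @param scanArgs extra arguments to [findMaximalIRs()].
#' @param classifyArgs extra arguments to [classifyIRs()].
#' @param pool randomization pooling mode ([randomizeGenome()]).
#' @param twoSided,bonferroni Grubbs critical-value form ([grubbsCall()]).
#' @return `profilePanelsWithControls()`: a named list of [BinnedProfile]
#'   objects carrying the control count matrix and per-bin Grubbs calls
#'   (`meta` records seeds and thresholds); `profileWithControls()`: a
#'   single [BinnedProfile].
#' @export
profilePanelsWithControls <- function(genome, genes, panels,
                                      regions = NULL, excluded = GRanges(),
                                      binWidth = 10L, nControls = 100L,
                                      seed = 1L, alphas = c(0.01, 0.001),
                                      scanArgs = list(),
                                      classifyArgs = list(),
                                      pool = "per_segment",
                                      twoSided = TRUE, bonferroni = FALSE) {
  nControls <- as.integer(nControls)
  if (nControls < 3L) stop("'nControls' must be >= 3")
  binWidth <- as.integer(binWidth)
  sl <- setNames(width(genome), names(genome))
  if (is.null(regions))
    regions <- partitionGenome(genes, excluded = excluded, seqlengths = sl)
  if (is.null(names(panels)))
    names(panels) <- vapply(panels, function(p)
      paste0(p$kind, "_", p$anchorKind,
             if (!is.null(p$irType)) paste0("_type", p$irType) else ""),
      character(1))
  need_types <- any(vapply(panels, function(p) !is.null(p$irType),
                           logical(1)))

  scan_all <- function(g) {
    irs <- do.call(findMaximalIRs, c(list(g), scanArgs))
    if (need_types) irs <- do.call(classifyIRs, c(list(irs), classifyArgs))
    irs
  }
  centers_of <- function(irs, irType) {
    if (!is.null(irType)) irs <- irs[as.character(irType(irs)) == irType]
    data.frame(chrom = as.character(seqnames(irs)), pos = irCenter(irs))
  }

  # per-panel fixed geometry (windows and bins) from the real annotations
  geometry <- lapply(panels, function(p) {
    reg <- p$regions %||% regions
    bw <- .build_windows(reg, genes, p$kind, p$anchorKind,
                         retain = p$retain %||% "auto")
    span <- p$span %||% .default_span(p$kind, p$anchorKind, bw$meanLen,
                                      binWidth)
    list(windows = bw$windows, meanLen = bw$meanLen,
         bins = .make_bins(span, binWidth), span = span,
         retain = p$retain %||% "auto", irType = p$irType)
  })

  real_irs <- scan_all(genome)
  real_counts <- lapply(names(panels), function(nm) {
    g <- geometry[[nm]]
    .count_in_windows(centers_of(real_irs, g$irType), g$windows, g$bins,
                      binWidth)
  })
  names(real_counts) <- names(panels)

  segments <- codingSegments(genes, sl)
  seeds <- seed + seq_len(nControls)
  ctrl_counts <- lapply(geometry, function(g)
    matrix(0L, length(g$bins), nControls,
           dimnames = list(NULL, paste0("ctrl", seq_len(nControls)))))
  for (b in seq_len(nControls)) {
    ctrl <- randomizeGenome(genome, segments, seed = seeds[b], pool = pool)
    irs <- scan_all(ctrl)
    for (nm in names(panels)) {
      g <- geometry[[nm]]
      ctrl_counts[[nm]][, b] <- .count_in_windows(centers_of(irs, g$irType),
                                                  g$windows, g$bins, binWidth)
    }
  }

  out <- lapply(names(panels), function(nm) {
    g <- geometry[[nm]]
    counts <- real_counts[[nm]]
    controls <- ctrl_counts[[nm]]
    calls <- do.call(rbind, lapply(seq_along(g$bins), function(i)
      grubbsCall(counts[i], controls[i, ], alphas = alphas,
                 twoSided = twoSided, bonferroni = bonferroni)))
    new("BinnedProfile", regionKind = panels[[nm]]$kind,
        anchorKind = panels[[nm]]$anchorKind, binWidth = binWidth,
        binStarts = g$bins, counts = counts,
        nSamples = nrow(g$windows), controls = controls, calls = calls,
        meta = list(meanLen = g$meanLen, retain = g$retain, span = g$span,
                    seed = seed, controlSeeds = seeds, alphas = alphas,
                    irType = g$irType, pool = pool, twoSided = twoSided,
                    bonferroni = bonferroni))
  })
  setNames(out, names(panels))
}

#' @rdname profilePanelsWithControls
#' @export
profileWithControls <- function(genome, genes, kind, anchorKind,
                                regions = NULL, excluded = GRanges(),
                                span = NULL, binWidth = 10L, retain = "auto",
                                irType = NULL, nControls = 100L, seed = 1L,
                                alphas = c(0.01, 0.001), scanArgs = list(),
                                classifyArgs = list(),
                                pool = "per_segment",
                                twoSided = TRUE, bonferroni = FALSE) {
  panel <- list(list(kind = kind, anchorKind = anchorKind, span = span,
                     retain = retain, irType = irType))
  profilePanelsWithControls(genome, genes, panel, regions = regions,
                            excluded = excluded, binWidth = binWidth,
                            nControls = nControls, seed = seed,
                            alphas = alphas, scanArgs = scanArgs,
                            classifyArgs = classifyArgs, pool = pool,
                            twoSided = twoSided,
                            bonferroni = bonferroni)[[1]]
}
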