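#' Read nucleosome calls from a BED file
#'
#' @param path BED3+ file of nucleosome intervals (one condition).
#' @param seqlengths optional named vector of chromosome lengths attached to
#'   the result (intervals are then bounds-checked downstream).
#' @return [GenomicRanges::GRanges].
#' @export
readNucleosomeCalls <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  gr
}

#' Binary nucleosome-occupancy track for one chromosome
#'
#' A base is occupied (value 1) exactly when at least one nucleosome call
#' covers it — overlapping calls count once (union semantics) — and
#' unoccupied (value 0) otherwise.
#'
#' @param calls [GenomicRanges::GRanges] of nucleosome intervals on a single
#'   chromosome (or the subset for `chrom` is taken).
#' @param chromLength chromosome length in bp.
#' @param chrom chromosome name (defaults to the single level present).
#' @return list with `values` (an [S4Vectors::Rle] of 0/1 over the
#'   chromosome) and `mean` (the chromosome-mean occupancy).
#' @examples
#' calls <- GenomicRanges::GRanges("c", IRanges::IRanges(11, 20))
#' buildOccupancyTrack(calls, 100)$mean   # 0.1
#' @export
buildOccupancyTrack <- function(calls, chromLength, chrom = NULL) {
  if (is.null(chrom)) {
    lev <- unique(as.character(seqnames(calls)))
    chrom <- if (length(lev)) lev[1] else NA_character_
  }
  calls <- calls[as.character(seqnames(calls)) == chrom]
  if (length(calls)) {
    bad <- start(calls) < 1L | end(calls) > chromLength
    if (any(bad)) {
      b <- which(bad)[1]
      stop("nucleosome call out of bounds on ", chrom, ": [",
           start(calls)[b], ", ", end(calls)[b], "] exceeds length ",
           chromLength)
    }
  }
  cov <- coverage(ranges(calls), width = chromLength)
  values <- Rle(as.integer(runValue(cov) > 0L), runLength(cov))
  list(values = values, mean = mean(values))
}

#' Occupancy tracks for all chromosomes of a genome
#' @param calls [GenomicRanges::GRanges] of nucleosome intervals.
#' @param seqlengths named vector of chromosome lengths.
#' @return named list of [buildOccupancyTrack()] results.
#' @export
occupancyTracks <- function(calls, seqlengths) {
  setNames(lapply(names(seqlengths), function(chrom)
    buildOccupancyTrack(calls, seqlengths[[chrom]], chrom = chrom)),
    names(seqlengths))
}

#' Average normalized nucleosome occupancy (nNuOc) around IR centers
#'
#' For each IR, the binary occupancy values at `center - flank ..
#' center + flank` are extracted, oriented so that positive offsets run
#' downstream in the owning gene's direction of transcription, and divided by
#' the chromosome's mean occupancy (so a chromosome's average occupancy is
#' 1.0 by definition). The normalized windows are then averaged across IRs
#' per offset. IRs within `flank` bp of a chromosome end, or on a chromosome
#' with zero occupancy, are skipped and counted in `nSkipped`.
#'
#' @param tracks per-chromosome tracks from [occupancyTracks()].
#' @param irs an [IRSet].
#' @param geneStrand strand (`"+"`/`"-"`) of each IR's owning gene; defaults
#'   to the `geneStrand` metadata column of `irs`.
#' @param flank half-window in bp (default 200).
#' @param condition label stored on the profile.
#' @return an [NnuocProfile].
#' @export
nnuocProfile <- function(tracks, irs, geneStrand = NULL, flank = 200L,
                         condition = "nucleosomes") {
  flank <- as.integer(flank)
  if (is.null(geneStrand)) geneStrand <- mcols(irs)$geneStrand
  if (is.null(geneStrand)) stop("supply 'geneStrand' (or a geneStrand ",
                                "metadata column on 'irs')")
  geneStrand <- rep(as.character(geneStrand), length.out = length(irs))
  if (length(irs) == 0L) stop("empty IR set")

  width <- 2L * flank + 1L
  acc <- numeric(width)
  n_used <- 0L
  n_skip <- 0L
  chroms <- as.character(seqnames(irs))
  centers <- irCenter(irs)
  for (i in seq_along(irs)) {
    tr <- tracks[[chroms[i]]]
    if (is.null(tr) || tr$mean == 0) { n_skip <- n_skip + 1L; next }
    lo <- centers[i] - flank
    hi <- centers[i] + flank
    if (lo < 1L || hi > length(tr$values)) { n_skip <- n_skip + 1L; next }
    v <- as.integer(window(tr$values, lo, hi))
    if (geneStrand[i] == "-") v <- rev(v)
    acc <- acc + v / tr$mean
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable IR windows (all skipped)")
  new("NnuocProfile", offsets = seq.int(-flank, flank),
      values = acc / n_used, nIRs = n_used, condition = condition,
      nSkipped = n_skip)
}

setMethod("show", "NnuocProfile", function(object) {
  cat("NnuocProfile (", object@condition, "): ", object@nIRs,
      " IR windows, offsets ", min(object@offsets), "..",
      max(object@offsets), "\n  value at center: ",
      signif(object@values[object@offsets == 0L], 4),
      "; mean: ", signif(mean(object@values), 4), "\n", sep = "")
  if (object@nSkipped)
    cat("  ", object@nSkipped, "IR window(s) skipped\n")
})

#' @describeIn NnuocProfile-class flatten to a `data.frame` with columns
#'   `offset`, `mean_nnuoc`, `n`.
#' @export
setMethod("as.data.frame", "NnuocProfile", function(x, ...) {
  data.frame(offset = x@offsets, mean_nnuoc = x@values, n = x@nIRs)
})

#' Write an nNuOc profile as TSV
#' @param x an [NnuocProfile].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNnuocProfile <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Gene ids of convergent gene pairs
#'
#' Convenience filter used by the occupancy analysis: only genes whose
#' 3' neighbor relationship is convergent (a `CON` region lies between them)
#' are kept, because the nucleosome-depleted promoter of a downstream tandem
#' gene would otherwise distort the 3'-UTR occupancy profiles.
#'
#' @param regions a [RegionSet] containing the intergenic regions.
#' @return character vector of gene ids flanking `CON` regions.
#' @export
convergentGenes <- function(regions) {
  con <- regions[as.character(regionKind(regions)) == "CON"]
  unique(unlist(strsplit(mcols(con)$geneId, ",", fixed = TRUE)))
}
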