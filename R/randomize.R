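#' Coding/noncoding segmentation of a genome
#'
#' Builds the segment set used for control-genome randomization: the merged
#' ORF intervals are the coding segments and their per-chromosome complement
#' the noncoding segments. Together the segments tile every chromosome.
#'
#' @param genes gene-model table from [readGeneModels()].
#' @param seqlengths named integer vector of chromosome lengths.
#' @return [GenomicRanges::GRanges] with metadata column `segment`
#'   (`"coding"`/`"noncoding"`), sorted, tiling each chromosome.
#' @export
codingSegments <- function(genes, seqlengths) {
  orf <- GRanges(genes$chrom,
                 IRanges(pmin(genes$start_codon, genes$stop_codon),
                         pmax(genes$start_codon, genes$stop_codon)))
  seqlevels(orf) <- names(seqlengths)
  seqlengths(orf) <- seqlengths
  coding <- reduce(orf)
  noncoding <- gaps(coding)
  noncoding <- noncoding[strand(noncoding) == "*"]
  mcols(coding)$segment <- "coding"
  mcols(noncoding)$segment <- "noncoding"
  sort(c(coding, noncoding), ignore.strand = TRUE)
}

#' Randomize a genome within fixed segments
#'
#' Permutes the bases of each segment independently and uniformly at random
#' (the method of per-segment sequence shuffling). Segment boundaries,
#' lengths and per-segment base composition are conserved exactly, so the
#' genome-wide and per-chromosome AT content is unchanged; annotations carry
#' over unchanged. With `pool = "noncoding"` all noncoding bases of a
#' chromosome are instead shuffled jointly across segments (coding segments
#' remain per-segment), which conserves composition per chromosome but not
#' per noncoding segment.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param segments [GenomicRanges::GRanges] tiling each chromosome (see
#'   [codingSegments()]); an error if a chromosome is not tiled exactly.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param pool `"per_segment"` (default) or `"noncoding"`.
#' @return a [Biostrings::DNAStringSet] of the same shape.
#' @export
randomizeGenome <- function(genome, segments, seed,
                            pool = c("per_segment", "noncoding")) {
  pool <- match.arg(pool)
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  set.seed(as.integer(seed))
  out <- lapply(names(genome), function(chrom) {
    L <- width(genome)[names(genome) == chrom]
    seg <- segments[as.character(seqnames(segments)) == chrom]
    seg <- seg[order(start(seg))]
    if (length(seg) == 0L || sum(width(seg)) != L ||
        any(start(seg)[-1] != head(end(seg), -1) + 1L) ||
        start(seg)[1] != 1L || end(seg)[length(seg)] != L)
      stop("segments do not tile chromosome ", chrom)
    raw <- charToRaw(as.character(genome[[chrom]]))
    segtype <- if (is.null(mcols(seg)$segment)) rep("coding", length(seg))
               else mcols(seg)$segment
    if (pool == "noncoding") {
      nc <- segtype == "noncoding"
      nc_pos <- unlist(lapply(which(nc), function(i) start(seg)[i]:end(seg)[i]),
                       use.names = FALSE)
      perm <- unlist(lapply(which(!nc), function(i) {
        idx <- start(seg)[i]:end(seg)[i]
        idx[sample.int(length(idx))]
      }), use.names = FALSE)
      raw2 <- raw
      if (length(nc_pos)) raw2[nc_pos] <- raw[nc_pos[sample.int(length(nc_pos))]]
      pos <- unlist(lapply(which(!nc), function(i) start(seg)[i]:end(seg)[i]),
                    use.names = FALSE)
      if (length(pos)) raw2[pos] <- raw[perm]
      rawToChar(raw2)
    } else {
      perm <- unlist(lapply(seq_along(seg), function(i) {
        idx <- start(seg)[i]:end(seg)[i]
        idx[sample.int(length(idx))]
      }), use.names = FALSE)
      rawToChar(raw[perm])
    }
  })
  res <- DNAStringSet(unlist(out))
  names(res) <- names(genome)
  res
}
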