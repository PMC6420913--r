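#' Partition the genome into genic and intergenic region classes
#'
#' Emits one region per gene and class:
#'
#' * `UTR5` = `[tss, start_codon)` in transcription orientation (empty when
#'   the TSS coincides with the start codon),
#' * `ORF`  = `[start_codon, stop_codon]` inclusive of both anchor bases,
#' * `UTR3` = `(stop_codon, polya_site]` — excludes the stop codon's third
#'   base and includes the poly(A)-site base,
#'
#' plus one intergenic region between each pair of adjacent clear-ended genes
#' (exclusive of both bounding anchor bases, which belong to the flanking
#' UTRs), labeled by the flanking gene orientations: `TAN` (tandem, same
#' strand), `DIV` (divergent, two TSSs face the region), `CON` (convergent,
#' two poly(A) sites face the region). Where the UTRs of two adjacent
#' clear-ended genes overlap, a single `OUR1`/`OUR2`/`OUR3` region (5'/5',
#' 3'/5', 3'/3' overlap) covering the union of the two overlapping UTRs
#' replaces them, and no intergenic region is emitted for that pair.
#'
#' Genes without clear ends contribute only their ORF and block intergenic
#' construction across their span. Intergenic regions whose span overlaps any
#' `excluded` feature (pseudogenes, tRNA/rRNA genes) are dropped entirely.
#'
#' @param genes gene-model table from [readGeneModels()].
#' @param excluded [GenomicRanges::GRanges] of features whose presence voids
#'   the enclosing intergenic region.
#' @param seqlengths optional named vector of chromosome lengths, attached to
#'   the result.
#' @return a [RegionSet].
#' @export
partitionGenome <- function(genes, excluded = GRanges(), seqlengths = NULL) {
  stopifnot(is.data.frame(genes))
  genes <- .gene_span(genes)

  reg <- list()
  add <- function(chrom, start, end, kind, geneId) {
    keep <- !is.na(start) & !is.na(end) & start <= end
    if (!any(keep)) return()
    reg[[length(reg) + 1L]] <<- data.frame(
      chrom = chrom[keep], start = start[keep], end = end[keep],
      kind = kind[keep], geneId = geneId[keep], stringsAsFactors = FALSE)
  }

  plus <- genes$strand == "+"
  n <- nrow(genes)
  # genic regions; UTRs only for clear-ended genes
  add(genes$chrom,
      pmin(genes$start_codon, genes$stop_codon),
      pmax(genes$start_codon, genes$stop_codon),
      rep("ORF", n), genes$gene_id)
  ce <- genes$clearEnds
  add(genes$chrom[ce],
      ifelse(plus[ce], genes$tss[ce], genes$start_codon[ce] + 1L),
      ifelse(plus[ce], genes$start_codon[ce] - 1L, genes$tss[ce]),
      rep("UTR5", sum(ce)), genes$gene_id[ce])
  add(genes$chrom[ce],
      ifelse(plus[ce], genes$stop_codon[ce] + 1L, genes$polya_site[ce]),
      ifelse(plus[ce], genes$polya_site[ce], genes$stop_codon[ce] - 1L),
      rep("UTR3", sum(ce)), genes$gene_id[ce])
  regions <- do.call(rbind, reg)

  # intergenic and OUR regions from adjacent gene pairs
  inter <- list()
  our_drop <- character()  # "geneId:UTR5"/"geneId:UTR3" regions replaced by OURs
  for (chrom in unique(genes$chrom)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    g <- g[order(g$span_start, g$span_end), , drop = FALSE]
    if (nrow(g) < 2L) next
    for (i in seq_len(nrow(g) - 1L)) {
      left <- g[i, ]; right <- g[i + 1L, ]
      if (!left$clearEnds || !right$clearEnds) next
      # facing UTR kind of each gene: the end that borders the gap
      left_utr <- if (left$strand == "+") "UTR3" else "UTR5"
      right_utr <- if (right$strand == "+") "UTR5" else "UTR3"
      if (left$span_end >= right$span_start) {
        # transcripts overlap: overlapping UTRs collapse into an OUR region
        kind <- if (left_utr == "UTR5" && right_utr == "UTR5") "OUR1"
                else if (left_utr == "UTR3" && right_utr == "UTR3") "OUR3"
                else "OUR2"
        lu <- regions[regions$geneId == left$gene_id &
                        regions$kind == left_utr, , drop = FALSE]
        ru <- regions[regions$geneId == right$gene_id &
                        regions$kind == right_utr, , drop = FALSE]
        if (nrow(lu) && nrow(ru) && lu$end >= ru$start) {
          inter[[length(inter) + 1L]] <- data.frame(
            chrom = chrom, start = min(lu$start, ru$start),
            end = max(lu$end, ru$end), kind = kind,
            geneId = paste(left$gene_id, right$gene_id, sep = ","),
            stringsAsFactors = FALSE)
          our_drop <- c(our_drop, paste(left$gene_id, left_utr, sep = ":"),
                        paste(right$gene_id, right_utr, sep = ":"))
        }
        next
      }
      kind <- if (left$strand == right$strand) "TAN"
              else if (left$strand == "-") "DIV"
              else "CON"
      istart <- left$span_end + 1L
      iend <- right$span_start - 1L
      if (istart > iend) next
      if (length(excluded) &&
          overlapsAny(GRanges(chrom, IRanges(istart, iend)), excluded)) next
      inter[[length(inter) + 1L]] <- data.frame(
        chrom = chrom, start = istart, end = iend, kind = kind,
        geneId = paste(left$gene_id, right$gene_id, sep = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(our_drop))
    regions <- regions[!(paste(regions$geneId, regions$kind, sep = ":") %in%
                           our_drop), , drop = FALSE]
  regions <- rbind(regions, do.call(rbind, inter))

  gr <- GRanges(regions$chrom, IRanges(regions$start, regions$end))
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  mcols(gr)$kind <- factor(regions$kind, levels = .REGION_KINDS)
  mcols(gr)$geneId <- regions$geneId
  sort(new("RegionSet", gr), ignore.strand = TRUE)
}

#' @rdname RegionSet-class
#' @export
setMethod("regionKind", "RegionSet", function(x) mcols(x)$kind)

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet with", length(object), "regions\n")
  if (length(object)) {
    print(table(regionKind(object)))
    callNextMethod()
  }
})

#' Sort regions into equal-count length groups (Q groups)
#'
#' Regions of one kind are sorted by length and split into `k` equal-count
#' groups (any remainder is spread over the shortest groups). The shortest
#' group is discarded and the remaining groups are named `Q1` (shortest
#' retained) through `Q{k-1}`.
#'
#' @param regions a [RegionSet] of a single kind (or anything with
#'   [width()]).
#' @param k number of groups formed before the shortest is discarded.
#' @return list with `groups` (named list of index vectors into `regions`),
#'   `bounds` (`data.frame` of per-group name, `min`, `max` length, `n`) and
#'   `discarded` (index vector of the dropped shortest group).
#' @examples
#' r <- GenomicRanges::GRanges("c", IRanges::IRanges(1, width = seq(10, 100, 10)))
#' lengthGroups(r, k = 5)$bounds
#' @export
lengthGroups <- function(regions, k = 5L) {
  w <- width(regions)
  n <- length(w)
  if (k < 2L) stop("'k' must be >= 2")
  if (n < k) stop("fewer regions (", n, ") than groups (", k, ")")
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  o <- order(w)
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  idx <- lapply(seq_len(k), function(i) o[starts[i]:stops[i]])
  groups <- setNames(idx[-1L], paste0("Q", seq_len(k - 1L)))
  bounds <- data.frame(
    name = names(groups),
    min = vapply(groups, function(i) min(w[i]), numeric(1)),
    max = vapply(groups, function(i) max(w[i]), numeric(1)),
    n = lengths(groups), row.names = NULL)
  list(groups = groups, bounds = bounds, discarded = idx[[1L]])
}
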