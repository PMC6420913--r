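#' Build gene models from an annotation table
#'
#' Each protein-coding gene is described by four anchors: the transcription
#' start site (TSS), the first nucleotide of the start codon, the third
#' nucleotide of the stop codon, and the poly(A) site. All positions are
#' 1-based genomic coordinates (as in the input file). On the `+` strand the
#' anchors must satisfy `tss <= start_codon < stop_codon <= polya_site`; on
#' the `-` strand the genomic order is mirrored
#' (`polya_site <= stop_codon < start_codon <= tss`).
#'
#' Rows with missing TSS and/or poly(A) site are retained but flagged
#' `clearEnds = FALSE`: such genes still contribute their ORF (start/stop are
#' always known) but are excluded from TSS- and poly(A)-anchored profiling
#' and from intergenic-region construction.
#'
#' @param x path to a tab-separated file, or a `data.frame`, with columns
#'   `gene_id`, `chrom`, `strand`, `tss`, `start_codon`, `stop_codon`,
#'   `polya_site` (`tss`/`polya_site` may be `NA`).
#' @return a validated `data.frame` of gene models with the same columns plus
#'   `clearEnds`.
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chrI", strand = "+",
#'                 tss = 101, start_codon = 121, stop_codon = 400,
#'                 polya_site = 470)
#' readGeneModels(g)
#' @export
readGeneModels <- function(x) {
  genes <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else x
  need <- c("gene_id", "chrom", "strand", "tss", "start_codon", "stop_codon",
            "polya_site")
  miss <- setdiff(need, colnames(genes))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  genes <- as.data.frame(genes)[need]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  for (col in c("tss", "start_codon", "stop_codon", "polya_site"))
    genes[[col]] <- suppressWarnings(as.integer(genes[[col]]))

  dup <- duplicated(genes$gene_id)
  if (any(dup))
    stop("duplicate gene id(s): ",
         paste(unique(genes$gene_id[dup]), collapse = ", "))
  bad_strand <- !(genes$strand %in% c("+", "-"))
  malformed <- bad_strand | is.na(genes$start_codon) | is.na(genes$stop_codon) |
    is.na(genes$gene_id) | is.na(genes$chrom)
  if (any(malformed))
    stop("malformed annotation row(s): ",
         paste(which(malformed), collapse = ", "))

  plus <- genes$strand == "+"
  ord_ok <- ifelse(plus,
                   genes$start_codon < genes$stop_codon,
                   genes$stop_codon < genes$start_codon)
  ord_ok <- ord_ok &
    ifelse(is.na(genes$tss), TRUE,
           ifelse(plus, genes$tss <= genes$start_codon,
                  genes$start_codon <= genes$tss)) &
    ifelse(is.na(genes$polya_site), TRUE,
           ifelse(plus, genes$stop_codon <= genes$polya_site,
                  genes$polya_site <= genes$stop_codon))
  if (any(!ord_ok))
    stop("anchor-order violation in annotation row(s): ",
         paste(which(!ord_ok), collapse = ", "))

  genes$clearEnds <- !is.na(genes$tss) & !is.na(genes$polya_site)
  rownames(genes) <- genes$gene_id
  genes
}

#' Signed offset of a genomic position relative to a gene anchor
#'
#' Offsets are measured along the gene's direction of transcription: the
#' anchor base itself is offset 0 and positive offsets lie downstream. On the
#' `+` strand the offset is `pos - anchor`; on the `-` strand it is
#' `anchor - pos`. For a fixed gene and anchor this is a bijection between
#' genomic positions and offsets.
#'
#' @param pos genomic position(s), 1-based.
#' @param anchorKind one of `"tss"`, `"start_codon"`, `"stop_codon"`,
#'   `"polya_site"`.
#' @param gene a one-row gene-model `data.frame` (see [readGeneModels()]), or
#'   a gene-model table with one row per element of `pos`.
#' @return integer offset(s) in bp.
#' @examples
#' g <- readGeneModels(data.frame(gene_id = "g1", chrom = "chrI",
#'   strand = "+", tss = 101, start_codon = 121, stop_codon = 400,
#'   polya_site = 470))
#' relativeOffset(410, "stop_codon", g)   # +10
#' @export
relativeOffset <- function(pos, anchorKind, gene) {
  anchorKind <- match.arg(anchorKind,
                          c("tss", "start_codon", "stop_codon", "polya_site"))
  anchor <- gene[[anchorKind]]
  if (nrow(gene) == 1L) anchor <- rep(anchor, length(pos))
  if (length(anchor) != length(pos))
    stop("'gene' must have one row, or one row per position")
  strand <- if (nrow(gene) == 1L) rep(gene$strand, length(pos)) else gene$strand
  as.integer(ifelse(strand == "+", pos - anchor, anchor - pos))
}

# Genomic span of the transcript (clear-ended genes) or the ORF (others),
# as start/end columns appended to the gene table.
.gene_span <- function(genes) {
  plus <- genes$strand == "+"
  lo_full <- ifelse(plus, genes$tss, genes$polya_site)
  hi_full <- ifelse(plus, genes$polya_site, genes$tss)
  lo_orf <- pmin(genes$start_codon, genes$stop_codon)
  hi_orf <- pmax(genes$start_codon, genes$stop_codon)
  genes$span_start <- ifelse(genes$clearEnds, lo_full, lo_orf)
  genes$span_end <- ifelse(genes$clearEnds, hi_full, hi_orf)
  genes
}
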