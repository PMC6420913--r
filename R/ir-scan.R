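#' Find all maximal perfect inverted repeats in a sequence
#'
#' Scans for perfect (Watson-Crick only, A:T / G:C) inverted repeats whose
#' repeat-unit (arm) length is at least `minArm` bp, whose spacer length is at
#' most `maxSpacer` bp and whose total length `2*armLen + spacerLen` is at
#' least `minTotal` bp. Defaults are the cruciform-competence thresholds
#' R >= 5, S <= 8, 2R + S >= 13. Every reported IR is maximal: extending both
#' arms outward by one base either leaves the sequence or pairs
#' non-complementary bases. IRs strictly contained inside a larger IR are
#' pruned (see [pruneContained()]); overlapping but non-nested IRs are all
#' kept. `N` bases pair with nothing, so arms never cross them.
#'
#' @param x sequence(s) to scan: a named [Biostrings::DNAStringSet], a
#'   [Biostrings::DNAString], or a character vector of sequences (upper or
#'   lower case; folded to upper case). Characters outside `A,C,G,T,N` are an
#'   error.
#' @param chrom chromosome id(s) used when `x` carries no names.
#' @param minArm minimum arm length in bp.
#' @param maxSpacer maximum spacer length in bp.
#' @param minTotal minimum total IR length in bp.
#' @return an [IRSet], sorted by chromosome and start.
#' @examples
#' findMaximalIRs("AAAAAAATTTTTTT")      # one R7S0 IR
#' findMaximalIRs("AAAAAAAAAAAAAAA")     # empty: A pairs only with T
#' @export
findMaximalIRs <- function(x, chrom = NULL, minArm = 5L, maxSpacer = 8L,
                           minTotal = 13L) {
  if (is(x, "DNAString")) x <- DNAStringSet(list(x))
  if (is.character(x)) {
    x <- toupper(x)
    if (any(grepl("[^ACGTN]", x)))
      stop("sequence(s) contain characters outside {A,C,G,T,N}")
    x <- DNAStringSet(x)
  }
  if (!is(x, "DNAStringSet"))
    stop("'x' must be a DNAStringSet, DNAString or character vector")
  if (is.null(names(x))) {
    names(x) <- if (!is.null(chrom)) chrom
                else if (length(x) == 1L) "seq" else paste0("seq", seq_along(x))
  }
  af <- alphabetFrequency(x)
  bad <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(bad > 0))
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(x)[bad > 0], collapse = ", "))

  per_chrom <- lapply(seq_along(x), function(i) {
    s <- as.character(x[[i]])
    cand <- .scan_ir_candidates(s, as.integer(minArm), as.integer(maxSpacer),
                                as.integer(minTotal))
    if (nrow(cand) == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), arm_len = integer(),
                        spacer_len = integer(), leftArm = character()))
    cand$end <- cand$start + 2L * cand$arm_len + cand$spacer_len - 1L
    cand <- .prune_intervals(cand)
    cand$leftArm <- substring(s, cand$start, cand$start + cand$arm_len - 1L)
    cand$chrom <- names(x)[i]
    cand[order(cand$start), c("chrom", "start", "end", "arm_len",
                              "spacer_len", "leftArm")]
  })
  df <- do.call(rbind, per_chrom)
  sl <- setNames(width(x), names(x))
  .IRSet_from_df(df, seqlengths = sl)
}

# Containment pruning on a candidate data.frame with columns
# start, end, arm_len, spacer_len (one chromosome).
.prune_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  # 1) among identical intervals keep max arm_len, then min spacer_len
  o <- order(df$start, df$end, -df$arm_len, df$spacer_len)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[c("start", "end")]), , drop = FALSE]
  # 2) drop proper sub-intervals: sorted by start asc, end desc, a record is
  # contained iff its end does not exceed the running max end of its
  # predecessors
  o2 <- order(df$start, -df$end)
  df <- df[o2, , drop = FALSE]
  prev_max <- c(-Inf, cummax(df$end)[-nrow(df)])
  df[df$end > prev_max, , drop = FALSE]
}

.IRSet_from_df <- function(df, seqlengths = NULL) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  mcols(gr)$armLen <- as.integer(df$arm_len)
  mcols(gr)$spacerLen <- as.integer(df$spacer_len)
  mcols(gr)$center <- start(gr) + (width(gr) - 1L) %/% 2L
  mcols(gr)$leftArm <- as.character(df$leftArm)
  new("IRSet", gr)
}

#' @rdname pruneContained
#' @export
setMethod("pruneContained", "IRSet", function(x) {
  if (length(x) == 0L) return(x)
  keep <- unlist(lapply(split(seq_along(x), as.character(seqnames(x))),
    function(idx) {
      df <- data.frame(i = idx, start = start(x)[idx], end = end(x)[idx],
                       arm_len = armLength(x)[idx],
                       spacer_len = spacerLength(x)[idx])
      .prune_intervals(df)$i
    }), use.names = FALSE)
  sort(x[sort(keep)])
})

#' @rdname pruneContained
#' @export
setMethod("pruneContained", "data.frame", function(x) .prune_intervals(x))

#' @rdname IRSet-class
#' @export
setMethod("armLength", "IRSet", function(x) mcols(x)$armLen)

#' @rdname IRSet-class
#' @export
setMethod("spacerLength", "IRSet", function(x) mcols(x)$spacerLen)

#' @rdname IRSet-class
#' @export
setMethod("irCenter", "IRSet", function(x) mcols(x)$center)

#' @rdname IRSet-class
#' @export
setMethod("leftArm", "IRSet", function(x) mcols(x)$leftArm)

#' @rdname IRSet-class
#' @export
setMethod("irType", "IRSet", function(x) mcols(x)$typeId)

#' R/S name of each IR, e.g. `"R8S4"`
#' @param x an [IRSet]
#' @return character vector of `R{armLen}S{spacerLen}` labels.
#' @export
irName <- function(x) paste0("R", armLength(x), "S", spacerLength(x))

setMethod("show", "IRSet", function(object) {
  cat("IRSet with", length(object), "inverted repeats on",
      length(unique(as.character(seqnames(object)))), "sequence(s)\n")
  if (length(object)) {
    cat("  arm length:", paste(range(armLength(object)), collapse = "-"),
        "bp; spacer:", paste(range(spacerLength(object)), collapse = "-"),
        "bp\n")
    if (!is.null(irType(object)))
      cat("  types:", paste(names(table(irType(object))),
                            table(irType(object)), sep = ":", collapse = " "),
          "\n")
    callNextMethod()
  }
})

#' Write an IRSet to BED6, TSV or GFF3
#'
#' BED output is 0-based half-open with `name = R{arm}S{spacer}`,
#' `score = armLen` and `strand = "."`. The TSV keeps 1-based coordinates and
#' all metadata columns. GFF3 is 1-based inclusive with the same attributes.
#'
#' @param x an [IRSet].
#' @param path output file.
#' @param format `"bed"`, `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
writeIRs <- function(x, path, format = c("bed", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(x)[, c("seqnames", "start", "end", "armLen",
                               "spacerLen", "center", "leftArm",
                               intersect(c("atContent", "tractOcc", "altOcc",
                                           "typeId", "geneId"),
                                         colnames(mcols(x))))]
    names(df)[1] <- "chrom"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gr <- granges(x)
    mcols(gr)$name <- irName(x)
    mcols(gr)$score <- armLength(x)
    if (format == "gff3") {
      mcols(gr)$type <- "inverted_repeat"
      mcols(gr)$armLen <- armLength(x)
      mcols(gr)$spacerLen <- spacerLength(x)
    }
    rtracklayer::export(gr, path,
                        format = if (format == "bed") "BED" else "GFF3")
  }
  invisible(path)
}

#' Read an IRSet back from the TSV written by [writeIRs()]
#' @param path TSV file.
#' @param seqlengths optional named integer vector of chromosome lengths.
#' @return an [IRSet].
#' @export
readIRs <- function(path, seqlengths = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$arm_len <- df$armLen
  df$spacer_len <- df$spacerLen
  x <- .IRSet_from_df(df, seqlengths = seqlengths)
  for (col in intersect(c("atContent", "tractOcc", "altOcc", "typeId",
                          "geneId"), colnames(df)))
    mcols(x)[[col]] <- df[[col]]
  x
}
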