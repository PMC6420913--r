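#' IRSet: a set of detected inverted repeats
#'
#' An `IRSet` extends [GenomicRanges::GRanges]. Each range spans one maximal
#' perfect inverted repeat (both arms plus the spacer), with metadata columns:
#'
#' * `armLen` — repeat-unit (arm) length R in bp,
#' * `spacerLen` — spacer length S in bp,
#' * `center` — 1-based genomic position of the central base,
#'   `start + (width - 1) %/% 2` (for even total length, the left-of-middle
#'   base),
#' * `leftArm` — the 5' arm sequence on the reference strand.
#'
#' After [classifyIRs()] the columns `atContent`, `tractOcc`, `altOcc` and
#' `typeId` are appended.
#'
#' @seealso [findMaximalIRs()], [classifyIRs()]
#' @export
setClass("IRSet", contains = "GRanges")

setValidity("IRSet", function(object) {
  m <- mcols(object)
  need <- c("armLen", "spacerLen", "center", "leftArm")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object) == 0L) return(TRUE)
  if (any(m$armLen < 1L)) return("armLen must be >= 1")
  if (any(m$spacerLen < 0L)) return("spacerLen must be >= 0")
  if (!all(width(object) == 2L * m$armLen + m$spacerLen))
    return("width must equal 2*armLen + spacerLen")
  if (!all(m$center == start(object) + (width(object) - 1L) %/% 2L))
    return("center must be start + (width - 1) %/% 2")
  if (!all(nchar(m$leftArm) == m$armLen))
    return("leftArm length must equal armLen")
  TRUE
})

#' RegionSet: labeled genomic segments from the genome partition
#'
#' A `RegionSet` extends [GenomicRanges::GRanges]. Metadata columns:
#'
#' * `kind` — one of `ORF`, `UTR5`, `UTR3`, `OUR1`, `OUR2`, `OUR3`,
#'   `TAN`, `DIV`, `CON`,
#' * `geneId` — owning gene id (genic kinds) or `leftGene,rightGene`
#'   (intergenic and OUR kinds).
#'
#' @seealso [partitionGenome()]
#' @export
setClass("RegionSet", contains = "GRanges")

.REGION_KINDS <- c("ORF", "UTR5", "UTR3", "OUR1", "OUR2", "OUR3",
                   "TAN", "DIV", "CON")

setValidity("RegionSet", function(object) {
  m <- mcols(object)
  if (!all(c("kind", "geneId") %in% colnames(m)))
    return("RegionSet needs metadata columns 'kind' and 'geneId'")
  if (length(object) && !all(as.character(m$kind) %in% .REGION_KINDS))
    return(paste("kind must be one of:", paste(.REGION_KINDS, collapse = ", ")))
  TRUE
})

#' BinnedProfile: binned positional profile of IR centers with control
#' ensemble and significance calls
#'
#' Holds the per-bin IR-center counts of one region kind profiled relative to
#' one gene anchor, optionally together with the count matrix from the
#' randomized control genomes and the per-bin Grubbs verdicts.
#'
#' @slot regionKind region class profiled (e.g. `"UTR3"`).
#' @slot anchorKind anchor defining offset 0 (`"tss"`, `"start_codon"`,
#'   `"stop_codon"` or `"polya_site"`).
#' @slot binWidth bin width in bp (default 10).
#' @slot binStarts integer vector; offset of the first base of each bin
#'   (bins are `[binStart, binStart + binWidth)` in anchored offsets).
#' @slot counts integer IR-center count per bin in the test genome.
#' @slot nSamples number of region windows contributing.
#' @slot controls integer matrix, bins x control genomes (0 columns when no
#'   controls were run).
#' @slot calls `data.frame` of per-bin Grubbs calls (columns `g`, `direction`,
#'   `pLevel`), zero rows when no controls were run.
#' @slot meta list of run metadata (seeds, thresholds, retention rule).
#' @seealso [binIRCenters()], [profileWithControls()], [grubbsCall()]
#' @export
setClass("BinnedProfile", representation(
  regionKind = "character",
  anchorKind = "character",
  binWidth   = "integer",
  binStarts  = "integer",
  counts     = "integer",
  nSamples   = "integer",
  controls   = "matrix",
  calls      = "data.frame",
  meta       = "list"
))

setValidity("BinnedProfile", function(object) {
  nb <- length(object@binStarts)
  if (length(object@counts) != nb)
    return("counts and binStarts must have equal length")
  if (any(object@counts < 0L)) return("counts must be >= 0")
  if (object@binWidth <= 0L) return("binWidth must be positive")
  if (nb > 1L && !all(diff(object@binStarts) == object@binWidth))
    return("binStarts must advance by binWidth")
  if (ncol(object@controls) > 0L && nrow(object@controls) != nb)
    return("controls must have one row per bin")
  if (nrow(object@calls) > 0L && nrow(object@calls) != nb)
    return("calls must have one row per bin")
  TRUE
})

#' NnuocProfile: average normalized nucleosome occupancy around IR centers
#'
#' Per-offset average of chromosome-normalized binary nucleosome occupancy
#' (nNuOc) in a window centered on IR centers, oriented along the owning
#' gene's direction of transcription.
#'
#' @slot offsets integer offsets (bp) relative to the IR center, `-flank:flank`.
#' @slot values non-negative average nNuOc per offset.
#' @slot nIRs number of IR windows averaged.
#' @slot condition label of the nucleosome-call condition (e.g. `"mnase"`).
#' @slot nSkipped IR windows dropped because they ran off a chromosome end or
#'   lay on a chromosome without calls.
#' @seealso [nnuocProfile()]
#' @export
setClass("NnuocProfile", representation(
  offsets   = "integer",
  values    = "numeric",
  nIRs      = "integer",
  condition = "character",
  nSkipped  = "integer"
))

setValidity("NnuocProfile", function(object) {
  if (length(object@offsets) != length(object@values))
    return("offsets and values must have equal length")
  if (length(object@values) && any(object@values < 0))
    return("nNuOc values must be >= 0")
  TRUE
})

#' SyntheticGenome: a generated genome with annotations, nucleosome calls and
#' ground truth
#'
#' @slot genome [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot genes `data.frame` of gene models (schema of [readGeneModels()]).
#' @slot nucleosomes named list of two [GenomicRanges::GRanges] call sets
#'   (conditions `"mnase"` and `"chemical"`, sharing one depletion layout).
#' @slot truth `data.frame` listing every planted IR (chrom, start, end,
#'   armLen, spacerLen, center, typeId, geneId, anchorKind, offset).
#' @slot depletion [GenomicRanges::GRanges] of realized nucleosome-depletion
#'   windows.
#' @slot config the [synthConfig()] recipe used.
#' @seealso [generateSyntheticGenome()]
#' @export
setClass("SyntheticGenome", representation(
  genome      = "DNAStringSet",
  genes       = "data.frame",
  nucleosomes = "list",
  truth       = "data.frame",
  depletion   = "GRanges",
  config      = "list"
))
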