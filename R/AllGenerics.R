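#' @rdname IRSet-class
#' @param x an object
#' @export
setGeneric("armLength", function(x) standardGeneric("armLength"))

#' @rdname IRSet-class
#' @export
setGeneric("spacerLength", function(x) standardGeneric("spacerLength"))

#' @rdname IRSet-class
#' @export
setGeneric("irCenter", function(x) standardGeneric("irCenter"))

#' @rdname IRSet-class
#' @export
setGeneric("leftArm", function(x) standardGeneric("leftArm"))

#' @rdname IRSet-class
#' @export
setGeneric("irType", function(x) standardGeneric("irType"))

#' @rdname RegionSet-class
#' @param x an object
#' @export
setGeneric("regionKind", function(x) standardGeneric("regionKind"))

#' @rdname BinnedProfile-class
#' @param x an object
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))

#' @rdname BinnedProfile-class
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname BinnedProfile-class
#' @export
setGeneric("controlCounts", function(x) standardGeneric("controlCounts"))

#' @rdname BinnedProfile-class
#' @export
setGeneric("significanceCalls", function(x) standardGeneric("significanceCalls"))

#' Prune inverted repeats contained in larger ones
#'
#' Removes every record whose interval is a proper sub-interval of another
#' record's interval (only the outer IR is kept). Among records with the
#' *same* interval but different arm/spacer decompositions exactly one is
#' kept: the one with the largest arm length, ties broken by the smallest
#' spacer.
#'
#' @param x an [IRSet] (or a candidate `data.frame` with columns `start`,
#'   `end`, `arm_len`, `spacer_len`; used internally).
#' @return an object of the same class with contained records removed.
#' @export
setGeneric("pruneContained", function(x) standardGeneric("pruneContained"))
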