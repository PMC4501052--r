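#' @include AllClasses.R
NULL

#' Accessors for annotation, design and coverage objects
#'
#' \code{precursors} and \code{matureArms} return the annotation GRanges;
#' \code{hairpinSeqs} the hairpin sequences; \code{sampleIds},
#' \code{caseSamples} and \code{controlSamples} the design columns;
#' \code{rawCounts} and \code{rpmCounts} the per-base matrices of one
#' precursor (samples x positions).
#'
#' @param x the object.
#' @param precursor a precursor identifier (for CoverageSet methods).
#' @return The corresponding slot content; matrices have sample rownames.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("precursors", function(x) standardGeneric("precursors"))

#' @rdname accessors
#' @export
setGeneric("matureArms", function(x) standardGeneric("matureArms"))

#' @rdname accessors
#' @export
setGeneric("hairpinSeqs", function(x) standardGeneric("hairpinSeqs"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("caseSamples", function(x) standardGeneric("caseSamples"))

#' @rdname accessors
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @rdname accessors
#' @export
setGeneric("rawCounts", function(x, precursor) standardGeneric("rawCounts"))

#' @rdname accessors
#' @export
setGeneric("rpmCounts", function(x, precursor) standardGeneric("rpmCounts"))
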