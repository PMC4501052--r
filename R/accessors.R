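#' @include AllGenerics.R
NULL

#' Construct a two-group study design
#'
#' @param samples character vector of sample identifiers.
#' @param groups parallel character vector of class labels (exactly two
#'   distinct labels).
#' @param caseLabel label of the case cohort (fold-change numerator). If
#'   missing, the label of the first sample is taken as case.
#' @param controlLabel label of the control cohort; defaults to the other
#'   label.
#' @return A \code{\linkS4class{StudyDesign}}.
#' @export
#' @examples
#' studyDesign(c("a1", "a2", "b1", "b2"),
#'             c("AD", "AD", "ctrl", "ctrl"), caseLabel = "AD")
studyDesign <- function(samples, groups, caseLabel = NULL,
                        controlLabel = NULL) {
    samples <- as.character(samples)
    groups <- as.character(groups)
    if (is.null(caseLabel))
        caseLabel <- groups[1L]
    if (is.null(controlLabel)) {
        other <- setdiff(unique(groups), caseLabel)
        if (length(other) != 1L)
            stop("cannot infer controlLabel: design does not have exactly two groups")
        controlLabel <- other
    }
    new("StudyDesign", samples = samples, groups = groups,
        caseLabel = caseLabel, controlLabel = controlLabel)
}

#' Read a design table (sample <TAB> class, no header)
#'
#' @param path two-column tab-delimited file, one sample per row.
#' @param caseLabel,controlLabel see \code{\link{studyDesign}}.
#' @return A \code{\linkS4class{StudyDesign}}.
#' @export
readDesign <- function(path, caseLabel = NULL, controlLabel = NULL) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "")
    if (ncol(df) != 2L)
        stop("design table must have exactly two columns (sample, class)")
    studyDesign(df[[1L]], df[[2L]], caseLabel, controlLabel)
}

#' Construct a normalization table
#'
#' @param totals named numeric vector of per-sample total read counts
#'   (ignored when \code{mode = "none"}).
#' @param mode "total_run" (totals are raw run read counts),
#'   "genome_mapped" (totals are genome-mapped read counts) or "none".
#' @return A \code{\linkS4class{NormalizationTable}}.
#' @export
normalizationTable <- function(totals = numeric(0),
                               mode = c("total_run", "genome_mapped", "none")) {
    mode <- match.arg(mode)
    new("NormalizationTable", totals = totals, mode = mode)
}

#' Read a totals table (sample <TAB> total reads, no header)
#'
#' @param path two-column tab-delimited file.
#' @param mode see \code{\link{normalizationTable}}.
#' @return A \code{\linkS4class{NormalizationTable}}.
#' @export
readTotals <- function(path, mode = c("total_run", "genome_mapped", "none")) {
    mode <- match.arg(mode)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = c("character", "numeric"),
                            quote = "", comment.char = "")
    if (ncol(df) != 2L)
        stop("totals table must have exactly two columns (sample, total reads)")
    totals <- df[[2L]]
    names(totals) <- df[[1L]]
    normalizationTable(totals, mode)
}

#' Analysis parameter set
#'
#' @param test hypothesis test: "t_test" (Welch) or "wilcoxon".
#' @param alpha significance threshold, default 0.05.
#' @param minSigPositions minimum significant positions for an arm to be
#'   reported differentially regulated, default 15.
#' @param windowSize isomiR window size in bases, default 2.
#' @param graphicsFormat "pdf", "png" or "jpeg".
#' @param aggregate record findings into the aggregation store.
#' @return A \code{\linkS4class{TestConfig}}.
#' @export
testConfig <- function(test = c("t_test", "wilcoxon"), alpha = 0.05,
                       minSigPositions = 15L, windowSize = 2L,
                       graphicsFormat = c("pdf", "png", "jpeg"),
                       aggregate = FALSE) {
    new("TestConfig", test = match.arg(test), alpha = alpha,
        minSigPositions = as.integer(minSigPositions),
        windowSize = as.integer(windowSize),
        graphicsFormat = match.arg(graphicsFormat),
        aggregate = isTRUE(aggregate))
}

## ---- accessor methods -------------------------------------------------

#' @rdname accessors
setMethod("precursors", "HairpinAnnotation", function(x) x@precursors)

#' @rdname accessors
setMethod("matureArms", "HairpinAnnotation", function(x) x@arms)

#' @rdname accessors
setMethod("hairpinSeqs", "HairpinAnnotation", function(x) x@seqs)

#' @rdname accessors
setMethod("precursors", "CoverageSet", function(x) x@annotation@precursors)

#' @rdname accessors
setMethod("matureArms", "CoverageSet", function(x) x@annotation@arms)

#' @rdname accessors
setMethod("sampleIds", "StudyDesign", function(x) x@samples)

#' @rdname accessors
setMethod("sampleIds", "CoverageSet", function(x) x@design@samples)

#' @rdname accessors
setMethod("caseSamples", "StudyDesign",
    function(x) x@samples[x@groups == x@caseLabel])

#' @rdname accessors
setMethod("controlSamples", "StudyDesign",
    function(x) x@samples[x@groups == x@controlLabel])

#' @rdname accessors
setMethod("caseSamples", "CoverageSet", function(x) caseSamples(x@design))

#' @rdname accessors
setMethod("controlSamples", "CoverageSet", function(x) controlSamples(x@design))

#' @rdname accessors
setMethod("rawCounts", "PrecursorCoverage", function(x, precursor) x@raw)

#' @rdname accessors
setMethod("rpmCounts", "PrecursorCoverage", function(x, precursor) {
    if (!length(x@rpm))
        stop("coverage has not been RPM-normalized yet; run normalizeRpm()")
    x@rpm
})

#' @rdname accessors
setMethod("rawCounts", "CoverageSet", function(x, precursor)
    rawCounts(x@coverages[[precursor]]))

#' @rdname accessors
setMethod("rpmCounts", "CoverageSet", function(x, precursor)
    rpmCounts(x@coverages[[precursor]]))

#' @export
setMethod("length", "HairpinAnnotation", function(x) length(x@precursors))

#' @export
setMethod("names", "HairpinAnnotation",
    function(x) mcols(x@precursors)$precursor_id)

#' @export
setMethod("length", "CoverageSet", function(x) length(x@coverages))

#' @export
setMethod("names", "CoverageSet", function(x) names(x@coverages))

#' @export
setMethod("[[", "CoverageSet", function(x, i, j, ...) x@coverages[[i]])

## ---- show methods -----------------------------------------------------

setMethod("show", "HairpinAnnotation", function(object) {
    cat("HairpinAnnotation with", length(object@precursors),
        "precursors and", length(object@arms), "mature arms\n")
    n2 <- sum(table(mcols(object@arms)$precursor_id) == 2L)
    cat("  two-arm precursors:", n2, "\n")
    cat("  hairpin sequences:",
        if (length(object@seqs)) length(object@seqs) else "absent", "\n")
})

setMethod("show", "StudyDesign", function(object) {
    cat("StudyDesign:", length(object@samples), "samples;",
        sum(object@groups == object@caseLabel), object@caseLabel,
        "(case) vs", sum(object@groups == object@controlLabel),
        object@controlLabel, "(control)\n")
})

setMethod("show", "CoverageSet", function(object) {
    cat("CoverageSet with", length(object@coverages), "precursors,",
        length(object@design@samples), "samples;",
        if (object@normalized) "RPM-normalized" else "raw counts only", "\n")
})

setMethod("show", "TestConfig", function(object) {
    cat("TestConfig:", object@test, "alpha =", object@alpha,
        "| minSigPositions =", object@minSigPositions,
        "| windowSize =", object@windowSize, "\n")
})

setMethod("show", "AggregationStore", function(object) {
    cat("AggregationStore at", object@path, "with",
        length(unique(object@records$study_hash)), "studies and",
        nrow(object@records), "findings\n")
})

## ---- small shared helpers --------------------------------------------

## pseudocount added to cohort means before forming fold changes (RPM units)
FC_PSEUDOCOUNT <- 0.01

foldChange <- function(meanCase, meanControl, eps = FC_PSEUDOCOUNT) {
    (meanCase + eps) / (meanControl + eps)
}
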