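#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
NULL

## Central annotation container: hairpin precursors plus their annotated
## mature arms, both as GRanges in genomic coordinates, with optional
## hairpin sequences for pileup / motif rendering.

#' Hairpin precursor annotation
#'
#' Holds miRNA precursor ("hairpin") intervals and their annotated mature
#' arms as \code{GRanges}, plus (optionally) the hairpin sequences.
#' Precursor metadata columns: \code{precursor_id}, \code{name}.
#' Arm metadata columns: \code{mature_id}, \code{name},
#' \code{precursor_id}, \code{arm_label} ("5p" or "3p").
#'
#' @slot precursors GRanges, one range per precursor.
#' @slot arms GRanges, one range per annotated mature arm.
#' @slot seqs DNAStringSet of hairpin sequences named by precursor name
#'   (may be empty; sequence-dependent outputs then degrade gracefully).
#'
#' @seealso \code{\link{readMirbaseGff}}
#' @exportClass HairpinAnnotation
setClass("HairpinAnnotation",
    slots = c(precursors = "GRanges", arms = "GRanges", seqs = "DNAStringSet"))

setValidity("HairpinAnnotation", function(object) {
    p <- object@precursors
    a <- object@arms
    msg <- character()
    need_p <- c("precursor_id", "name")
    if (!all(need_p %in% colnames(mcols(p))))
        msg <- c(msg, "precursor mcols must contain precursor_id, name")
    need_a <- c("mature_id", "name", "precursor_id", "arm_label")
    if (!all(need_a %in% colnames(mcols(a))))
        msg <- c(msg, "arm mcols must contain mature_id, name, precursor_id, arm_label")
    if (length(msg))
        return(msg)
    if (anyDuplicated(mcols(p)$precursor_id))
        msg <- c(msg, "duplicate precursor IDs")
    if (length(a)) {
        idx <- match(mcols(a)$precursor_id, mcols(p)$precursor_id)
        if (anyNA(idx)) {
            msg <- c(msg, "arm with unknown parent precursor")
        } else {
            inside <- start(a) >= start(p)[idx] & end(a) <= end(p)[idx]
            if (!all(inside))
                msg <- c(msg, "mature arm not contained in its precursor")
            if (!all(as.character(strand(a)) == as.character(strand(p))[idx]))
                msg <- c(msg, "mature arm strand differs from precursor strand")
            lab <- mcols(a)$arm_label
            if (!all(lab %in% c("5p", "3p")))
                msg <- c(msg, "arm_label must be '5p' or '3p'")
            if (anyDuplicated(paste(mcols(a)$precursor_id, lab)))
                msg <- c(msg, "more than one arm with the same label on a precursor")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Two-group study design
#'
#' Maps sample identifiers to one of exactly two class labels.
#'
#' @slot samples character vector of sample identifiers (unique).
#' @slot groups character vector of class labels, parallel to samples.
#' @slot caseLabel,controlLabel the two labels; \code{caseLabel} is the
#'   numerator of every fold change.
#' @exportClass StudyDesign
setClass("StudyDesign",
    slots = c(samples = "character", groups = "character",
              caseLabel = "character", controlLabel = "character"))

setValidity("StudyDesign", function(object) {
    msg <- character()
    if (length(object@samples) != length(object@groups))
        msg <- c(msg, "samples and groups differ in length")
    if (anyDuplicated(object@samples))
        msg <- c(msg, "duplicated sample identifiers")
    labs <- unique(object@groups)
    if (length(labs) != 2L)
        msg <- c(msg, "design must contain exactly two distinct group labels")
    if (length(object@caseLabel) != 1L || length(object@controlLabel) != 1L)
        msg <- c(msg, "caseLabel and controlLabel must be single strings")
    else {
        if (!all(c(object@caseLabel, object@controlLabel) %in% object@groups))
            msg <- c(msg, "case/control labels absent from groups")
        if (object@caseLabel == object@controlLabel)
            msg <- c(msg, "caseLabel equals controlLabel")
    }
    if (length(msg)) msg else TRUE
})

#' Per-sample totals used for reads-per-million normalization
#'
#' @slot totals named numeric vector of positive per-sample total read
#'   counts (either raw run totals or genome-mapped totals).
#' @slot mode one of "total_run", "genome_mapped", "none".
#' @exportClass NormalizationTable
setClass("NormalizationTable",
    slots = c(totals = "numeric", mode = "character"))

setValidity("NormalizationTable", function(object) {
    msg <- character()
    if (!object@mode %in% c("total_run", "genome_mapped", "none"))
        msg <- c(msg, "mode must be total_run, genome_mapped or none")
    if (object@mode != "none") {
        if (is.null(names(object@totals)) || anyDuplicated(names(object@totals)))
            msg <- c(msg, "totals must be uniquely named by sample")
        if (any(!is.finite(object@totals)) || any(object@totals <= 0))
            msg <- c(msg, "totals must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' Per-precursor coverage matrices
#'
#' Raw and RPM-normalized per-base read coverage for one precursor,
#' samples in rows (rownames) and precursor positions 1..L in columns.
#'
#' @slot precursorId precursor identifier.
#' @slot raw integer matrix of per-base read counts.
#' @slot rpm numeric matrix of reads-per-million values; empty (0 x 0)
#'   until \code{\link{normalizeRpm}} has been run.
#' @exportClass PrecursorCoverage
setClass("PrecursorCoverage",
    slots = c(precursorId = "character", raw = "matrix", rpm = "matrix"))

setValidity("PrecursorCoverage", function(object) {
    msg <- character()
    if (length(object@precursorId) != 1L)
        msg <- c(msg, "precursorId must be a single string")
    if (is.null(rownames(object@raw)))
        msg <- c(msg, "raw matrix must have sample rownames")
    if (any(object@raw < 0))
        msg <- c(msg, "raw counts must be non-negative")
    if (length(object@rpm)) {
        if (!identical(dim(object@rpm), dim(object@raw)))
            msg <- c(msg, "rpm and raw must have identical shape")
        if (any(object@rpm < 0))
            msg <- c(msg, "rpm values must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' A full study's coverage: one PrecursorCoverage per precursor
#'
#' @slot coverages named list of \code{PrecursorCoverage}, all sharing the
#'   same sample ordering.
#' @slot design StudyDesign.
#' @slot normalization NormalizationTable.
#' @slot annotation HairpinAnnotation the coverage was built against.
#' @slot normalized logical; TRUE once RPM matrices are filled.
#' @exportClass CoverageSet
setClass("CoverageSet",
    slots = c(coverages = "list", design = "StudyDesign",
              normalization = "NormalizationTable",
              annotation = "HairpinAnnotation", normalized = "logical"))

setValidity("CoverageSet", function(object) {
    msg <- character()
    if (!all(vapply(object@coverages, is, TRUE, class2 = "PrecursorCoverage")))
        msg <- c(msg, "coverages must all be PrecursorCoverage")
    if (length(object@coverages)) {
        sam <- rownames(object@coverages[[1L]]@raw)
        same <- vapply(object@coverages,
                       function(x) identical(rownames(x@raw), sam), TRUE)
        if (!all(same))
            msg <- c(msg, "all coverages must share the same sample ordering")
        if (!identical(sam, object@design@samples))
            msg <- c(msg, "coverage sample ordering must match the design")
    }
    if (length(msg)) msg else TRUE
})

#' Analysis parameters
#'
#' @slot test "t_test" (Welch) or "wilcoxon" (Mann-Whitney rank sum).
#' @slot alpha per-position/per-feature significance threshold.
#' @slot minSigPositions minimum number of significant positions for a
#'   mature arm to be flagged differentially regulated (default 15).
#' @slot windowSize isomiR window size in bases (1-10, default 2;
#'   2-4 is the typical working range).
#' @slot graphicsFormat "pdf", "png" or "jpeg".
#' @slot aggregate opt-in to the cross-study aggregation store.
#' @exportClass TestConfig
setClass("TestConfig",
    slots = c(test = "character", alpha = "numeric",
              minSigPositions = "integer", windowSize = "integer",
              graphicsFormat = "character", aggregate = "logical"))

setValidity("TestConfig", function(object) {
    msg <- character()
    if (!object@test %in% c("t_test", "wilcoxon"))
        msg <- c(msg, "test must be 't_test' or 'wilcoxon'")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must lie strictly between 0 and 1")
    if (object@minSigPositions < 1L)
        msg <- c(msg, "minSigPositions must be positive")
    if (object@windowSize < 1L || object@windowSize > 10L)
        msg <- c(msg, "windowSize must be between 1 and 10")
    if (!object@graphicsFormat %in% c("pdf", "png", "jpeg"))
        msg <- c(msg, "graphicsFormat must be pdf, png or jpeg")
    if (length(msg)) msg else TRUE
})

#' Local cross-study aggregation store
#'
#' Append-only, anonymized record of study-level findings backed by a
#' plain-text file. Columns: study_hash, finding_type, mirna_key,
#' direction, significant. No sample-level data are ever stored.
#'
#' @slot path file backing the store.
#' @slot records data.frame of all recorded findings.
#' @exportClass AggregationStore
setClass("AggregationStore",
    slots = c(path = "character", records = "data.frame"))

setValidity("AggregationStore", function(object) {
    need <- c("study_hash", "finding_type", "mirna_key", "direction",
              "significant")
    if (!identical(colnames(object@records), need))
        return("store records must have columns study_hash, finding_type, mirna_key, direction, significant")
    ok_type <- object@records$finding_type %in%
        c("novel_arm", "isomir_window", "significant_precursor",
          "significant_mature")
    if (!all(ok_type))
        return("unknown finding_type in store")
    if (any(!nzchar(object@records$mirna_key)))
        return("mirna_key must be non-empty")
    TRUE
})
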