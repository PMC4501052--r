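#' Build per-precursor, per-sample, per-base coverage
#'
#' Tallies, for every precursor position, the number of alignments of
#' each sample covering that base. Alignments on the strand opposite the
#' precursor are ignored; alignments that only partially overlap a
#' precursor contribute their overlapping bases; an alignment overlapping
#' several precursors contributes to each of them.
#'
#' @param recordsBySample named list (sample id -> data.frame from
#'   \code{\link{readArf}}).
#' @param annotation a \code{\linkS4class{HairpinAnnotation}}.
#' @param design a \code{\linkS4class{StudyDesign}}; every sample in
#'   \code{recordsBySample} must appear in it. Design samples without
#'   records get an all-zero row with a warning.
#' @return A \code{\linkS4class{CoverageSet}} with raw counts only
#'   (normalization mode "none" until \code{\link{normalizeRpm}}).
#' @export
buildCoverage <- function(recordsBySample, annotation, design) {
    samples <- sampleIds(design)
    extra <- setdiff(names(recordsBySample), samples)
    if (length(extra))
        stop("samples absent from design: ", paste(extra, collapse = ", "))
    missing <- setdiff(samples, names(recordsBySample))
    if (length(missing))
        warning("design sample(s) without alignment records, using zero coverage: ",
                paste(missing, collapse = ", "))

    grl <- lapply(samples, function(s) {
        rec <- recordsBySample[[s]]
        if (is.null(rec) || !nrow(rec))
            return(GRanges())
        arfToGRanges(rec, sample = s)
    })
    aln <- do.call(c, grl)
    alnSample <- if (length(aln)) mcols(aln)$sample else character(0)

    prec <- annotation@precursors
    covs <- vector("list", length(prec))
    hits <- GenomicRanges::findOverlaps(aln, prec)  # strand-aware
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (i in seq_along(prec)) {
        L <- end(prec)[i] - start(prec)[i] + 1L
        raw <- matrix(0L, nrow = length(samples), ncol = L,
                      dimnames = list(samples, NULL))
        sel <- qh[sh == i]
        if (length(sel)) {
            rel <- mapToPrecursor(start(aln)[sel], end(aln)[sel],
                                  start(prec)[i], end(prec)[i],
                                  as.character(strand(prec))[i])
            bySample <- split(seq_along(sel), alnSample[sel])
            for (s in names(bySample)) {
                j <- bySample[[s]]
                rle <- IRanges::coverage(
                    IRanges(rel[j, "start"], rel[j, "end"]), width = L)
                raw[s, ] <- as.integer(rle)
            }
        }
        covs[[i]] <- new("PrecursorCoverage",
                         precursorId = mcols(prec)$precursor_id[i],
                         raw = raw,
                         rpm = matrix(numeric(0), 0, 0))
    }
    names(covs) <- mcols(prec)$precursor_id
    new("CoverageSet", coverages = covs, design = design,
        normalization = normalizationTable(mode = "none"),
        annotation = annotation, normalized = FALSE)
}

#' Normalize coverage to reads per million
#'
#' Fills the RPM matrices: \code{rpm[s, p] = raw[s, p] * 1e6 /
#' total_reads[s]}. With mode "none" the raw counts are copied
#' unchanged.
#'
#' @param cov a \code{\linkS4class{CoverageSet}}.
#' @param table a \code{\linkS4class{NormalizationTable}}; with mode
#'   other than "none" it must provide a positive total for every design
#'   sample.
#' @return The \code{CoverageSet} with RPM matrices filled.
#' @export
normalizeRpm <- function(cov, table) {
    samples <- sampleIds(cov)
    if (table@mode == "none") {
        fac <- rep(1, length(samples))
    } else {
        totals <- table@totals[samples]
        if (anyNA(totals))
            stop("normalization totals missing for sample(s): ",
                 paste(samples[is.na(totals)], collapse = ", "))
        if (any(totals <= 0))
            stop("normalization totals must be positive")
        fac <- 1e6 / totals
    }
    cov@coverages <- lapply(cov@coverages, function(pc) {
        pc@rpm <- pc@raw * fac
        rownames(pc@rpm) <- rownames(pc@raw)
        pc
    })
    cov@normalization <- table
    cov@normalized <- TRUE
    validObject(cov)
    cov
}

#' Export per-precursor coverage matrices as TSV
#'
#' One tab-delimited file per precursor (positions as columns, samples as
#' rows), raw counts and, when available, RPM values.
#'
#' @param cov a \code{\linkS4class{CoverageSet}}.
#' @param dir output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
exportCoverage <- function(cov, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (id in names(cov)) {
        pc <- cov[[id]]
        p <- file.path(dir, paste0("coverage_raw_", id, ".tsv"))
        writeMatrixTsv(pc@raw, p)
        paths <- c(paths, p)
        if (length(pc@rpm)) {
            p <- file.path(dir, paste0("coverage_rpm_", id, ".tsv"))
            writeMatrixTsv(pc@rpm, p)
            paths <- c(paths, p)
        }
    }
    invisible(paths)
}

writeMatrixTsv <- function(m, path) {
    df <- data.frame(sample = rownames(m), m, check.names = FALSE)
    colnames(df) <- c("sample", paste0("pos_", seq_len(ncol(m))))
    writeTsv(df, path)
}
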