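## Local, anonymized cross-study store: which miRNA-level findings were
## seen in how many independently analyzed studies. Backed by a plain
## append-only tab-delimited file with a versioned header. Only
## study-level findings (miRNA key, finding type, direction, significant
## flag) are stored: no sample identifiers, group labels or per-sample
## values ever reach the file.

STORE_HEADER <- "#isomiRscope-aggregation\tv1"
STORE_COLUMNS <- c("study_hash", "finding_type", "mirna_key", "direction",
                   "significant")

emptyStoreRecords <- function() {
    data.frame(study_hash = character(0), finding_type = character(0),
               mirna_key = character(0), direction = character(0),
               significant = logical(0), stringsAsFactors = FALSE)
}

#' Open (or create) an aggregation store
#'
#' @param path backing file; created with a versioned header if absent.
#' @return An \code{\linkS4class{AggregationStore}}.
#' @export
openStore <- function(path) {
    if (!file.exists(path)) {
        writeLines(STORE_HEADER, path)
        return(new("AggregationStore", path = path,
                   records = emptyStoreRecords()))
    }
    lines <- readLines(path)
    if (!length(lines) || lines[1L] != STORE_HEADER)
        stop("not an aggregation store (missing version header): ", path)
    lines <- lines[-1L]
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(new("AggregationStore", path = path,
                   records = emptyStoreRecords()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 5L))
        stop("corrupt aggregation store line in ", path)
    m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
    rec <- data.frame(study_hash = m[, 1L], finding_type = m[, 2L],
                      mirna_key = m[, 3L], direction = m[, 4L],
                      significant = m[, 5L] == "1",
                      stringsAsFactors = FALSE)
    new("AggregationStore", path = path, records = rec)
}

#' Record a study's findings in the aggregation store
#'
#' Appends one study's anonymized findings under an opaque study hash.
#' The hash is an idempotency key: recording the same hash twice is
#' rejected so repeated submissions never double-count.
#'
#' @param store an \code{\linkS4class{AggregationStore}}.
#' @param studyHash opaque study identifier (e.g. from
#'   \code{\link{studyHash}}).
#' @param findings data.frame with columns finding_type (one of
#'   "novel_arm", "isomir_window", "significant_precursor",
#'   "significant_mature"), mirna_key, direction ("up", "down", "none")
#'   and significant (logical). Non-significant rows matter too: they
#'   define in how many studies a miRNA was analyzed at all.
#' @return The updated store (also persisted to its backing file).
#' @export
recordStudy <- function(store, studyHash, findings) {
    stopifnot(is(store, "AggregationStore"))
    if (studyHash %in% store@records$study_hash)
        stop("study hash already recorded, refusing to double-count: ",
             studyHash)
    findings <- as.data.frame(findings)
    need <- c("finding_type", "mirna_key", "direction", "significant")
    if (!all(need %in% colnames(findings)))
        stop("findings must have columns ", paste(need, collapse = ", "))
    rec <- data.frame(study_hash = rep(studyHash, nrow(findings)),
                      finding_type = as.character(findings$finding_type),
                      mirna_key = as.character(findings$mirna_key),
                      direction = as.character(findings$direction),
                      significant = as.logical(findings$significant),
                      stringsAsFactors = FALSE)
    store@records <- rbind(store@records, rec)
    validObject(store)
    lines <- sprintf("%s\t%s\t%s\t%s\t%d", rec$study_hash, rec$finding_type,
                     rec$mirna_key, rec$direction, as.integer(rec$significant))
    con <- file(store@path, open = "a")
    on.exit(close(con))
    writeLines(lines, con)
    store
}

#' How often was a finding seen across studies?
#'
#' @param store an \code{\linkS4class{AggregationStore}}.
#' @param mirnaKey precursor or mature miRNA name.
#' @param findingType one of the recorded finding types.
#' @return list(mirna_key, finding_type, n_experiments, n_with_finding):
#'   the number of recorded studies in which the miRNA was analyzed for
#'   this finding type, and in how many of them the finding was
#'   significant. Unknown keys give (0, 0). A high
#'   n_with_finding/n_experiments fraction flags a probable recurrent
#'   platform artifact rather than a trait-specific signal.
#' @export
queryFrequency <- function(store, mirnaKey, findingType) {
    rec <- store@records
    sel <- rec$mirna_key == mirnaKey & rec$finding_type == findingType
    list(mirna_key = mirnaKey, finding_type = findingType,
         n_experiments = length(unique(rec$study_hash[sel])),
         n_with_finding = length(unique(rec$study_hash[sel & rec$significant])))
}

#' Export / import an aggregation store
#'
#' \code{exportStore} copies the backing file; \code{importStore} merges
#' another store file into this one, skipping study hashes already
#' present.
#'
#' @param store an \code{\linkS4class{AggregationStore}}.
#' @param path file to export to / import from.
#' @return \code{exportStore}: the path, invisibly. \code{importStore}:
#'   the updated store.
#' @export
exportStore <- function(store, path) {
    file.copy(store@path, path, overwrite = TRUE)
    invisible(path)
}

#' @rdname exportStore
#' @export
importStore <- function(store, path) {
    other <- openStore(path)
    for (h in setdiff(unique(other@records$study_hash),
                      unique(store@records$study_hash))) {
        rows <- other@records[other@records$study_hash == h, ]
        store <- recordStudy(store, h, rows[, -1L])
    }
    store
}

#' Opaque study hash from the run parameters file
#'
#' @param paramsFile the machine-readable parameter echo of a run (any
#'   file uniquely describing the study inputs).
#' @return md5 digest string.
#' @export
studyHash <- function(paramsFile) {
    unname(tools::md5sum(paramsFile))
}

## a window finding is recorded significant when the cohorts differ by at
## least this many percentage points of window coverage
WINDOW_FINDING_MIN_DIFF <- 20

#' Collect anonymized findings from analysis results
#'
#' Builds the findings table handed to \code{\link{recordStudy}}:
#' precursor and mature features analyzed (nonzero coverage in at least
#' one sample), flagged significant at \code{cfg@alpha}; novel-arm calls
#' (all single-arm precursors analyzed, calls significant at alpha); and
#' window findings (significant when the cohort percentages differ by at
#' least 20 points).
#'
#' @param precursorResults,matureResults expression \code{DataFrame}s.
#' @param novelArms \code{DataFrame} from \code{\link{novelArmScan}}.
#' @param windows \code{DataFrame} from \code{\link{windowAnalysis}}.
#' @param cov the \code{\linkS4class{CoverageSet}} (defines which
#'   single-arm precursors were analyzed for novel arms).
#' @param cfg a \code{\linkS4class{TestConfig}}.
#' @return data.frame with columns finding_type, mirna_key, direction,
#'   significant.
#' @export
collectFindings <- function(precursorResults, matureResults, novelArms,
                            windows, cov, cfg = testConfig()) {
    dirOf <- function(fc) ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))
    precIds <- mcols(cov@annotation@precursors)$precursor_id
    precNames <- mcols(cov@annotation@precursors)$name
    rows <- list()
    if (nrow(precursorResults)) {
        nm <- precNames[match(precursorResults$feature_id, precIds)]
        nm[is.na(nm)] <- precursorResults$feature_id[is.na(nm)]
        rows$prec <- data.frame(
            finding_type = "significant_precursor", mirna_key = nm,
            direction = dirOf(precursorResults$fold_change),
            significant = precursorResults$p_value < cfg@alpha)
    }
    if (nrow(matureResults))
        rows$mat <- data.frame(
            finding_type = "significant_mature",
            mirna_key = matureResults$feature_id,
            direction = dirOf(matureResults$fold_change),
            significant = matureResults$p_value < cfg@alpha)
    rel <- armRelativeCoords(cov@annotation)
    single <- names(which(table(rel$precursor_id) == 1L))
    analyzed <- single[vapply(single, function(id)
        !is.null(cov@coverages[[id]]) && any(cov@coverages[[id]]@raw > 0), TRUE)]
    if (length(analyzed)) {
        nm <- precNames[match(analyzed, precIds)]
        called <- analyzed %in% novelArms$precursor_id
        fc <- novelArms$fold_change[match(analyzed, novelArms$precursor_id)]
        pv <- novelArms$p_value[match(analyzed, novelArms$precursor_id)]
        rows$novel <- data.frame(
            finding_type = "novel_arm", mirna_key = nm,
            direction = ifelse(called, dirOf(fc), "none"),
            significant = called & pv < cfg@alpha)
        rows$novel$significant[is.na(rows$novel$significant)] <- FALSE
    }
    if (!is.null(windows) && nrow(windows))
        rows$win <- data.frame(
            finding_type = "isomir_window", mirna_key = windows$name,
            direction = ifelse(windows$difference > 0, "up",
                               ifelse(windows$difference < 0, "down", "none")),
            significant = abs(windows$difference) >= WINDOW_FINDING_MIN_DIFF)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
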