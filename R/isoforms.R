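## isomiR window analysis at mature-arm ends and detection of candidate
## unannotated mature arms on single-arm precursors.

## detect_novel_arm parameters: exclusion zone around the annotated arm,
## required pooled mean coverage, and the plausible mature-arm length
NOVEL_GUARD_NT <- 5L
NOVEL_MIN_MEAN_READS <- 1
NOVEL_LEN_RANGE <- c(16L, 30L)

## window positions (precursor-relative) immediately outside an arm end;
## relStart/relEnd are the arm's precursor-relative coordinates
windowPositions <- function(relStart, relEnd, end = c("five_prime", "three_prime"),
                            w, L) {
    end <- match.arg(end)
    if (w < 1L)
        stop("window size w must be >= 1")
    win <- if (end == "five_prime") (relStart - w):(relStart - 1L)
           else (relEnd + 1L):(relEnd + w)
    win[win >= 1L & win <= L]
}

#' Cohort window-coverage percentages outside a mature-arm end
#'
#' The window is the \code{w} precursor positions immediately outside
#' the given end of the arm (towards the precursor 5' end for
#' \code{"five_prime"}, towards its 3' end for \code{"three_prime"}).
#' A (sample, position) cell counts as covered when the raw read count
#' is at least 1; the cohort percentage is 100 times the cohort mean of
#' per-sample covered-position fractions. At \code{w = 1} this reduces
#' to the percentage of samples with any read at the window base.
#'
#' @param pc a \code{\linkS4class{PrecursorCoverage}}.
#' @param relStart,relEnd precursor-relative arm coordinates.
#' @param end "five_prime" or "three_prime" (ends in precursor
#'   orientation).
#' @param w window size in bases (>= 1).
#' @param design a \code{\linkS4class{StudyDesign}}.
#' @return named numeric \code{c(pct_case, pct_control)}, or NULL when
#'   the window lies entirely outside the precursor.
#' @export
windowCoverage <- function(pc, relStart, relEnd,
                           end = c("five_prime", "three_prime"), w, design) {
    end <- match.arg(end)
    L <- ncol(pc@raw)
    win <- windowPositions(relStart, relEnd, end, w, L)
    if (!length(win))
        return(NULL)
    covered <- pc@raw[, win, drop = FALSE] >= 1L
    frac <- rowMeans(covered)
    c(pct_case = 100 * mean(frac[caseSamples(design)]),
      pct_control = 100 * mean(frac[controlSamples(design)]))
}

#' Case/control quotient of window percentages
#'
#' @param pctCase,pctControl cohort window-coverage percentages.
#' @return \code{pctCase / pctControl}, unrounded; \code{NA} when
#'   \code{pctControl} is 0 (reported as not available downstream).
#' @export
#' @examples
#' windowQuotient(31.5, 68.1)  # ~0.46
windowQuotient <- function(pctCase, pctControl) {
    ifelse(pctControl > 0, pctCase / pctControl, NA_real_)
}

#' Precursor bases just outside an arm end (the window motif)
#'
#' @param seq hairpin sequence (character or XString), 5'->3' in
#'   precursor orientation.
#' @param relStart,relEnd precursor-relative arm coordinates.
#' @param end "five_prime" or "three_prime".
#' @param w window size (>= 1).
#' @return the \code{w} bases immediately outside the arm end, 5'->3' in
#'   precursor orientation, truncated at the precursor boundary (possibly
#'   empty); \code{NA} when no sequence is available.
#' @export
#' @examples
#' endMotif("AACCGGTT", 3, 6, "three_prime", 2)  # "TT"
endMotif <- function(seq, relStart, relEnd,
                     end = c("five_prime", "three_prime"), w) {
    end <- match.arg(end)
    if (w < 1L)
        stop("window size w must be >= 1")
    if (is.null(seq) || (is.character(seq) && (!length(seq) || is.na(seq))))
        return(NA_character_)
    seq <- as.character(seq)
    win <- windowPositions(relStart, relEnd, end, w, nchar(seq))
    if (!length(win))
        return("")
    paste(strsplit(seq, "")[[1L]][win], collapse = "")
}

#' Window analysis across all annotated arms
#'
#' For every annotated mature arm and both of its ends, computes the
#' cohort window-coverage percentages, their difference and case/control
#' quotient, plus the end motif when the hairpin sequence is known. Two-
#' arm precursors thus contribute four percentages per cohort, single-arm
#' precursors two, as many as their ends allow.
#'
#' @param cov a \code{\linkS4class{CoverageSet}}.
#' @param cfg a \code{\linkS4class{TestConfig}} (supplies the default
#'   window size).
#' @param w window size override (defaults to \code{cfg@windowSize}).
#' @return \code{DataFrame}: mature_id, name, precursor_id, arm_label,
#'   end, window_size, pct_case, pct_control, difference, quotient,
#'   motif. Windows falling entirely outside the precursor are dropped.
#' @export
windowAnalysis <- function(cov, cfg = testConfig(), w = cfg@windowSize) {
    rel <- armRelativeCoords(cov@annotation)
    seqs <- cov@annotation@seqs
    precNames <- mcols(cov@annotation@precursors)$name
    precIds <- mcols(cov@annotation@precursors)$precursor_id
    rows <- list()
    for (i in seq_len(nrow(rel))) {
        pc <- cov@coverages[[rel$precursor_id[i]]]
        if (is.null(pc)) next
        pn <- precNames[match(rel$precursor_id[i], precIds)]
        seq <- if (length(seqs) && pn %in% names(seqs))
            as.character(seqs[[pn]]) else NA_character_
        for (endType in c("five_prime", "three_prime")) {
            pct <- windowCoverage(pc, rel$rel_start[i], rel$rel_end[i],
                                  endType, w, cov@design)
            if (is.null(pct)) next
            rows[[length(rows) + 1L]] <- DataFrame(
                mature_id = rel$mature_id[i], name = rel$name[i],
                precursor_id = rel$precursor_id[i],
                arm_label = rel$arm_label[i], end = endType,
                window_size = as.integer(w),
                pct_case = unname(pct["pct_case"]),
                pct_control = unname(pct["pct_control"]),
                difference = unname(pct["pct_case"] - pct["pct_control"]),
                quotient = windowQuotient(unname(pct["pct_case"]),
                                          unname(pct["pct_control"])),
                motif = endMotif(seq, rel$rel_start[i], rel$rel_end[i],
                                 endType, w))
        }
    }
    if (!length(rows))
        return(DataFrame(mature_id = character(0), name = character(0),
                         precursor_id = character(0),
                         arm_label = character(0), end = character(0),
                         window_size = integer(0), pct_case = numeric(0),
                         pct_control = numeric(0), difference = numeric(0),
                         quotient = numeric(0), motif = character(0)))
    do.call(rbind, rows)
}

#' Detect a candidate unannotated mature arm on a single-arm precursor
#'
#' Searches the precursor region outside the annotated arm (plus a 5 nt
#' guard band on both sides of it) for the maximal contiguous run of
#' positions whose pooled (all-sample) mean raw coverage is at least 1
#' read. A run of 16-30 nt is reported as a candidate novel arm with its
#' mean read count, case/control fold change and p-value on the
#' per-sample mean RPM over the region.
#'
#' @param pc a \code{\linkS4class{PrecursorCoverage}}.
#' @param relStart,relEnd precursor-relative coordinates of the single
#'   annotated arm.
#' @param design a \code{\linkS4class{StudyDesign}}.
#' @param cfg a \code{\linkS4class{TestConfig}}.
#' @return list(region_start, region_end, length, mean_reads,
#'   fold_change, p_value) or NULL when no qualifying region exists.
#' @export
detectNovelArm <- function(pc, relStart, relEnd, design, cfg = testConfig()) {
    L <- ncol(pc@raw)
    pooled <- colMeans(pc@raw)
    allowed <- rep(TRUE, L)
    guard <- max(1L, relStart - NOVEL_GUARD_NT):min(L, relEnd + NOVEL_GUARD_NT)
    allowed[guard] <- FALSE
    ok <- allowed & pooled >= NOVEL_MIN_MEAN_READS
    if (!any(ok))
        return(NULL)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    # maximal run; ties broken towards higher pooled coverage
    lens <- r$lengths[runs]
    best <- runs[order(-lens, -vapply(runs, function(i)
        mean(pooled[starts[i]:ends[i]]), 0))][1L]
    rs <- starts[best]; re <- ends[best]
    len <- re - rs + 1L
    if (len < NOVEL_LEN_RANGE[1L] || len > NOVEL_LEN_RANGE[2L])
        return(NULL)
    region <- rs:re
    if (!length(pc@rpm))
        stop("coverage must be RPM-normalized before novel-arm detection")
    v <- rowMeans(pc@rpm[, region, drop = FALSE])
    cs <- caseSamples(design)
    ct <- controlSamples(design)
    res <- twoGroupTest(v[cs], v[ct], cfg@test)
    list(region_start = rs, region_end = re, length = len,
         mean_reads = mean(pc@raw[, region]),
         fold_change = foldChange(mean(v[cs]), mean(v[ct])),
         p_value = res$p_value)
}

#' Scan all single-arm precursors for candidate novel arms
#'
#' Applies \code{\link{detectNovelArm}} to every precursor with exactly
#' one annotated mature arm (two-arm precursors are skipped by the
#' precondition of the operation).
#'
#' @param cov an RPM-normalized \code{\linkS4class{CoverageSet}}.
#' @param cfg a \code{\linkS4class{TestConfig}}.
#' @return \code{DataFrame}: precursor_id, precursor_name,
#'   annotated_arm, region_start, region_end, length, mean_reads,
#'   fold_change, p_value; zero rows when nothing is called.
#' @export
novelArmScan <- function(cov, cfg = testConfig()) {
    rel <- armRelativeCoords(cov@annotation)
    tab <- table(rel$precursor_id)
    single <- names(tab)[tab == 1L]
    precNames <- mcols(cov@annotation@precursors)$name
    precIds <- mcols(cov@annotation@precursors)$precursor_id
    rows <- list()
    for (id in single) {
        pc <- cov@coverages[[id]]
        if (is.null(pc)) next
        a <- rel[rel$precursor_id == id, ]
        call <- detectNovelArm(pc, a$rel_start, a$rel_end, cov@design, cfg)
        if (is.null(call)) next
        rows[[length(rows) + 1L]] <- DataFrame(
            precursor_id = id,
            precursor_name = precNames[match(id, precIds)],
            annotated_arm = a$arm_label,
            region_start = call$region_start, region_end = call$region_end,
            length = call$length, mean_reads = call$mean_reads,
            fold_change = call$fold_change, p_value = call$p_value)
    }
    if (!length(rows))
        return(DataFrame(precursor_id = character(0),
                         precursor_name = character(0),
                         annotated_arm = character(0),
                         region_start = integer(0), region_end = integer(0),
                         length = integer(0), mean_reads = numeric(0),
                         fold_change = numeric(0), p_value = numeric(0)))
    do.call(rbind, rows)
}
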