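## Hypothesis testing at precursor, mature-arm, arm-ratio and single-base
## resolution. The per-sample statistic everywhere is the mean per-base
## RPM coverage over the feature's positions; fold changes are formed
## from cohort means with a 0.01 RPM pseudocount on both sides.

## exact permutation enumeration is used while the number of group
## assignments stays below this bound (covers both groups <= 8)
WILCOXON_EXACT_MAX <- 20000

#' Two-sided two-group test
#'
#' Compares two cohorts of per-sample values with either a Welch
#' (unequal-variance) t test or a Wilcoxon Mann-Whitney rank-sum test.
#' The Wilcoxon path is an exact two-sided permutation enumeration of
#' the rank-sum statistic (midranks, hence exact under ties) whenever
#' \code{choose(n, n1) <= 20000}; for larger cohorts the normal
#' approximation with tie correction is used.
#'
#' @param valuesCase,valuesControl numeric vectors, at least 2 values
#'   each.
#' @param test "t_test" or "wilcoxon".
#' @return list with \code{p_value} (two-sided, in [0, 1]) and
#'   \code{degenerate} (TRUE when the data carried no usable signal:
#'   all values identical, or both cohorts constant).
#' @export
#' @examples
#' twoGroupTest(c(1, 2, 3), c(4, 5, 6), "wilcoxon")$p_value  # 0.1 exact
twoGroupTest <- function(valuesCase, valuesControl,
                         test = c("t_test", "wilcoxon")) {
    test <- match.arg(test)
    x <- as.numeric(valuesCase)
    y <- as.numeric(valuesControl)
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least 2 values")
    if (identical(sort(x), sort(y)))  # identical cohorts: no signal at all
        return(list(p_value = 1, degenerate = TRUE))
    if (all(c(x, y) == c(x, y)[1L]))
        return(list(p_value = 1, degenerate = TRUE))
    if (test == "t_test") {
        vx <- stats::var(x)
        vy <- stats::var(y)
        if (vx == 0 && vy == 0) {
            # constant within each cohort but different between them
            return(list(p_value = if (mean(x) == mean(y)) 1 else 0,
                        degenerate = TRUE))
        }
        p <- stats::t.test(x, y, var.equal = FALSE)$p.value
        return(list(p_value = p, degenerate = FALSE))
    }
    ## wilcoxon
    n1 <- length(x)
    n <- n1 + length(y)
    if (choose(n, n1) <= WILCOXON_EXACT_MAX) {
        p <- exactRankSumP(x, y)
    } else {
        p <- suppressWarnings(
            stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    }
    list(p_value = p, degenerate = FALSE)
}

## exact two-sided permutation p-value of the rank-sum statistic:
## the fraction of equally-likely case/control assignments whose group-1
## rank sum deviates from its permutation mean at least as much as the
## observed one (midranks shared with the observed data).
exactRankSumP <- function(x, y) {
    r <- rank(c(x, y))
    n1 <- length(x)
    n <- length(r)
    centre <- n1 * (n + 1) / 2
    obs <- abs(sum(r[seq_len(n1)]) - centre)
    sets <- utils::combn(n, n1)
    sums <- colSums(matrix(r[sets], nrow = n1))
    mean(abs(sums - centre) >= obs - 1e-9)
}

## per-sample mean RPM over a set of precursor positions, all samples
featureStatistic <- function(pc, positions) {
    rowMeans(pc@rpm[, positions, drop = FALSE])
}

expressionTable <- function(ids, stats, design, test) {
    cs <- caseSamples(design)
    ct <- controlSamples(design)
    n <- length(ids)
    meanCase <- meanControl <- fc <- p <- numeric(n)
    degen <- logical(n)
    for (i in seq_len(n)) {
        v <- stats[[i]]
        meanCase[i] <- mean(v[cs])
        meanControl[i] <- mean(v[ct])
        fc[i] <- foldChange(meanCase[i], meanControl[i])
        res <- twoGroupTest(v[cs], v[ct], test)
        p[i] <- res$p_value
        degen[i] <- res$degenerate
    }
    DataFrame(feature_id = ids, mean_case = meanCase,
              mean_control = meanControl, fold_change = fc,
              p_value = p, p_adj = stats::p.adjust(p, method = "BH"),
              degenerate = degen)
}

#' Precursor-level differential expression
#'
#' The per-sample statistic is the mean RPM coverage over all positions
#' of the precursor; cohorts are compared with the configured test and
#' the fold change is case/control on cohort means (pseudocount 0.01
#' RPM). Precursors with zero coverage in every sample are excluded with
#' a message.
#'
#' @param cov an RPM-normalized \code{\linkS4class{CoverageSet}}.
#' @param cfg a \code{\linkS4class{TestConfig}}.
#' @return \code{DataFrame} with columns feature_id, mean_case,
#'   mean_control, fold_change, p_value, p_adj (Benjamini-Hochberg,
#'   reported but never used for filtering) and degenerate.
#' @export
precursorExpression <- function(cov, cfg = testConfig()) {
    stopifnot(is(cov, "CoverageSet"))
    if (!cov@normalized)
        stop("coverage must be RPM-normalized first (normalizeRpm)")
    ids <- names(cov)
    keep <- vapply(ids, function(id) any(cov[[id]]@raw > 0), TRUE)
    if (any(!keep))
        message("excluding ", sum(!keep),
                " precursor(s) with zero coverage in all samples")
    ids <- ids[keep]
    stats <- lapply(ids, function(id) {
        pc <- cov[[id]]
        featureStatistic(pc, seq_len(ncol(pc@raw)))
    })
    expressionTable(ids, stats, cov@design, cfg@test)
}

#' Mature-arm differential expression
#'
#' As \code{\link{precursorExpression}} but the per-sample statistic is
#' the mean RPM over the annotated arm's positions only; one result row
#' per annotated mature arm. Arms with zero coverage in every sample are
#' excluded with a message.
#'
#' @inheritParams precursorExpression
#' @return \code{DataFrame} as in \code{\link{precursorExpression}} plus
#'   columns precursor_id and arm_label.
#' @export
matureExpression <- function(cov, cfg = testConfig()) {
    stopifnot(is(cov, "CoverageSet"))
    if (!cov@normalized)
        stop("coverage must be RPM-normalized first (normalizeRpm)")
    rel <- armRelativeCoords(cov@annotation)
    keep <- logical(nrow(rel))
    stats <- vector("list", nrow(rel))
    for (i in seq_len(nrow(rel))) {
        pc <- cov@coverages[[rel$precursor_id[i]]]
        if (is.null(pc)) next
        pos <- rel$rel_start[i]:rel$rel_end[i]
        if (!any(pc@raw[, pos, drop = FALSE] > 0)) next
        keep[i] <- TRUE
        stats[[i]] <- featureStatistic(pc, pos)
    }
    if (any(!keep))
        message("excluding ", sum(!keep),
                " mature arm(s) with zero coverage in all samples")
    out <- expressionTable(rel$name[keep], stats[keep], cov@design, cfg@test)
    out$precursor_id <- rel$precursor_id[keep]
    out$arm_label <- rel$arm_label[keep]
    out
}

#' 3' to 5' arm expression ratio
#'
#' For every precursor with both arms present in the mature results, the
#' quotient of the 5p and 3p fold changes. A quotient near 1 means both
#' arms move together; much greater than 1 means 5p-dominant
#' up-regulation; much less than 1 means 3p-dominant. Single-arm
#' precursors are omitted.
#'
#' @param matureResults \code{DataFrame} from
#'   \code{\link{matureExpression}}.
#' @return \code{DataFrame} with precursor_id, fc_5p, fc_3p, p_5p, p_3p,
#'   ratio_quotient.
#' @export
armRatio <- function(matureResults) {
    m <- as.data.frame(matureResults)
    m5 <- m[m$arm_label == "5p", ]
    m3 <- m[m$arm_label == "3p", ]
    common <- intersect(m5$precursor_id, m3$precursor_id)
    i5 <- match(common, m5$precursor_id)
    i3 <- match(common, m3$precursor_id)
    DataFrame(precursor_id = common,
              fc_5p = m5$fold_change[i5], fc_3p = m3$fold_change[i3],
              p_5p = m5$p_value[i5], p_3p = m3$p_value[i3],
              ratio_quotient = m5$fold_change[i5] / m3$fold_change[i3])
}

#' Per-base differential expression along precursors
#'
#' Applies the configured two-group test independently at every
#' precursor position. Positions with zero coverage in all samples get
#' p = 1 and direction "none". A mature arm is flagged differentially
#' regulated when at least \code{cfg@minSigPositions} of its positions
#' are significant at \code{cfg@alpha}.
#'
#' @inheritParams precursorExpression
#' @return list with elements:
#'   \describe{
#'     \item{positions}{named list (precursor id) of \code{DataFrame}s
#'       with position, p_value, direction ("up_in_cases",
#'       "down_in_cases", "none").}
#'     \item{summary}{\code{DataFrame}: precursor_id, length,
#'       n_significant.}
#'     \item{arms}{\code{DataFrame}: one row per annotated arm with
#'       n_significant within the arm and the differentially_regulated
#'       flag.}
#'   }
#' @export
perBaseExpression <- function(cov, cfg = testConfig()) {
    stopifnot(is(cov, "CoverageSet"))
    if (!cov@normalized)
        stop("coverage must be RPM-normalized first (normalizeRpm)")
    design <- cov@design
    cs <- caseSamples(design)
    ct <- controlSamples(design)
    positions <- list()
    ids <- names(cov)
    nSig <- integer(length(ids))
    lens <- integer(length(ids))
    for (k in seq_along(ids)) {
        pc <- cov[[ids[k]]]
        L <- ncol(pc@raw)
        lens[k] <- L
        p <- rep(1, L)
        dir <- rep("none", L)
        for (j in seq_len(L)) {
            if (!any(pc@raw[, j] > 0)) next
            v <- pc@rpm[, j]
            res <- twoGroupTest(v[cs], v[ct], cfg@test)
            p[j] <- res$p_value
            mc <- mean(v[cs]); mt <- mean(v[ct])
            if (p[j] < cfg@alpha && mc != mt)
                dir[j] <- if (mc > mt) "up_in_cases" else "down_in_cases"
        }
        nSig[k] <- sum(p < cfg@alpha)
        positions[[ids[k]]] <- DataFrame(position = seq_len(L),
                                         p_value = p, direction = dir)
    }
    rel <- armRelativeCoords(cov@annotation)
    armSig <- integer(nrow(rel))
    armLen <- integer(nrow(rel))
    for (i in seq_len(nrow(rel))) {
        pb <- positions[[rel$precursor_id[i]]]
        pos <- rel$rel_start[i]:rel$rel_end[i]
        armLen[i] <- length(pos)
        armSig[i] <- if (is.null(pb)) 0L else
            sum(pb$p_value[pos] < cfg@alpha)
    }
    list(positions = positions,
         summary = DataFrame(precursor_id = ids, length = lens,
                             n_significant = nSig),
         arms = DataFrame(mature_id = rel$mature_id, name = rel$name,
                          precursor_id = rel$precursor_id,
                          arm_label = rel$arm_label,
                          arm_length = armLen,
                          n_significant = armSig,
                          differentially_regulated =
                              armSig >= cfg@minSigPositions))
}
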