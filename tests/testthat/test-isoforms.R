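test_that("window coverage percentages follow the covered-cell definition", {
    design <- smallDesign(10, 4)
    raw <- matrix(0L, nrow = 14, ncol = 80,
                  dimnames = list(sampleIds(design), NULL))
    raw[, 10:31] <- 5L  # everyone covers the 5p arm itself
    # w = 1: exactly 3 of 10 case samples covered at the single window base
    raw[c("case01", "case02", "case03"), 32] <- 1L
    pc <- new("PrecursorCoverage", precursorId = "FIXP1", raw = raw,
              rpm = raw + 0)
    pct <- windowCoverage(pc, 10L, 31L, "three_prime", 1L, design)
    expect_equal(unname(pct["pct_case"]), 30)
    expect_equal(unname(pct["pct_control"]), 0)
    # w = 2 on controls: both bases, one base, none, none -> 37.5
    raw2 <- raw
    raw2["ctrl01", 32:33] <- 1L
    raw2["ctrl02", 32] <- 1L
    pc2 <- new("PrecursorCoverage", precursorId = "FIXP1", raw = raw2,
               rpm = raw2 + 0)
    pct2 <- windowCoverage(pc2, 10L, 31L, "three_prime", 2L, design)
    expect_equal(unname(pct2["pct_control"]), 100 * (2/2 + 1/2) / 4)
    # no reads beyond the arm end at all -> (0, 0)
    pct0 <- windowCoverage(pc, 10L, 31L, "five_prime", 2L, design)
    expect_equal(unname(pct0), c(0, 0))
    # percentages are bounded in [0, 100]
    expect_true(all(pct2 >= 0 & pct2 <= 100))
    # window entirely outside the precursor -> NULL
    expect_null(windowCoverage(pc, 1L, 31L, "five_prime", 3L, design))
})

test_that("window quotient is case/control, scale-invariant, NA at zero", {
    expect_equal(windowQuotient(31.5, 68.1), 31.5 / 68.1)
    expect_equal(windowQuotient(51.9, 5.3), 51.9 / 5.3)
    expect_equal(windowQuotient(12.3, 12.3), 1.0)
    expect_true(is.na(windowQuotient(10, 0)))
    # multiplying both cohort percentages by a constant changes nothing
    expect_equal(windowQuotient(3 * 31.5, 3 * 68.1),
                 windowQuotient(31.5, 68.1))
})

test_that("end motifs are the bases just outside the arm, truncated", {
    expect_identical(endMotif("AACCGGTT", 3L, 6L, "three_prime", 2L), "TT")
    expect_identical(endMotif("AACCGGTT", 3L, 6L, "five_prime", 2L), "AA")
    # arm flush with the precursor end: truncation to 0 or 1 base
    expect_identical(endMotif("AACCGGTT", 3L, 8L, "three_prime", 2L), "")
    expect_identical(endMotif("AACCGGTT", 3L, 7L, "three_prime", 2L), "T")
    expect_error(endMotif("AACCGGTT", 3L, 6L, "three_prime", 0L), "w must")
    expect_true(is.na(endMotif(NA_character_, 3L, 6L, "three_prime", 2L)))
})

test_that("window percentages decay with w while the quotient is stable", {
    # synthetic decaying end profile: covered-sample fraction halves with
    # each base beyond the arm end, same shape in both cohorts
    design <- smallDesign(8, 8)
    raw <- matrix(0L, nrow = 16, ncol = 80,
                  dimnames = list(sampleIds(design), NULL))
    raw[, 10:31] <- 5L
    extLens <- function(k) rep(1:4, c(ceiling(k / 2), ceiling(k / 4),
                                      ceiling(k / 8), ceiling(k / 8)))[1:k]
    csam <- caseSamples(design)[1:8]   # all 8 cases extend
    tsam <- controlSamples(design)[1:4]  # 4 of 8 controls extend
    lc <- extLens(8); lt <- extLens(4)
    for (i in seq_along(csam)) raw[csam[i], 32:(31 + lc[i])] <- 1L
    for (i in seq_along(tsam)) raw[tsam[i], 32:(31 + lt[i])] <- 1L
    pc <- new("PrecursorCoverage", precursorId = "FIXP1", raw = raw,
              rpm = raw + 0)
    pcts <- sapply(1:4, function(w)
        windowCoverage(pc, 10L, 31L, "three_prime", w, design))
    expect_true(all(diff(pcts["pct_case", ]) <= 1e-9))
    expect_true(all(diff(pcts["pct_control", ]) <= 1e-9))
    q <- pcts["pct_case", ] / pcts["pct_control", ]
    expect_lt(max(abs(q / q[1] - 1)), 0.25)
})

test_that("novel arms are called only on qualifying single-arm precursors", {
    design <- smallDesign(4, 4)
    ann1 <- makeAnnotation(L = 90L, arms = list(`5p` = c(10L, 31L)))
    raw <- matrix(0L, nrow = 8, ncol = 90,
                  dimnames = list(sampleIds(design), NULL))
    raw[, 10:31] <- 10L
    # zero coverage outside the arm -> nothing
    cov <- makeCoverageSet(raw, design, ann1)
    expect_equal(nrow(novelArmScan(cov)), 0L)
    # a clean 26 nt block outside arm + guard band -> a call
    raw2 <- raw
    raw2[, 50:75] <- 8L
    raw2[1:4, 50:75] <- 13L
    cov2 <- makeCoverageSet(raw2, design, ann1)
    calls <- as.data.frame(novelArmScan(cov2))
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$region_start, 50L)
    expect_equal(calls$length, 26L)
    expect_equal(calls$fold_change, (13 + 0.01) / (8 + 0.01))
    # the call never overlaps the annotated arm plus its 5 nt guard band
    expect_gt(calls$region_start, 31L + 5L)
    # a run shorter than a plausible mature arm is not called
    raw3 <- raw
    raw3[, 50:59] <- 8L
    expect_equal(nrow(novelArmScan(makeCoverageSet(raw3, design, ann1))), 0L)
    # runs longer than 30 nt are not mature-arm-like either
    raw4 <- raw
    raw4[, 40:85] <- 8L
    expect_equal(nrow(novelArmScan(makeCoverageSet(raw4, design, ann1))), 0L)
    # two-arm precursors are skipped by the precondition
    ann2 <- makeAnnotation(L = 90L)
    cov3 <- makeCoverageSet(raw2, design, ann2)
    expect_equal(nrow(novelArmScan(cov3)), 0L)
})

test_that("windowAnalysis reports both ends of every annotated arm", {
    design <- smallDesign(3, 3)
    seq <- paste(rep(c("A", "C", "G", "T"), 20), collapse = "")
    ann <- makeAnnotation(L = 80L, seq = seq)
    raw <- matrix(0L, nrow = 6, ncol = 80,
                  dimnames = list(sampleIds(design), NULL))
    raw[, 10:31] <- 4L
    raw[, 49:70] <- 4L
    cov <- makeCoverageSet(raw, design, ann)
    w <- as.data.frame(windowAnalysis(cov, w = 2L))
    expect_equal(nrow(w), 4L)  # 2 arms x 2 ends
    expect_setequal(w$end, c("five_prime", "three_prime"))
    # motifs come from the hairpin sequence just outside each end
    chars <- strsplit(seq, "")[[1]]
    m5five <- w$motif[w$arm_label == "5p" & w$end == "five_prime"]
    expect_identical(m5five, paste(chars[8:9], collapse = ""))
    m5three <- w$motif[w$arm_label == "5p" & w$end == "three_prime"]
    expect_identical(m5three, paste(chars[32:33], collapse = ""))
    expect_equal(w$difference, w$pct_case - w$pct_control)
})
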