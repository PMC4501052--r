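test_that("degenerate inputs are flagged with the prescribed p-values", {
    for (test in c("t_test", "wilcoxon")) {
        res <- twoGroupTest(c(1, 2, 3), c(1, 2, 3), test)
        expect_equal(res$p_value, 1)
        expect_true(res$degenerate)
        res <- twoGroupTest(c(2, 2, 2), c(2, 2, 2), test)
        expect_equal(res$p_value, 1)
        expect_true(res$degenerate)
    }
    # constant but different cohorts: zero-variance t-test edge
    res <- twoGroupTest(c(0, 0, 0, 0), c(5, 5, 5, 5), "t_test")
    expect_equal(res$p_value, 0)
    expect_true(res$degenerate)
    expect_error(twoGroupTest(1, c(1, 2)), "at least 2")
})

test_that("wilcoxon p-values equal exact permutation enumeration", {
    expect_equal(twoGroupTest(c(1, 2, 3), c(4, 5, 6), "wilcoxon")$p_value,
                 2 / 20)
    set.seed(42)
    for (n1 in c(2L, 3L, 5L)) {
        for (n2 in c(2L, 4L, 6L)) {
            x <- round(rnorm(n1, 1), 2)
            y <- round(rnorm(n2), 2)
            expect_equal(twoGroupTest(x, y, "wilcoxon")$p_value,
                         permutationRankSumOracle(x, y))
            # with ties (midranks)
            xt <- sample(0:2, n1, TRUE)
            yt <- sample(0:2, n2, TRUE)
            if (!all(c(xt, yt) == xt[1]))
                expect_equal(twoGroupTest(xt, yt, "wilcoxon")$p_value,
                             permutationRankSumOracle(xt, yt))
        }
    }
})

test_that("t-test p-value matches the closed-form Welch computation", {
    x <- c(4.1, 5.2, 6.3, 5.8)
    y <- c(3.0, 3.5, 2.8, 3.9, 3.1)
    t_stat <- (mean(x) - mean(y)) / sqrt(var(x) / 4 + var(y) / 5)
    df <- (var(x) / 4 + var(y) / 5)^2 /
        ((var(x) / 4)^2 / 3 + (var(y) / 5)^2 / 4)
    p_manual <- 2 * pt(-abs(t_stat), df)
    expect_equal(twoGroupTest(x, y, "t_test")$p_value, p_manual)
})

test_that("identical cohorts give unit fold changes and p = 1 everywhere", {
    design <- smallDesign(3, 3)
    set.seed(9)
    half <- matrix(rpois(3 * 60, 20), nrow = 3)
    raw <- rbind(half, half)
    mode(raw) <- "integer"
    rownames(raw) <- sampleIds(design)
    cov <- makeCoverageSet(raw, design)
    res <- precursorExpression(cov)
    expect_equal(res$fold_change, 1)
    expect_equal(res$p_value, 1)
    pb <- perBaseExpression(cov)
    expect_equal(pb$summary$n_significant, 0L)
    expect_true(all(pb$positions$FIXP1$direction == "none"))
})

test_that("swapping cohort labels inverts fold changes, keeps p-values", {
    set.seed(10)
    for (test in c("t_test", "wilcoxon")) {
        design <- smallDesign(3, 4)
        flipped <- studyDesign(sampleIds(design),
                               c(rep("case", 3), rep("control", 4)),
                               caseLabel = "control")
        raw <- matrix(rpois(7 * 50, 15), nrow = 7,
                      dimnames = list(sampleIds(design), NULL))
        mode(raw) <- "integer"
        cov <- makeCoverageSet(raw, design)
        covF <- makeCoverageSet(raw, flipped)
        cfg <- testConfig(test = test)
        a <- precursorExpression(cov, cfg)
        b <- precursorExpression(covF, cfg)
        expect_equal(b$fold_change, 1 / a$fold_change)
        expect_equal(b$p_value, a$p_value)
        ma <- matureExpression(cov, cfg)
        mb <- matureExpression(covF, cfg)
        expect_equal(mb$fold_change, 1 / ma$fold_change)
        expect_equal(mb$p_value, ma$p_value)
    }
})

test_that("mature statistics use only the arm's positions", {
    design <- smallDesign(2, 2)
    raw <- matrix(0L, nrow = 4, ncol = 80,
                  dimnames = list(sampleIds(design), NULL))
    raw[, 10:31] <- 6L   # uniform coverage c on the 5p arm
    raw[, 49:70] <- 2L
    cov <- makeCoverageSet(raw, design)
    me <- as.data.frame(matureExpression(cov))
    m5 <- me[me$arm_label == "5p", ]
    expect_equal(m5$mean_case, 6)
    expect_equal(m5$mean_control, 6)
    m3 <- me[me$arm_label == "3p", ]
    expect_equal(m3$mean_case, 2)
})

test_that("single-arm precursors appear once in mature and never in ratios", {
    design <- smallDesign(2, 2)
    ann <- makeAnnotation(L = 80L, arms = list(`5p` = c(10L, 31L)))
    raw <- matrix(3L, nrow = 4, ncol = 80,
                  dimnames = list(sampleIds(design), NULL))
    cov <- makeCoverageSet(raw, design, ann)
    me <- matureExpression(cov)
    expect_equal(nrow(me), 1L)
    expect_equal(nrow(armRatio(me)), 0L)
})

test_that("arm-ratio quotients follow fc_5p / fc_3p", {
    m <- S4Vectors::DataFrame(
        feature_id = c("x-5p", "x-3p", "y-5p", "y-3p"),
        mean_case = 1, mean_control = 1,
        fold_change = c(1.8, 1.8, 3.5, 0.5),
        p_value = c(0.2, 0.2, 0.007, 0.003),
        p_adj = NA_real_, degenerate = FALSE,
        precursor_id = c("x", "x", "y", "y"),
        arm_label = c("5p", "3p", "5p", "3p"))
    r <- as.data.frame(armRatio(m))
    expect_equal(r$ratio_quotient[r$precursor_id == "x"], 1.0)
    # opposite arm regulation: 3.5 / 0.5 -> the 7-fold pattern
    expect_equal(r$ratio_quotient[r$precursor_id == "y"], 7.0)
})

test_that("per-base results have one entry per position and count alpha", {
    design <- smallDesign(3, 3)
    set.seed(12)
    raw <- matrix(rpois(6 * 70, 12), nrow = 6,
                  dimnames = list(sampleIds(design), NULL))
    raw[1:3, 20:40] <- raw[1:3, 20:40] + 40L  # strong case-up block
    mode(raw) <- "integer"
    cov <- makeCoverageSet(raw, design, makeAnnotation(L = 70L))
    cfg <- testConfig(alpha = 0.05, minSigPositions = 15L)
    pb <- perBaseExpression(cov, cfg)
    df <- as.data.frame(pb$positions$FIXP1)
    expect_equal(nrow(df), 70L)
    expect_equal(pb$summary$n_significant,
                 sum(df$p_value < cfg@alpha))
    expect_true(all(df$direction[df$p_value < 0.05 &
                                 df$position %in% 20:40] == "up_in_cases"))
    # lowering alpha never increases the significant-position count
    stricter <- perBaseExpression(cov, testConfig(alpha = 0.01))
    expect_lte(stricter$summary$n_significant, pb$summary$n_significant)
    # arm flag: the 5p arm (10..31) overlaps the block by >= 12 positions
    arms <- as.data.frame(pb$arms)
    expect_equal(arms$n_significant[arms$arm_label == "5p"],
                 sum(df$p_value[10:31] < 0.05))
})

test_that("all-zero precursors are excluded with a message", {
    design <- smallDesign(2, 2)
    raw <- matrix(0L, nrow = 4, ncol = 40,
                  dimnames = list(sampleIds(design), NULL))
    cov <- makeCoverageSet(raw, design, makeAnnotation(L = 40L))
    expect_message(res <- precursorExpression(cov), "zero coverage")
    expect_equal(nrow(res), 0L)
})
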