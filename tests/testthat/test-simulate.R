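simDirs <- function() file.path(tempfile("sim"), c("a", "b"))

test_that("identical seed and config give byte-identical outputs", {
    dirs <- simDirs()
    specs <- defaultPrecursorSpecs(3)
    specs$fc_5p <- c(2, 1, 1)
    specs$two_arm[3] <- FALSE
    specs$novel_len[3] <- 26L; specs$novel_fc[3] <- 1.6
    cfg <- simulationConfig(nCase = 3, nControl = 3, precursors = specs,
                            depth = 50, seed = 77)
    s1 <- simulateStudy(cfg, dirs[1])
    s2 <- simulateStudy(cfg, dirs[2])
    for (f in c(basename(s1$arf), "annotation.gff3", "hairpin.fa",
                "mature.fa", "design.tsv", "totals.tsv")) {
        expect_identical(readLines(file.path(dirs[1], f)),
                         readLines(file.path(dirs[2], f)),
                         label = paste("file", f))
    }
    # a different seed changes the reads
    s3 <- simulateStudy(simulationConfig(nCase = 3, nControl = 3,
                                         precursors = specs, depth = 50,
                                         seed = 78),
                        file.path(tempfile("sim"), "c"))
    expect_false(identical(readLines(s1$arf[[1]]), readLines(s3$arf[[1]])))
})

test_that("generated studies pass the format readers for many seeds", {
    for (seed in c(1, 7, 19, 101, 2023)) {
        dir <- file.path(tempfile("sweep"), as.character(seed))
        cfg <- simulationConfig(nCase = 2, nControl = 2,
                                nPrecursors = 2, depth = 20, seed = seed)
        sim <- simulateStudy(cfg, dir)
        for (p in sim$arf)
            expect_silent(rec <- readArf(p))
        ann <- readMirbaseGff(sim$gff, hairpinFasta = sim$hairpin)
        expect_equal(length(ann), 2L)
        expect_s4_class(ann, "HairpinAnnotation")
        expect_equal(length(hairpinSeqs(ann)), 2L)
        mat <- readMatureFasta(sim$mature)
        expect_equal(length(mat), 4L)
        design <- readDesign(sim$design, caseLabel = "case")
        expect_equal(length(sampleIds(design)), 4L)
        totals <- readTotals(sim$totals)
        expect_true(all(totals@totals > 0))
    }
})

test_that("annotated mature sequences match the simulated genome", {
    dir <- file.path(tempfile(), "seqcheck")
    cfg <- simulationConfig(nCase = 2, nControl = 2, nPrecursors = 4,
                            depth = 30, seed = 5)
    sim <- simulateStudy(cfg, dir)
    ann <- readMirbaseGff(sim$gff, hairpinFasta = sim$hairpin)
    mat <- readMatureFasta(sim$mature)
    rel <- isomiRscope:::armRelativeCoords(ann)
    seqs <- hairpinSeqs(ann)
    precNames <- S4Vectors::mcols(precursors(ann))$name
    pids <- S4Vectors::mcols(precursors(ann))$precursor_id
    for (i in seq_len(nrow(rel))) {
        pn <- precNames[match(rel$precursor_id[i], pids)]
        hp <- as.character(seqs[[pn]])
        expect_identical(substr(hp, rel$rel_start[i], rel$rel_end[i]),
                         as.character(mat[[rel$name[i]]]),
                         label = rel$name[i])
    }
})

test_that("extension_prob 0 leaves arm ends clean; carriers hit exactly", {
    specs <- defaultPrecursorSpecs(2)
    specs$ext_arm[2] <- "5p"; specs$ext_end[2] <- "three_prime"
    specs$ext_p_case[2] <- 0.6; specs$ext_p_control[2] <- 0.3
    specs$ext_max[2] <- 2L
    cfg <- simulationConfig(nCase = 10, nControl = 10, precursors = specs,
                            depth = 100, seed = 13)
    sim <- simulateStudy(cfg, file.path(tempfile(), "ext"))
    params <- runParameters(sim$arf, sim$gff, sim$design,
                            outDir = tempfile(), totalsFile = sim$totals,
                            caseLabel = "case", makeFigures = FALSE)
    cov <- loadStudy(params)
    design <- readDesign(sim$design, caseLabel = "case")
    rel <- isomiRscope:::armRelativeCoords(cov@annotation)
    # precursor 1 has no extension spec: window coverage 0 everywhere
    r1 <- rel[rel$precursor_id == "MI900001" & rel$arm_label == "5p", ]
    pct <- windowCoverage(cov[["MI900001"]], r1$rel_start, r1$rel_end,
                          "three_prime", 2L, design)
    expect_equal(unname(pct), c(0, 0))
    # precursor 2: carrier fractions are hit exactly at w = 1
    r2 <- rel[rel$precursor_id == "MI900002" & rel$arm_label == "5p", ]
    pct2 <- windowCoverage(cov[["MI900002"]], r2$rel_start, r2$rel_end,
                           "three_prime", 1L, design)
    expect_equal(unname(pct2["pct_case"]), 60)
    expect_equal(unname(pct2["pct_control"]), 30)
    # and the truth table predicts the measured percentages at any w
    for (w in 1:2) {
        pt <- truthWindowPct(sim, "sim-02", "5p", "three_prime", w)
        pw <- windowCoverage(cov[["MI900002"]], r2$rel_start, r2$rel_end,
                             "three_prime", w, design)
        expect_equal(unname(pw), unname(pt), tolerance = 1e-9)
    }
})

test_that("mean per-arm coverage converges to the configured depth", {
    # counts are overdispersed (NB CV ~ 0.45 at dispersion 0.2), so the
    # law-of-large-numbers check pools 600 sample-arm draws
    cfg <- simulationConfig(nCase = 150, nControl = 150, nPrecursors = 1,
                            depth = 1000, libSizeSd = 0, seed = 99)
    sim <- simulateStudy(cfg, file.path(tempfile(), "lln"))
    params <- runParameters(sim$arf, sim$gff, sim$design,
                            outDir = tempfile(), totalsFile = sim$totals,
                            caseLabel = "case", makeFigures = FALSE)
    cov <- loadStudy(params)
    rel <- isomiRscope:::armRelativeCoords(cov@annotation)
    raw <- rawCounts(cov, "MI900001")
    perArm <- vapply(seq_len(nrow(rel)), function(i) {
        pos <- rel$rel_start[i]:rel$rel_end[i]
        mean(rowMeans(raw[, pos, drop = FALSE]))
    }, numeric(1))
    expect_lt(abs(mean(perArm) - 1000) / 1000, 0.05)
})

test_that("truthCompare reports one row per truth parameter", {
    specs <- defaultPrecursorSpecs(3)
    specs$two_arm[3] <- FALSE
    specs$novel_len[3] <- 26L; specs$novel_fc[3] <- 1.6
    cfg <- simulationConfig(nCase = 4, nControl = 4, precursors = specs,
                            depth = 80, seed = 3)
    sim <- simulateStudy(cfg, file.path(tempfile(), "tc"))
    params <- runParameters(sim$arf, sim$gff, sim$design,
                            outDir = tempfile(), totalsFile = sim$totals,
                            caseLabel = "case", makeFigures = FALSE)
    cov <- loadStudy(params)
    mat <- matureExpression(cov)
    nov <- novelArmScan(cov)
    rep <- truthCompare(mat, nov, sim)
    # 2 + 2 + 1 arm fold changes, plus novel fc and novel length
    expect_equal(nrow(rep), 5L + 2L)
    expect_equal(sum(rep$type == "arm_fc"), 5L)
    expect_true(all(c("novel_fc", "novel_length") %in% rep$type))
    expect_equal(rep$rel_error,
                 (rep$estimate - rep$truth) / rep$truth)
    # specificity: precursors simulated without a novel arm get no call
    expect_false(any(c("MI900001", "MI900002") %in% nov$precursor_id))
})
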