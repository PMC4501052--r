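covFromReads <- function(readsBySample, ann, design) {
    recs <- lapply(readsBySample, function(iv) {
        if (!nrow(iv)) return(readArf(writeArfFixture(character(0))))
        lines <- vapply(seq_len(nrow(iv)), function(k) {
            len <- iv$end[k] - iv$start[k] + 1L
            arfLine(read_id = sprintf("r%d", k), len = len,
                    read_seq = strrep("A", len), ref_start = iv$start[k],
                    ref_end = iv$end[k], strand = iv$strand[k])
        }, character(1))
        readArf(writeArfFixture(lines))
    })
    buildCoverage(recs, ann, design)
}

test_that("single and overlapping reads tally per-base counts correctly", {
    ann <- makeAnnotation(L = 80L, precStart = 1001L)
    design <- smallDesign(2, 2)
    reads <- list(
        case01 = data.frame(start = 1000L + 1L, end = 1000L + 22L,
                            strand = "+"),
        case02 = data.frame(start = 1000L + c(1L, 10L),
                            end = 1000L + c(22L, 31L), strand = "+"),
        ctrl01 = data.frame(start = integer(0), end = integer(0),
                            strand = character(0)),
        ctrl02 = data.frame(start = integer(0), end = integer(0),
                            strand = character(0)))
    cov <- covFromReads(reads, ann, design)
    raw <- rawCounts(cov, "FIXP1")
    expect_equal(unname(raw["case01", ]), c(rep(1, 22), rep(0, 58)))
    expect_equal(unname(raw["case02", ]),
                 c(rep(1, 9), rep(2, 13), rep(1, 9), rep(0, 49)))
    expect_equal(sum(raw["ctrl01", ]), 0)
})

test_that("opposite-strand alignments are ignored and partial overlaps clip", {
    ann <- makeAnnotation(L = 80L, precStart = 1001L)
    design <- smallDesign(2, 2)
    reads <- list(case01 = data.frame(
        start = 1000L + c(1L, -9L), end = 1000L + c(22L, 5L),
        strand = c("-", "+")))
    cov <- suppressWarnings(covFromReads(reads, ann, design))
    raw <- rawCounts(cov, "FIXP1")
    # minus-strand read dropped; partial read contributes positions 1..5
    expect_equal(unname(raw["case01", ]), c(rep(1, 5), rep(0, 75)))
})

test_that("coverage conserves alignment overlap lengths (brute-force oracle)", {
    set.seed(33)
    design <- smallDesign(1, 1)
    for (rep in 1:50) {
        L <- sample(60:100, 1)
        strand <- sample(c("+", "-"), 1)
        ann <- makeAnnotation(L = L, strand = strand, precStart = 2001L)
        n <- sample(0:10, 1)
        st <- sample(1960:(2000 + L + 20), n, replace = TRUE)
        en <- st + sample(15:30, n, replace = TRUE)
        reads <- list(case01 = data.frame(start = st, end = en,
                                          strand = rep(strand, n)))
        cov <- suppressWarnings(covFromReads(reads, ann, design))
        raw <- rawCounts(cov, "FIXP1")
        ovl <- pmax(0L, pmin(en, 2000L + L) - pmax(st, 2001L) + 1L)
        expect_equal(sum(raw["case01", ]), sum(ovl))
        # per-base equality against the brute-force tally (reflected for -)
        rel <- mapToPrecursor(st, en, 2001L, 2000L + L, strand)
        keep <- !is.na(rel[, 1])
        expect_equal(unname(raw["case01", ]),
                     bruteCoverage(rel[keep, "start"], rel[keep, "end"], L))
    }
})

test_that("a design sample without records yields a zero row and a warning", {
    ann <- makeAnnotation(L = 40L)
    design <- smallDesign(2, 2)
    reads <- list(case01 = data.frame(start = 1001L, end = 1022L,
                                      strand = "+"))
    expect_warning(cov <- covFromReads(reads, ann, design),
                   "zero coverage")
    expect_equal(sum(rawCounts(cov, "FIXP1")["ctrl02", ]), 0)
    # but a record sample missing from the design is an error
    expect_error(buildCoverage(list(unknown = readArf(
        writeArfFixture(arfLine()))), ann, design), "absent from design")
})

test_that("RPM normalization follows the reads-per-million definition", {
    design <- smallDesign(1, 1)
    raw <- matrix(c(10L, 7L), nrow = 2, ncol = 1,
                  dimnames = list(c("case01", "ctrl01"), NULL))
    pc <- new("PrecursorCoverage", precursorId = "FIXP1", raw = raw,
              rpm = matrix(numeric(0), 0, 0))
    cov <- new("CoverageSet", coverages = list(FIXP1 = pc), design = design,
               normalization = normalizationTable(mode = "none"),
               annotation = makeAnnotation(L = 1L, arms = list()),
               normalized = FALSE)
    tot <- normalizationTable(c(case01 = 2e6, ctrl01 = 1e6), "total_run")
    rpm <- rpmCounts(normalizeRpm(cov, tot), "FIXP1")
    expect_equal(unname(rpm["case01", 1]), 5)     # 10 * 1e6 / 2e6
    expect_equal(unname(rpm["ctrl01", 1]), 7)     # totals of 1e6: identity
    # mode none copies raw unchanged
    rpm0 <- rpmCounts(normalizeRpm(cov, normalizationTable(mode = "none")),
                      "FIXP1")
    expect_equal(unname(rpm0[, 1]), c(10, 7))
    # non-positive totals and missing samples are rejected
    expect_error(normalizeRpm(cov, normalizationTable(
        c(case01 = 0, ctrl01 = 1e6), "total_run")), "positive")
    expect_error(normalizeRpm(cov, normalizationTable(
        c(case01 = 1e6), "total_run")), "missing")
})

test_that("RPM normalization is linear in the raw counts", {
    design <- smallDesign(2, 2)
    set.seed(5)
    raw <- matrix(rpois(4 * 30, 8), nrow = 4,
                  dimnames = list(sampleIds(design), NULL))
    mode(raw) <- "integer"
    ann <- makeAnnotation(L = 30L, arms = list())
    mk <- function(m) {
        pc <- new("PrecursorCoverage", precursorId = "FIXP1", raw = m,
                  rpm = matrix(numeric(0), 0, 0))
        cov <- new("CoverageSet", coverages = list(FIXP1 = pc),
                   design = design,
                   normalization = normalizationTable(mode = "none"),
                   annotation = ann, normalized = FALSE)
        tot <- normalizationTable(setNames(rep(3e6, 4), sampleIds(design)),
                                  "genome_mapped")
        rpmCounts(normalizeRpm(cov, tot), "FIXP1")
    }
    expect_equal(mk(2L * raw), 2 * mk(raw))
})
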