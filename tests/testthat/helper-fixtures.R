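# Fixtures are built in code at test time; nothing binary is stored.

arfLine <- function(read_id = "r1", len = 22L, read_seq = strrep("A", len),
                    ref_id = "chr1", ref_len = 248956422L,
                    ref_start = 100L, ref_end = ref_start + len - 1L,
                    ref_seq = read_seq, strand = "+", mm = 0L,
                    edit = strrep("m", ref_end - ref_start + 1L)) {
    paste(read_id, len, 1L, len, read_seq, ref_id, ref_len, ref_start,
          ref_end, ref_seq, strand, mm, edit, sep = "\t")
}

writeArfFixture <- function(lines) {
    path <- tempfile(fileext = ".arf")
    writeLines(lines, path)
    path
}

# one-precursor annotation built directly; arms as relative coordinates
makeAnnotation <- function(L = 80L, strand = "+",
                           arms = list(`5p` = c(10L, 31L),
                                       `3p` = c(L - 31L, L - 10L)),
                           precStart = 1001L, chrom = "chr1",
                           name = "hsa-mir-fix-1", seq = NULL) {
    precEnd <- precStart + L - 1L
    prec <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(precStart, precEnd),
                                   strand = strand)
    S4Vectors::mcols(prec)$precursor_id <- "FIXP1"
    S4Vectors::mcols(prec)$name <- name
    relToGen <- function(rel) {
        if (strand == "+") c(precStart + rel[1L] - 1L, precStart + rel[2L] - 1L)
        else c(precEnd - rel[2L] + 1L, precEnd - rel[1L] + 1L)
    }
    if (length(arms)) {
        g <- t(vapply(arms, relToGen, numeric(2L)))
        arm <- GenomicRanges::GRanges(chrom, IRanges::IRanges(g[, 1L], g[, 2L]),
                                      strand = strand)
        S4Vectors::mcols(arm)$mature_id <- paste0("FIXM", seq_along(arms))
        S4Vectors::mcols(arm)$name <- paste0(name, "-", names(arms))
        S4Vectors::mcols(arm)$precursor_id <- "FIXP1"
        S4Vectors::mcols(arm)$arm_label <- names(arms)
    } else {
        arm <- isomiRscope:::emptyArmGR()
    }
    seqs <- if (is.null(seq)) Biostrings::DNAStringSet() else {
        s <- Biostrings::DNAStringSet(seq)
        names(s) <- name
        s
    }
    new("HairpinAnnotation", precursors = prec, arms = arm, seqs = seqs)
}

# CoverageSet straight from a raw matrix (samples x L), RPM = raw
makeCoverageSet <- function(raw, design, annotation = NULL) {
    if (is.null(annotation))
        annotation <- makeAnnotation(L = ncol(raw))
    pc <- new("PrecursorCoverage", precursorId = "FIXP1",
              raw = raw, rpm = matrix(numeric(0), 0, 0))
    cov <- new("CoverageSet", coverages = list(FIXP1 = pc),
               design = design,
               normalization = normalizationTable(mode = "none"),
               annotation = annotation, normalized = FALSE)
    normalizeRpm(cov, normalizationTable(mode = "none"))
}

smallDesign <- function(nCase = 2L, nControl = 2L) {
    studyDesign(c(sprintf("case%02d", seq_len(nCase)),
                  sprintf("ctrl%02d", seq_len(nControl))),
                rep(c("case", "control"), c(nCase, nControl)),
                caseLabel = "case")
}

# exact permutation oracle for the two-sided rank-sum test: enumerate all
# case/control assignments and count those whose group mean-rank
# difference is at least as extreme as observed
permutationRankSumOracle <- function(x, y) {
    r <- rank(c(x, y))
    n1 <- length(x)
    n <- length(r)
    obs <- abs(mean(r[seq_len(n1)]) - mean(r[-seq_len(n1)]))
    sets <- utils::combn(n, n1)
    devs <- apply(sets, 2L, function(idx)
        abs(mean(r[idx]) - mean(r[-idx])))
    mean(devs >= obs - 1e-9)
}

# brute-force per-base tally: independent of IRanges::coverage
bruteCoverage <- function(starts, ends, L) {
    v <- integer(L)
    for (k in seq_along(starts)) {
        a <- max(1L, starts[k]); b <- min(L, ends[k])
        if (a <= b) v[a:b] <- v[a:b] + 1L
    }
    v
}

# tiny miRBase-style GFF3 written to a tempfile
gffFixture <- function(lines) {
    path <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3", lines), path)
    path
}

gffRow <- function(type, start, end, attrs, chrom = "chr1", strand = "+") {
    paste(chrom, ".", type, start, end, ".", strand, ".", attrs, sep = "\t")
}
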