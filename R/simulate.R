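## Seeded generator of complete synthetic case/control studies:
## miRBase-style annotation (GFF3 + hairpin and mature FASTA), one arf
## alignment file per sample, totals and design tables, and a truth
## table for parameter-recovery benchmarking.
##
## Read counts per sample/arm are negative binomial (var = mu + disp *
## mu^2, default dispersion 0.2: overdispersed as miRNA-seq cohorts
## are). IsomiR end extensions are a per-sample trait: round(p * n)
## samples per cohort carry the isoform (so the cohort fraction -- what
## the window analysis estimates -- is controlled exactly), and within a
## carrier a fixed fraction of the arm's reads is extended by the
## carrier's extension length. Extension lengths follow a truncated
## geometric profile allocated by stratified inverse-CDF, which makes
## the expected window percentages decay with window size while the
## case/control quotient stays constant.

#' Simulation configuration
#'
#' @param nCase,nControl cohort sizes.
#' @param precursors data.frame of per-precursor specs, or NULL for
#'   \code{defaultPrecursorSpecs(nPrecursors)}. Columns (defaults filled
#'   in when missing): id, length, strand, arm_len, two_arm (annotate
#'   and express both arms), fc_5p, fc_3p, novel_len / novel_fc (NA for
#'   no spiked unannotated arm; only meaningful with two_arm = FALSE),
#'   ext_arm ("5p"/"3p"/NA), ext_end ("five_prime"/"three_prime"),
#'   ext_p_case, ext_p_control, ext_max.
#' @param nPrecursors number of default precursors when
#'   \code{precursors} is NULL.
#' @param depth expected read count per annotated arm per control
#'   sample (case arms scale by their fold change).
#' @param dispersion negative-binomial dispersion (var = mu + dispersion
#'   * mu^2); 0 gives Poisson counts.
#' @param totalReads nominal per-sample total read count written to the
#'   normalization table.
#' @param libSizeSd log-scale standard deviation of per-sample library
#'   size factors; totals and expected counts scale together, so RPM
#'   normalization removes the factor.
#' @param extReadFraction fraction of a carrier sample's arm reads that
#'   are extended.
#' @param extDecay geometric decay of the extension-length profile over
#'   1..ext_max.
#' @param seed integer seed; mandatory. Identical seed and config give
#'   byte-identical outputs.
#' @return classed list ("SimulationConfig").
#' @export
simulationConfig <- function(nCase = 10L, nControl = 10L, precursors = NULL,
                             nPrecursors = 20L, depth = 200,
                             dispersion = 0.2, totalReads = 5e6,
                             libSizeSd = 0.1, extReadFraction = 0.3,
                             extDecay = 0.5, seed) {
    if (missing(seed))
        stop("seed is mandatory")
    if (is.null(precursors))
        precursors <- defaultPrecursorSpecs(nPrecursors)
    precursors <- fillPrecursorSpecs(precursors)
    stopifnot(nCase >= 2L, nControl >= 2L, depth > 0, dispersion >= 0,
              totalReads > 0, extReadFraction > 0, extReadFraction <= 1,
              extDecay > 0, extDecay <= 1)
    badArm <- precursors$arm_len + 20L > precursors$length
    if (any(badArm))
        stop("arm does not fit inside precursor: ",
             paste(precursors$id[badArm], collapse = ", "))
    structure(list(nCase = as.integer(nCase), nControl = as.integer(nControl),
                   precursors = precursors, depth = depth,
                   dispersion = dispersion, totalReads = totalReads,
                   libSizeSd = libSizeSd, extReadFraction = extReadFraction,
                   extDecay = extDecay, seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' @rdname simulationConfig
#' @export
defaultPrecursorSpecs <- function(nPrecursors = 20L) {
    n <- as.integer(nPrecursors)
    data.frame(id = sprintf("sim-%02d", seq_len(n)),
               length = 70L + 5L * (seq_len(n) %% 5L),
               strand = ifelse(seq_len(n) %% 2L == 1L, "+", "-"),
               arm_len = 21L + (seq_len(n) %% 3L),
               two_arm = TRUE, fc_5p = 1, fc_3p = 1,
               novel_len = NA_integer_, novel_fc = NA_real_,
               ext_arm = NA_character_, ext_end = NA_character_,
               ext_p_case = NA_real_, ext_p_control = NA_real_,
               ext_max = NA_integer_,
               stringsAsFactors = FALSE)
}

fillPrecursorSpecs <- function(df) {
    n <- nrow(df)
    defaults <- defaultPrecursorSpecs(n)
    for (cc in colnames(defaults))
        if (!cc %in% colnames(df)) df[[cc]] <- defaults[[cc]]
    df$length <- as.integer(df$length)
    df$arm_len <- as.integer(df$arm_len)
    df
}

## precursor-relative arm coordinates used by the generator:
## 5p arm starts at position 10; 3p arm ends 10 bases from the 3' end
simArmCoords <- function(L, armLen) {
    list(`5p` = c(10L, 10L + armLen - 1L),
         `3p` = c(L - 9L - armLen, L - 10L))
}

## truncated geometric extension-length profile over 1..m
extLengthProfile <- function(m, decay) {
    p <- decay^(seq_len(m) - 1L)
    p / sum(p)
}

## stratified inverse-CDF allocation of k lengths from the profile
allocateExtLengths <- function(k, m, decay) {
    if (k == 0L) return(integer(0))
    cdf <- cumsum(extLengthProfile(m, decay))
    q <- (seq_len(k) - 0.5) / k
    vapply(q, function(x) which(cdf >= x - 1e-12)[1L], 1L)
}

#' Simulate a complete synthetic study
#'
#' Writes, under \code{dir}: one miRDeep2-style arf file per sample,
#' miRBase-dialect annotation (annotation.gff3, hairpin.fa, mature.fa
#' with RNA alphabet), design.tsv, totals.tsv, and plain-text truth
#' tables. All outputs are valid inputs for the readers in this package
#' and byte-identical across runs with the same config.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param dir output directory (created).
#' @return list with the file paths (\code{arf} named by sample,
#'   \code{gff}, \code{hairpin}, \code{mature}, \code{design},
#'   \code{totals}), the sample ids, and \code{truth}: a list of
#'   data.frames \code{arms} (true per-arm fold changes),
#'   \code{ext} (per-carrier extension lengths) and \code{novel}
#'   (spiked unannotated arm regions).
#' @export
simulateStudy <- function(cfg, dir) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(cfg$seed, kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")

    specs <- cfg$precursors
    nP <- nrow(specs)
    flank <- 150L
    gStart <- integer(nP)
    pos <- flank + 1L
    for (i in seq_len(nP)) {
        gStart[i] <- pos
        pos <- pos + specs$length[i] + flank
    }
    chromLen <- pos + flank
    chromSeq <- paste(sample(c("A", "C", "G", "T"), chromLen,
                             replace = TRUE), collapse = "")
    chrom <- "chr1"

    samples <- c(sprintf("case%02d", seq_len(cfg$nCase)),
                 sprintf("ctrl%02d", seq_len(cfg$nControl)))
    groups <- rep(c("case", "control"), c(cfg$nCase, cfg$nControl))
    isCase <- groups == "case"
    sf <- exp(stats::rnorm(length(samples), 0, cfg$libSizeSd))
    totals <- round(cfg$totalReads * sf)

    ## per-sample extension carrier assignment, exact cohort fractions
    extDetail <- list()
    carrierLen <- list()  # key: prec|arm|end|sample -> ext length
    for (i in seq_len(nP)) {
        if (is.na(specs$ext_arm[i])) next
        for (coh in c("case", "control")) {
            cohSamples <- samples[groups == coh]
            p <- if (coh == "case") specs$ext_p_case[i] else
                specs$ext_p_control[i]
            k <- round(p * length(cohSamples))
            carriers <- if (k > 0L) sample(cohSamples, k) else character(0)
            lens <- allocateExtLengths(k, specs$ext_max[i], cfg$extDecay)
            if (k > 0L)
                lens <- lens[sample.int(k)]
            for (j in seq_along(carriers))
                carrierLen[[paste(specs$id[i], specs$ext_arm[i],
                                  specs$ext_end[i], carriers[j],
                                  sep = "|")]] <- lens[j]
            if (k > 0L)
                extDetail[[length(extDetail) + 1L]] <- data.frame(
                    precursor = specs$id[i], arm = specs$ext_arm[i],
                    end = specs$ext_end[i], cohort = coh,
                    sample = carriers, ext_len = lens,
                    stringsAsFactors = FALSE)
        }
    }

    subseq <- function(s, a, b) substr(chromSeq, a, b)
    revcomp <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))

    drawCount <- function(mu) {
        if (mu <= 0) return(0L)
        if (cfg$dispersion == 0)
            stats::rpois(1L, mu)
        else
            stats::rnbinom(1L, size = 1 / cfg$dispersion, mu = mu)
    }

    arfPaths <- stats::setNames(file.path(dir, paste0(samples, ".arf")),
                                samples)
    for (si in seq_along(samples)) {
        s <- samples[si]
        rows <- list()
        for (i in seq_len(nP)) {
            L <- specs$length[i]
            arms <- simArmCoords(L, specs$arm_len[i])
            armSet <- if (specs$two_arm[i]) c("5p", "3p") else "5p"
            for (arm in armSet) {
                fc <- if (arm == "5p") specs$fc_5p[i] else specs$fc_3p[i]
                mu <- cfg$depth * sf[si] * (if (isCase[si]) fc else 1)
                count <- drawCount(mu)
                if (count == 0L) next
                a <- arms[[arm]][1L]; b <- arms[[arm]][2L]
                key <- paste(specs$id[i], arm,
                             if (is.na(specs$ext_end[i])) "" else
                                 specs$ext_end[i], s, sep = "|")
                extLen <- if (!is.na(specs$ext_arm[i]) &&
                              specs$ext_arm[i] == arm)
                    carrierLen[[key]] else NULL
                nExt <- if (is.null(extLen)) 0L else
                    max(1L, ceiling(cfg$extReadFraction * count))
                nExt <- min(nExt, count)
                ivs <- matrix(rep(c(a, b), count), ncol = 2L, byrow = TRUE)
                if (nExt > 0L) {
                    idx <- seq_len(nExt)
                    if (specs$ext_end[i] == "three_prime")
                        ivs[idx, 2L] <- b + extLen
                    else
                        ivs[idx, 1L] <- a - extLen
                }
                rows[[length(rows) + 1L]] <-
                    cbind(prec = i, rs = ivs[, 1L], re = ivs[, 2L])
            }
            if (!specs$two_arm[i] && !is.na(specs$novel_len[i])) {
                mu <- cfg$depth * sf[si] *
                    (if (isCase[si]) specs$novel_fc[i] else 1)
                count <- drawCount(mu)
                if (count > 0L) {
                    arms3 <- simArmCoords(L, specs$novel_len[i])[["3p"]]
                    rows[[length(rows) + 1L]] <-
                        cbind(prec = i, rs = rep(arms3[1L], count),
                              re = rep(arms3[2L], count))
                }
            }
        }
        if (length(rows)) {
            m <- do.call(rbind, rows)
        } else {
            m <- matrix(integer(0), ncol = 3L,
                        dimnames = list(NULL, c("prec", "rs", "re")))
        }
        ## precursor-relative -> genomic, strand-aware
        i <- m[, "prec"]
        plus <- specs$strand[i] == "+"
        ps <- gStart[i]
        pe <- gStart[i] + specs$length[i] - 1L
        g1 <- ifelse(plus, ps + m[, "rs"] - 1L, pe - m[, "re"] + 1L)
        g2 <- ifelse(plus, ps + m[, "re"] - 1L, pe - m[, "rs"] + 1L)
        len <- g2 - g1 + 1L
        refSeq <- substring(chromSeq, g1, g2)
        if (any(!plus))
            refSeq[!plus] <- vapply(refSeq[!plus], revcomp, character(1L),
                                    USE.NAMES = FALSE)
        nR <- length(g1)
        rec <- data.frame(
            read_id = sprintf("%s_r%06d", s, seq_len(nR)),
            read_length = as.integer(len),
            read_start = rep(1L, nR), read_end = as.integer(len),
            read_seq = refSeq, ref_id = rep(chrom, nR),
            ref_length = rep(chromLen, nR),
            ref_start = as.integer(g1), ref_end = as.integer(g2),
            ref_seq = refSeq,
            strand = ifelse(plus, "+", "-"),
            n_mismatches = rep(0L, nR),
            edit_string = strrep("m", len),
            stringsAsFactors = FALSE)
        writeArf(rec, arfPaths[[s]])
    }

    writeSimAnnotation(specs, gStart, chrom, chromLen, chromSeq, dir)
    writeLines(paste(samples, groups, sep = "\t"),
               file.path(dir, "design.tsv"))
    writeLines(paste(samples, format(totals, scientific = FALSE,
                                     trim = TRUE), sep = "\t"),
               file.path(dir, "totals.tsv"))

    truthArms <- do.call(rbind, lapply(seq_len(nP), function(i) {
        arms <- if (specs$two_arm[i]) c("5p", "3p") else "5p"
        data.frame(precursor = specs$id[i],
                   name = sprintf("hsa-miR-%s-%s", specs$id[i], arms),
                   arm = arms,
                   fc = ifelse(arms == "5p", specs$fc_5p[i], specs$fc_3p[i]),
                   stringsAsFactors = FALSE)
    }))
    truthExt <- if (length(extDetail)) do.call(rbind, extDetail) else
        data.frame(precursor = character(0), arm = character(0),
                   end = character(0), cohort = character(0),
                   sample = character(0), ext_len = integer(0))
    novelIdx <- which(!specs$two_arm & !is.na(specs$novel_len))
    truthNovel <- do.call(rbind, c(list(
        data.frame(precursor = character(0), rel_start = integer(0),
                   rel_end = integer(0), length = integer(0),
                   fc = numeric(0))),
        lapply(novelIdx, function(i) {
            reg <- simArmCoords(specs$length[i], specs$novel_len[i])[["3p"]]
            data.frame(precursor = specs$id[i], rel_start = reg[1L],
                       rel_end = reg[2L], length = specs$novel_len[i],
                       fc = specs$novel_fc[i])
        })))
    utils::write.table(truthArms, file.path(dir, "truth_arms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truthExt, file.path(dir, "truth_ext.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truthNovel, file.path(dir, "truth_novel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    list(dir = dir, arf = arfPaths,
         gff = file.path(dir, "annotation.gff3"),
         hairpin = file.path(dir, "hairpin.fa"),
         mature = file.path(dir, "mature.fa"),
         design = file.path(dir, "design.tsv"),
         totals = file.path(dir, "totals.tsv"),
         samples = samples, groups = groups,
         truth = list(arms = truthArms, ext = truthExt, novel = truthNovel),
         config = cfg)
}

writeSimAnnotation <- function(specs, gStart, chrom, chromLen, chromSeq,
                               dir) {
    nP <- nrow(specs)
    gff <- c("##gff-version 3")
    hairpin <- character(0)
    mature <- character(0)
    revcomp <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (i in seq_len(nP)) {
        L <- specs$length[i]
        ps <- gStart[i]; pe <- ps + L - 1L
        strand <- specs$strand[i]
        pname <- sprintf("hsa-mir-%s", specs$id[i])
        pid <- sprintf("MI90%04d", i)
        gff <- c(gff, sprintf(
            "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
            chrom, ps, pe, strand, pid, pname))
        pseq <- substr(chromSeq, ps, pe)
        if (strand == "-") pseq <- revcomp(pseq)
        hairpin <- c(hairpin, paste0(">", pname), pseq)
        arms <- simArmCoords(L, specs$arm_len[i])
        armSet <- if (specs$two_arm[i]) c("5p", "3p") else "5p"
        for (arm in armSet) {
            a <- arms[[arm]][1L]; b <- arms[[arm]][2L]
            if (strand == "+") { ga <- ps + a - 1L; gb <- ps + b - 1L }
            else { ga <- pe - b + 1L; gb <- pe - a + 1L }
            mname <- sprintf("hsa-miR-%s-%s", specs$id[i], arm)
            mid <- sprintf("MIMAT90%04d%s", i, if (arm == "5p") "a" else "b")
            gff <- c(gff, sprintf(
                "%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
                chrom, ga, gb, strand, mid, mname, pid))
            mseq <- substr(pseq, a, b)  # precursor orientation
            mature <- c(mature, paste0(">", mname, " ", mid),
                        chartr("T", "U", mseq))
        }
    }
    writeLines(gff, file.path(dir, "annotation.gff3"))
    writeLines(hairpin, file.path(dir, "hairpin.fa"))
    writeLines(mature, file.path(dir, "mature.fa"))
    invisible(NULL)
}

#' Expected window percentages implied by a simulation truth table
#'
#' From the per-carrier extension lengths, the expected cohort window
#' percentage at window size w: 100 * sum(min(ext_len, w)) / (w * n).
#'
#' @param sim result of \code{\link{simulateStudy}}.
#' @param precursor,arm,end which arm end.
#' @param w window size.
#' @return named numeric c(pct_case, pct_control).
#' @export
truthWindowPct <- function(sim, precursor, arm, end, w) {
    ext <- sim$truth$ext
    n <- c(case = sim$config$nCase, control = sim$config$nControl)
    out <- c(pct_case = 0, pct_control = 0)
    for (coh in c("case", "control")) {
        sel <- ext$precursor == precursor & ext$arm == arm &
            ext$end == end & ext$cohort == coh
        val <- 100 * sum(pmin(ext$ext_len[sel], w)) / (w * n[[coh]])
        out[[paste0("pct_", coh)]] <- val
    }
    out
}

#' Benchmark study configurations
#'
#' Two ready-made simulation designs used by the package's benchmark
#' suite and the reproduction script:
#' \describe{
#'   \item{recovery}{10 + 10 samples, depth 200, 20 precursors of length
#'     80: ten two-arm precursors with 5p fold change 2.0 and 3p fold
#'     change 1.0 (the first three also carry a 3-base case-specific end
#'     shift on the 5p arm, 90\% of cases vs no controls), six
#'     single-arm precursors with a spiked 26 nt unannotated arm at 1.6x,
#'     and four clean single-arm precursors for specificity.}
#'   \item{window}{20 + 20 samples, depth 100, two two-arm precursors
#'     (one per strand), each with an isomiR end extension carried by
#'     60\% of cases vs 30\% of controls, maximum extension 4 nt with a
#'     decaying length profile.}
#' }
#'
#' @param type "recovery" or "window".
#' @param seed integer seed passed through to
#'   \code{\link{simulationConfig}}.
#' @return a \code{\link{simulationConfig}}.
#' @export
exampleStudyConfig <- function(type = c("recovery", "window"), seed) {
    type <- match.arg(type)
    if (type == "recovery") {
        specs <- defaultPrecursorSpecs(20L)
        specs$length <- 80L
        specs$arm_len <- 22L
        specs$fc_5p[1:10] <- 2.0
        specs$fc_3p[1:10] <- 1.0
        specs$ext_arm[1:3] <- "5p"
        specs$ext_end[1:3] <- "three_prime"
        specs$ext_p_case[1:3] <- 0.9
        specs$ext_p_control[1:3] <- 0.0
        specs$ext_max[1:3] <- 3L
        specs$two_arm[11:20] <- FALSE
        specs$novel_len[11:16] <- 26L
        specs$novel_fc[11:16] <- 1.6
        simulationConfig(nCase = 10L, nControl = 10L, precursors = specs,
                         depth = 200, seed = seed)
    } else {
        specs <- defaultPrecursorSpecs(2L)
        specs$length <- 80L
        specs$arm_len <- 22L
        specs$ext_arm <- c("5p", "3p")
        specs$ext_end <- c("three_prime", "five_prime")
        specs$ext_p_case <- 0.6
        specs$ext_p_control <- 0.3
        specs$ext_max <- 4L
        simulationConfig(nCase = 20L, nControl = 20L, precursors = specs,
                         depth = 100, seed = seed)
    }
}

#' Compare pipeline estimates with the simulation truth
#'
#' @param matureResults \code{DataFrame} from
#'   \code{\link{matureExpression}} run on the simulated study.
#' @param novelArms \code{DataFrame} from \code{\link{novelArmScan}}.
#' @param sim result of \code{\link{simulateStudy}}.
#' @return data.frame with one row per recovered parameter: parameter,
#'   type ("arm_fc", "novel_fc", "novel_length"), truth, estimate,
#'   rel_error (NA when the parameter was not recovered at all).
#' @export
truthCompare <- function(matureResults, novelArms, sim) {
    truth <- sim$truth
    m <- as.data.frame(matureResults)
    rows <- list()
    for (i in seq_len(nrow(truth$arms))) {
        est <- m$fold_change[match(truth$arms$name[i], m$feature_id)]
        rows[[length(rows) + 1L]] <- data.frame(
            parameter = paste0("fc:", truth$arms$name[i]), type = "arm_fc",
            truth = truth$arms$fc[i], estimate = est,
            stringsAsFactors = FALSE)
    }
    nv <- as.data.frame(novelArms)
    nvName <- sub("^MI90*", "", nv$precursor_id)
    for (i in seq_len(nrow(truth$novel))) {
        pn <- sprintf("hsa-mir-%s", truth$novel$precursor[i])
        j <- match(pn, nv$precursor_name)
        rows[[length(rows) + 1L]] <- data.frame(
            parameter = paste0("novel_fc:", pn), type = "novel_fc",
            truth = truth$novel$fc[i],
            estimate = if (is.na(j)) NA_real_ else nv$fold_change[j],
            stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            parameter = paste0("novel_length:", pn), type = "novel_length",
            truth = as.numeric(truth$novel$length[i]),
            estimate = if (is.na(j)) NA_real_ else as.numeric(nv$length[j]),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$rel_error <- (out$estimate - out$truth) / out$truth
    out
}
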