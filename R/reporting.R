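## Visual and tabular outputs. Every figure has a tab-delimited twin
## carrying exactly the plotted numbers; figures are never the only
## record of a result.

## -log10(p) plotting cap for p-value underflow (p = 0)
NEG_LOG10_CAP <- 320

## karyotype order used for the Manhattan x-axis
CHROM_ORDER <- c(paste0("chr", c(1:22, "X", "Y")), 1:22, "X", "Y")

## deterministic TSV writer: fixed column order, no quoting, C locale
## number formatting, so identical inputs give byte-identical files
writeTsv <- function(df, path) {
    df <- as.data.frame(df)
    for (j in seq_along(df)) {
        if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
            df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

openDevice <- function(path, fmt, width = 8, height = 5) {
    switch(fmt,
           pdf = grDevices::pdf(path, width = width, height = height,
                                useDingbats = FALSE),
           png = grDevices::png(path, width = width * 100,
                                height = height * 100),
           jpeg = grDevices::jpeg(path, width = width * 100,
                                  height = height * 100),
           stop("unsupported graphics format: ", fmt))
}

negLog10 <- function(p) {
    y <- -log10(p)
    y[!is.finite(y) | y > NEG_LOG10_CAP] <- NEG_LOG10_CAP
    y
}

#' Manhattan table and plot
#'
#' One point per tested miRNA feature: x in genome order (chromosomes
#' concatenated in karyotype order 1..22, X, Y; within a chromosome by
#' the precursor's annotated start), y the negative decade logarithm of
#' the p-value (capped at 320 for p-value underflow).
#'
#' @param results expression \code{DataFrame} (feature_id or
#'   precursor_id column locates each feature's precursor).
#' @param annotation a \code{\linkS4class{HairpinAnnotation}}.
#' @return \code{manhattanTable}: \code{DataFrame} with mirna_key,
#'   chrom, genomic_position, p_value, neg_log10_p, sorted in plotting
#'   order. \code{plotManhattan}: the figure path, invisibly; the TSV
#'   twin is written next to it.
#' @export
manhattanTable <- function(results, annotation) {
    prec <- annotation@precursors
    pid <- if ("precursor_id" %in% colnames(results))
        results$precursor_id else results$feature_id
    idx <- match(pid, mcols(prec)$precursor_id)
    keep <- !is.na(idx)
    results <- results[keep, , drop = FALSE]
    idx <- idx[keep]
    tab <- DataFrame(mirna_key = results$feature_id,
                     chrom = as.character(seqnames(prec))[idx],
                     genomic_position = start(prec)[idx],
                     p_value = results$p_value,
                     neg_log10_p = negLog10(results$p_value))
    ord <- order(match(tab$chrom, CHROM_ORDER), tab$genomic_position)
    tab[ord, ]
}

#' @rdname manhattanTable
#' @param path output figure path (its extension should match
#'   \code{fmt}).
#' @param fmt "pdf", "png" or "jpeg".
#' @param main plot title.
#' @export
plotManhattan <- function(results, annotation, path, fmt = "pdf",
                          main = "Expression analysis") {
    tab <- manhattanTable(results, annotation)
    writeTsv(as.data.frame(tab), paste0(path, ".tsv"))
    chrom <- factor(tab$chrom, levels = unique(tab$chrom))
    x <- seq_len(nrow(tab))
    openDevice(path, fmt)
    on.exit(grDevices::dev.off())
    graphics::plot(x, tab$neg_log10_p, pch = 19, cex = 0.7,
                   col = c("grey30", "steelblue")[
                       (as.integer(chrom) %% 2L) + 1L],
                   xlab = "genomic order", xaxt = "n",
                   ylab = expression(-log[10](p)), main = main)
    mids <- tapply(x, chrom, stats::median)
    graphics::axis(1, at = mids, labels = levels(chrom), las = 2,
                   cex.axis = 0.7)
    invisible(path)
}

#' Per-base significance bar plot
#'
#' One bar per precursor position, height -log10(p); red bars mark
#' up-regulation in cases, green bars down-regulation in cases,
#' grey bars non-significant positions.
#'
#' @param perBase one element of \code{perBaseExpression()$positions}.
#' @param path output figure path.
#' @param fmt "pdf", "png" or "jpeg".
#' @param main plot title.
#' @return the figure path, invisibly; a TSV twin is written alongside.
#' @export
plotPerBaseBars <- function(perBase, path, fmt = "pdf",
                            main = "Per-base significance") {
    df <- as.data.frame(perBase)
    df$neg_log10_p <- negLog10(df$p_value)
    writeTsv(df, paste0(path, ".tsv"))
    col <- ifelse(df$direction == "up_in_cases", "red3",
                  ifelse(df$direction == "down_in_cases", "green4", "grey70"))
    openDevice(path, fmt)
    on.exit(grDevices::dev.off())
    graphics::barplot(df$neg_log10_p, col = col, border = NA,
                      names.arg = df$position, las = 2, cex.names = 0.5,
                      xlab = "precursor position",
                      ylab = expression(-log[10](p)), main = main)
    invisible(path)
}

#' Read-distribution line plot along one precursor
#'
#' One polyline per sample over precursor positions 1..L of RPM
#' coverage; red lines are cases, green lines controls.
#'
#' @param pc a \code{\linkS4class{PrecursorCoverage}} (RPM filled).
#' @param design a \code{\linkS4class{StudyDesign}}.
#' @param path output figure path.
#' @param fmt "pdf", "png" or "jpeg".
#' @param main plot title.
#' @return the figure path, invisibly; a TSV twin (long format:
#'   sample, group, position, rpm) is written alongside.
#' @export
plotReadDistribution <- function(pc, design, path, fmt = "pdf",
                                 main = "Read distribution") {
    m <- pc@rpm
    if (!length(m))
        stop("coverage has not been RPM-normalized")
    L <- ncol(m)
    samples <- rownames(m)
    grp <- ifelse(samples %in% caseSamples(design), "case", "control")
    long <- data.frame(sample = rep(samples, each = L),
                       group = rep(grp, each = L),
                       position = rep(seq_len(L), times = length(samples)),
                       rpm = as.vector(t(m)))
    writeTsv(long, paste0(path, ".tsv"))
    openDevice(path, fmt)
    on.exit(grDevices::dev.off())
    graphics::plot(NA, xlim = c(1, L), ylim = c(0, max(m, 1)),
                   xlab = "precursor position", ylab = "coverage (RPM)",
                   main = main)
    for (i in seq_along(samples))
        graphics::lines(seq_len(L), m[i, ],
                        col = if (grp[i] == "case") "red3" else "green4")
    graphics::legend("topright", legend = c("case", "control"),
                     col = c("red3", "green4"), lty = 1, bty = "n")
    invisible(path)
}

#' Text pileup rendering of per-sample coverage
#'
#' Per sample, a row showing at each precursor position the precursor
#' base when that sample has at least one read covering it, and a blank
#' otherwise (a per-sample consensus in the absence of allele calling:
#' arf edit strings record only match/mismatch). Case rows come first,
#' then the precursor sequence line, then an arm line marking annotated
#' mature spans (5 / 3), then control rows. Samples without a single
#' mapped read get no row. Without a hairpin sequence, covered positions
#' are shown as "#".
#'
#' @param pc a \code{\linkS4class{PrecursorCoverage}}.
#' @param annotation a \code{\linkS4class{HairpinAnnotation}}.
#' @param design a \code{\linkS4class{StudyDesign}}.
#' @return named character vector of fixed-width lines (names: sample
#'   ids, "precursor", "arms"); byte-stable for fixed input.
#' @export
pileupText <- function(pc, annotation, design) {
    L <- ncol(pc@raw)
    precIds <- mcols(annotation@precursors)$precursor_id
    i <- match(pc@precursorId, precIds)
    pn <- mcols(annotation@precursors)$name[i]
    seq <- if (length(annotation@seqs) && pn %in% names(annotation@seqs))
        strsplit(as.character(annotation@seqs[[pn]]), "")[[1L]]
    else rep("#", L)
    rel <- armRelativeCoords(annotation)
    rel <- rel[rel$precursor_id == pc@precursorId, , drop = FALSE]
    armLine <- rep(".", L)
    for (k in seq_len(nrow(rel))) {
        span <- rel$rel_start[k]:rel$rel_end[k]
        armLine[span] <- if (rel$arm_label[k] == "5p") "5" else "3"
    }
    rowFor <- function(s) {
        chars <- ifelse(pc@raw[s, ] >= 1L, seq, " ")
        paste(chars, collapse = "")
    }
    hasRead <- rowSums(pc@raw >= 1L) > 0
    cs <- intersect(caseSamples(design), rownames(pc@raw)[hasRead])
    ct <- intersect(controlSamples(design), rownames(pc@raw)[hasRead])
    out <- c(vapply(cs, rowFor, character(1L)),
             precursor = paste(seq, collapse = ""),
             arms = paste(armLine, collapse = ""),
             vapply(ct, rowFor, character(1L)))
    out
}

#' Pileup figure with text twin
#'
#' Renders \code{\link{pileupText}} graphically: cases above the
#' precursor sequence line, controls below, annotated mature spans
#' shaded (5p red, 3p blue). The identical-content text rendering is
#' written next to the figure for exact comparison.
#'
#' @inheritParams pileupText
#' @param path output figure path.
#' @param fmt "pdf", "png" or "jpeg".
#' @return the figure path, invisibly; the text twin is written to
#'   \code{paste0(path, ".txt")}.
#' @export
plotPileup <- function(pc, annotation, design, path, fmt = "pdf") {
    txt <- pileupText(pc, annotation, design)
    writeLines(paste(format(names(txt), width = 12), txt, sep = "  "),
               paste0(path, ".txt"))
    L <- ncol(pc@raw)
    n <- length(txt)
    rel <- armRelativeCoords(annotation)
    rel <- rel[rel$precursor_id == pc@precursorId, , drop = FALSE]
    openDevice(path, fmt, width = max(6, L / 12), height = max(3, n / 6))
    on.exit(grDevices::dev.off())
    graphics::plot(NA, xlim = c(0, L + 1), ylim = c(0, n + 1), xlab = "",
                   ylab = "", axes = FALSE,
                   main = paste("Pileup", pc@precursorId))
    seqRow <- which(names(txt) == "precursor")
    for (k in seq_len(nrow(rel))) {
        col <- if (rel$arm_label[k] == "5p")
            grDevices::adjustcolor("red3", 0.2)
        else grDevices::adjustcolor("steelblue", 0.25)
        graphics::rect(rel$rel_start[k] - 0.5, 0.5, rel$rel_end[k] + 0.5,
                       n + 0.5, col = col, border = NA)
    }
    for (i in seq_len(n)) {
        chars <- strsplit(txt[i], "")[[1L]]
        y <- n - i + 1
        show <- which(chars != " ")
        if (length(show))
            graphics::text(show, y, chars[show], cex = 0.45, family = "mono",
                           col = if (names(txt)[i] %in% c("precursor", "arms"))
                               "black" else "grey25")
    }
    invisible(path)
}

#' Bundle every result file into a compressed archive
#'
#' Collects all figures and tab-delimited tables of a study directory
#' into a gzip-compressed tar archive with a deterministic manifest
#' (MANIFEST.txt, one relative path per line, sorted).
#'
#' @param studyDir directory holding the study outputs.
#' @param archive output archive path (default
#'   \code{<studyDir>/bundle.tar.gz}).
#' @return the archive path, invisibly.
#' @export
exportBundle <- function(studyDir,
                         archive = file.path(studyDir, "bundle.tar.gz")) {
    files <- sort(list.files(studyDir, recursive = TRUE))
    files <- setdiff(files, basename(archive))
    manifest <- file.path(studyDir, "MANIFEST.txt")
    writeLines(sort(c(files, "MANIFEST.txt")), manifest)
    files <- sort(c(files, "MANIFEST.txt"))
    old <- setwd(studyDir)
    on.exit(setwd(old))
    utils::tar(basename(archive), files = files, compression = "gzip",
               tar = "internal")
    invisible(archive)
}
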