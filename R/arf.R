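## miRDeep2 arf alignment format: 13 tab-separated columns per line:
## read id, read length, read start, read end, read sequence,
## reference id, reference length, reference start, reference end,
## reference sequence, strand, number of mismatches, edit string
## (per aligned base: m = match, M = mismatch). Coordinates are 1-based
## inclusive. No R package reads this format, so the parser lives here.

ARF_COLUMNS <- c("read_id", "read_length", "read_start", "read_end",
                 "read_seq", "ref_id", "ref_length", "ref_start", "ref_end",
                 "ref_seq", "strand", "n_mismatches", "edit_string")
ARF_INT_COLUMNS <- c("read_length", "read_start", "read_end", "ref_length",
                     "ref_start", "ref_end", "n_mismatches")

#' Read a miRDeep2 arf alignment file
#'
#' Parses the 13-column tab-separated arf format into a data.frame with
#' one validated alignment record per line (line order preserved). Empty
#' lines are skipped.
#'
#' @param path path to an arf file.
#' @return data.frame with columns \code{read_id}, \code{read_length},
#'   \code{read_start}, \code{read_end}, \code{read_seq}, \code{ref_id},
#'   \code{ref_length}, \code{ref_start}, \code{ref_end}, \code{ref_seq},
#'   \code{strand}, \code{n_mismatches}, \code{edit_string}.
#' @details Validation enforces, per record: end >= start on both read and
#'   reference, strand in \{+, -\}, edit string length equal to the
#'   reference span, and the mismatch count equal to the number of
#'   mismatch codes ("M") in the edit string. Violations raise errors
#'   naming the offending line.
#' @export
#' @examples
#' arf <- tempfile(fileext = ".arf")
#' writeLines(paste("r1", 4, 1, 4, "ACGT", "chr1", 1000, 11, 14, "ACGT",
#'                  "+", 0, "mmmm", sep = "\t"), arf)
#' readArf(arf)
readArf <- function(path) {
    if (!file.exists(path))
        stop("arf file does not exist: ", path)
    lines <- readLines(path)
    keep <- nzchar(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        df <- as.data.frame(stats::setNames(
            rep(list(character(0)), length(ARF_COLUMNS)), ARF_COLUMNS))
        for (cc in ARF_INT_COLUMNS) df[[cc]] <- integer(0)
        return(df)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 13L)) {
        bad <- which(nf != 13L)[1L]
        stop(sprintf("arf parse error at line %d: expected 13 tab-separated fields, found %d",
                     lineno[bad], nf[bad]))
    }
    m <- matrix(unlist(fields, use.names = FALSE), ncol = 13L, byrow = TRUE)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    colnames(df) <- ARF_COLUMNS
    for (cc in ARF_INT_COLUMNS) {
        v <- suppressWarnings(as.integer(df[[cc]]))
        if (anyNA(v)) {
            bad <- which(is.na(v))[1L]
            stop(sprintf("arf parse error at line %d: non-numeric value '%s' in column %s",
                         lineno[bad], df[[cc]][bad], cc))
        }
        df[[cc]] <- v
    }
    validateArf(df, lineno)
    df
}

validateArf <- function(df, lineno = seq_len(nrow(df))) {
    fail <- function(idx, what)
        stop(sprintf("arf validation error at line %d: %s", lineno[idx], what))
    bad <- which(!df$strand %in% c("+", "-"))
    if (length(bad)) fail(bad[1L], paste0("invalid strand '", df$strand[bad[1L]], "'"))
    bad <- which(df$read_end < df$read_start)
    if (length(bad)) fail(bad[1L], "read_end < read_start")
    bad <- which(df$ref_end < df$ref_start)
    if (length(bad)) fail(bad[1L], "ref_end < ref_start")
    bad <- which(df$read_length < 1L | df$ref_length < 1L)
    if (length(bad)) fail(bad[1L], "non-positive read or reference length")
    bad <- which(df$n_mismatches < 0L)
    if (length(bad)) fail(bad[1L], "negative mismatch count")
    span <- df$ref_end - df$ref_start + 1L
    bad <- which(nchar(df$edit_string) != span)
    if (length(bad)) fail(bad[1L],
        "edit string length does not equal the reference span")
    nM <- nchar(df$edit_string) - nchar(gsub("M", "", df$edit_string, fixed = TRUE))
    bad <- which(nM != df$n_mismatches)
    if (length(bad)) fail(bad[1L],
        "mismatch count does not equal the number of mismatch codes in the edit string")
    invisible(df)
}

#' Write alignment records back to arf
#'
#' Inverse of \code{\link{readArf}}: writing and re-reading yields an
#' identical data.frame.
#'
#' @param records data.frame as returned by \code{readArf}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeArf <- function(records, path) {
    stopifnot(identical(colnames(records), ARF_COLUMNS))
    lines <- do.call(paste, c(lapply(records, as.character), sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Alignment records as genomic ranges
#'
#' @param records data.frame from \code{\link{readArf}}.
#' @param sample optional sample identifier stored as a metadata column.
#' @return GRanges over the reference coordinates with strand; metadata
#'   columns \code{read_id} and (if given) \code{sample}.
#' @export
arfToGRanges <- function(records, sample = NULL) {
    gr <- GRanges(seqnames = records$ref_id,
                  ranges = IRanges(records$ref_start, records$ref_end),
                  strand = records$strand)
    mcols(gr)$read_id <- records$read_id
    if (!is.null(sample))
        mcols(gr)$sample <- sample
    gr
}
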