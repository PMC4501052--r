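#' Read miRBase precursor/mature annotation from GFF3
#'
#' Parses a miRBase-dialect GFF3 (feature types
#' \code{miRNA_primary_transcript} and \code{miRNA}, attributes ID, Name,
#' Derives_from), keeps only entries of one organism, attaches mature
#' arms to their parent precursors and assigns 5p/3p arm labels.
#'
#' @param path GFF3 file.
#' @param organismPrefix keep precursors whose Name starts with this
#'   prefix (default "hsa": human entries only).
#' @param hairpinFasta optional FASTA of hairpin sequences named by
#'   precursor name; needed for pileup sequence rendering and end motifs.
#' @return A \code{\linkS4class{HairpinAnnotation}}.
#' @details Arm labels come from a \code{-5p}/\code{-3p} suffix on the
#'   mature name when present; otherwise the arm whose midpoint lies in
#'   the 5' half of the precursor (strand-aware) is labeled 5p. Mature
#'   rows whose Derives_from points to no retained precursor are skipped
#'   with a warning; duplicated precursor IDs are an error.
#' @export
readMirbaseGff <- function(path, organismPrefix = "hsa", hairpinFasta = NULL) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (!length(gr))
        return(new("HairpinAnnotation", precursors = emptyPrecursorGR(),
                   arms = emptyArmGR(), seqs = DNAStringSet()))
    type <- as.character(gr$type)
    prec <- gr[type == "miRNA_primary_transcript"]
    mat <- gr[type == "miRNA"]

    keep <- startsWith(as.character(mcols(prec)$Name),
                       paste0(organismPrefix, "-"))
    prec <- prec[keep]
    pid <- as.character(mcols(prec)$ID)
    if (anyDuplicated(pid))
        stop("duplicate precursor IDs in GFF3: ",
             paste(unique(pid[duplicated(pid)]), collapse = ", "))

    precursors <- GRanges(seqnames(prec), IRanges(start(prec), end(prec)),
                          strand = strand(prec))
    mcols(precursors)$precursor_id <- pid
    mcols(precursors)$name <- as.character(mcols(prec)$Name)

    parent <- as.character(mcols(mat)$Derives_from)
    hit <- match(parent, pid)
    orphan <- is.na(hit) &
        startsWith(as.character(mcols(mat)$Name), paste0(organismPrefix, "-"))
    if (any(orphan))
        warning("skipping ", sum(orphan),
                " mature row(s) with unknown parent precursor: ",
                paste(utils::head(as.character(mcols(mat)$Name)[orphan], 5L),
                      collapse = ", "))
    mat <- mat[!is.na(hit)]
    hit <- hit[!is.na(hit)]

    arms <- GRanges(seqnames(mat), IRanges(start(mat), end(mat)),
                    strand = strand(precursors)[hit])
    mcols(arms)$mature_id <- as.character(mcols(mat)$ID)
    mcols(arms)$name <- as.character(mcols(mat)$Name)
    mcols(arms)$precursor_id <- pid[hit]
    mcols(arms)$arm_label <- assignArmLabels(arms, precursors, hit)

    seqs <- DNAStringSet()
    if (!is.null(hairpinFasta)) {
        seqs <- readHairpinFasta(hairpinFasta, organismPrefix)
        seqs <- seqs[names(seqs) %in% mcols(precursors)$name]
    }
    new("HairpinAnnotation", precursors = precursors, arms = arms,
        seqs = seqs)
}

emptyPrecursorGR <- function() {
    g <- GRanges()
    mcols(g)$precursor_id <- character(0)
    mcols(g)$name <- character(0)
    g
}

emptyArmGR <- function() {
    g <- GRanges()
    mcols(g)$mature_id <- character(0)
    mcols(g)$name <- character(0)
    mcols(g)$precursor_id <- character(0)
    mcols(g)$arm_label <- character(0)
    g
}

## 5p/3p from the name suffix when present, else strand-aware midpoint:
## an arm whose midpoint falls in the 5' half of the hairpin is 5p.
assignArmLabels <- function(arms, precursors, hit) {
    nm <- mcols(arms)$name
    lab <- rep(NA_character_, length(arms))
    lab[grepl("-5p$", nm)] <- "5p"
    lab[grepl("-3p$", nm)] <- "3p"
    todo <- which(is.na(lab))
    if (length(todo)) {
        p <- precursors[hit[todo]]
        mid <- (start(arms)[todo] + end(arms)[todo]) / 2
        pmid <- (start(p) + end(p)) / 2
        plus <- as.character(strand(p)) != "-"
        lab[todo] <- ifelse(plus == (mid <= pmid), "5p", "3p")
    }
    lab
}

#' Read miRBase mature sequences
#'
#' Reads mature.fa (all organisms, RNA alphabet), keeps one organism and
#' returns DNA sequences (U converted to T) so they are directly
#' comparable with sequencing reads.
#'
#' @param path FASTA file of mature miRNA sequences.
#' @param organismPrefix keep entries whose header starts with this
#'   prefix (default "hsa").
#' @return A named \code{DNAStringSet}; names are the first token of each
#'   FASTA header. Duplicate headers keep the first entry with a warning.
#' @export
readMatureFasta <- function(path, organismPrefix = "hsa") {
    ss <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(ss))
    keep <- startsWith(nm, paste0(organismPrefix, "-"))
    ss <- ss[keep]
    nm <- nm[keep]
    if (anyDuplicated(nm)) {
        warning("duplicate FASTA headers, keeping first occurrence: ",
                paste(unique(nm[duplicated(nm)]), collapse = ", "))
        ss <- ss[!duplicated(nm)]
        nm <- nm[!duplicated(nm)]
    }
    seqs <- chartr("Uu", "Tt", toupper(as.character(ss)))
    out <- DNAStringSet(seqs)
    names(out) <- nm
    out
}

readHairpinFasta <- function(path, organismPrefix = "hsa") {
    ss <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(ss))
    keep <- startsWith(nm, paste0(organismPrefix, "-"))
    ss <- ss[keep]
    out <- DNAStringSet(chartr("Uu", "Tt", toupper(as.character(ss))))
    names(out) <- nm[keep]
    out
}

#' Map a genomic interval into precursor-relative coordinates
#'
#' Position 1 is the precursor's 5' end: for minus-strand precursors the
#' genomic end maps to position 1.
#'
#' @param refStart,refEnd 1-based inclusive genomic interval of an
#'   alignment (vectors recycle).
#' @param precStart,precEnd genomic interval of the precursor.
#' @param precStrand "+" or "-".
#' @return A two-column matrix (start, end) of 1-based precursor
#'   positions, one row per input interval; rows are NA when the
#'   alignment does not overlap the precursor.
#' @export
#' @examples
#' mapToPrecursor(100, 121, 100, 180, "+")  # positions 1..22
#' mapToPrecursor(159, 180, 100, 180, "-")  # positions 1..22
mapToPrecursor <- function(refStart, refEnd, precStart, precEnd, precStrand) {
    o1 <- pmax(refStart, precStart)
    o2 <- pmin(refEnd, precEnd)
    none <- o1 > o2
    if (identical(precStrand, "-") || all(precStrand == "-")) {
        rs <- precEnd - o2 + 1L
        re <- precEnd - o1 + 1L
    } else if (all(precStrand == "+")) {
        rs <- o1 - precStart + 1L
        re <- o2 - precStart + 1L
    } else {
        minus <- precStrand == "-"
        rs <- ifelse(minus, precEnd - o2 + 1L, o1 - precStart + 1L)
        re <- ifelse(minus, precEnd - o1 + 1L, o2 - precStart + 1L)
    }
    rs[none] <- NA_integer_
    re[none] <- NA_integer_
    cbind(start = as.integer(rs), end = as.integer(re))
}

## precursor-relative coordinates of every arm, keyed by mature_id
armRelativeCoords <- function(annotation) {
    arms <- annotation@arms
    prec <- annotation@precursors
    idx <- match(mcols(arms)$precursor_id, mcols(prec)$precursor_id)
    rel <- mapToPrecursor(start(arms), end(arms),
                          start(prec)[idx], end(prec)[idx],
                          as.character(strand(prec))[idx])
    data.frame(mature_id = mcols(arms)$mature_id,
               name = mcols(arms)$name,
               precursor_id = mcols(arms)$precursor_id,
               arm_label = mcols(arms)$arm_label,
               rel_start = rel[, "start"], rel_end = rel[, "end"],
               stringsAsFactors = FALSE)
}
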