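#' @include utils.R
NULL

#' GC ratio of a sequence
#'
#' Fraction of G and C bases, in `[0, 1]`.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @return numeric fraction.
#' @examples
#' gcRatio("ACGT")  # 0.5
#' @export
gcRatio <- function(seq) {
    s <- .asSeqChar(seq)
    if (nchar(s) == 0L)
        stop("undefined metric: empty sequence")
    d <- Biostrings::DNAString(s)
    sum(Biostrings::letterFrequency(d, c("G", "C"))) / nchar(s)
}

#' Longest homopolymer run
#'
#' Length in nt of the longest run of a single base.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @return integer run length.
#' @examples
#' longestHomopolymer("GCTTTTTTAG")  # 6
#' @export
longestHomopolymer <- function(seq) {
    s <- .asSeqChar(seq)
    if (nchar(s) == 0L)
        stop("undefined metric: empty sequence")
    .longestRun(s)
}

#' Composition statistics for a set of sequences
#'
#' One row per sequence: id, length, GC ratio and longest homopolymer.
#'
#' @param seqs a [Biostrings::DNAStringSet], named character vector, or
#'   FASTA path.
#' @return data.frame with columns `id`, `length`, `gc_ratio`,
#'   `longest_homopolymer`.
#' @examples
#' seqStatsTable(c(a = "ACGT", b = "GCTTTTTTAG"))
#' @export
seqStatsTable <- function(seqs) {
    if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
        seqs <- readSequences(seqs)
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    ids <- if (is.null(names(seqs)))
        sprintf("seq_%d", seq_along(seqs) - 1L) else names(seqs)
    chars <- as.character(seqs)
    data.frame(
        id = ids,
        length = nchar(chars),
        gc_ratio = vapply(chars, gcRatio, numeric(1), USE.NAMES = FALSE),
        longest_homopolymer = vapply(chars, longestHomopolymer, integer(1),
                                     USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
}

#' Export a sequence as a base heat-map table
#'
#' Writes a TSV matrix mapping A/C/G/T to 0-3 after wrapping the sequence
#' row-major to `nCols` columns (a presentation aid for heat-map rendering;
#' the final partial row, if any, is dropped).
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param path output TSV path.
#' @param nCols wrap width.
#' @return invisibly, `path`.
#' @export
writeBaseHeatmapTSV <- function(seq, path, nCols = 128L) {
    s <- .asSeqChar(seq)
    codes <- match(.seqChars(s), .BASES) - 1L
    n <- (length(codes) %/% nCols) * nCols
    m <- matrix(codes[seq_len(n)], ncol = nCols, byrow = TRUE)
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}
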