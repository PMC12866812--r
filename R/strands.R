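#' @include codec.R
NULL

## Fixed strand layout (nt): forward primer 20, index 8, payload <= 57,
## reverse primer 21; a full strand is 106 nt.
.FORWARD_PRIMER <- "ACACGACGCTCTTCCGATCT"
.REVERSE_PRIMER <- "AGATCGGAAGAGCACACGTCT"
.INDEX_LEN <- 8L
.PAYLOAD_LEN <- 57L

#' Strand layout constants
#'
#' The fixed regions of a sequencing-ready strand: 20-nt forward primer
#' binding region, 8-nt index, up to 57-nt payload, 21-nt reverse primer
#' binding region (106 nt for a full strand).
#'
#' @return named character vector with elements `forward` and `reverse`.
#' @examples primerRegions()
#' @export
primerRegions <- function() {
    c(forward = .FORWARD_PRIMER, reverse = .REVERSE_PRIMER)
}

#' Split an encoded sequence into sequencing-ready strands
#'
#' Splits the payload sequence into consecutive chunks (the final chunk may
#' be short) and flanks each with the fixed primer regions and an 8-nt
#' index: the 16-bit big-endian chunk ordinal, simple-mapped to 4 bases per
#' byte boundary. Full chunks yield 106-nt strands.
#'
#' @param payload encoded sequence (character or [Biostrings::DNAString]).
#' @param chunk chunk length in nt (default 57).
#' @param prefix name prefix for the strand ids (`<prefix>_<ordinal>`).
#' @return a [Biostrings::DNAStringSet] of strands, with `mcols` columns
#'   `ordinal` (0-based) and `payloadWidth`.
#' @examples
#' st <- assembleStrands(encodeSequence(randomBits(400), "R0-B9"))
#' Biostrings::width(st)
#' @export
assembleStrands <- function(payload, chunk = .PAYLOAD_LEN, prefix = "strand") {
    s <- .asSeqChar(payload)
    if (chunk < 1L)
        stop("chunk must be >= 1")
    if (nchar(s) == 0L)
        stop("empty payload: nothing to assemble")
    starts <- seq(1L, nchar(s), by = chunk)
    nStrand <- length(starts)
    if (nStrand > 65535L)
        stop("index overflow: more than 65535 chunks")
    chunks <- substring(s, starts, pmin(starts + chunk - 1L, nchar(s)))
    ordinals <- seq_len(nStrand) - 1L
    indexSeq <- vapply(ordinals, function(i) {
        bits <- as.integer(intToBits(i)[16:1])    # 16-bit big-endian ordinal
        as.character(simpleMap(bits))
    }, character(1))
    strands <- Biostrings::DNAStringSet(
        paste0(.FORWARD_PRIMER, indexSeq, chunks, .REVERSE_PRIMER))
    names(strands) <- sprintf("%s_%d", prefix, ordinals)
    S4Vectors::mcols(strands) <- S4Vectors::DataFrame(
        ordinal = ordinals, payloadWidth = nchar(chunks))
    strands
}

#' Extract strand regions
#'
#' Accessors for the fixed-layout regions of strands built by
#' [assembleStrands()]: forward primer (nt 1-20), index (21-28), payload
#' (29 to width-21) and reverse primer (last 21 nt).
#'
#' @param strands a [Biostrings::DNAStringSet] of strands.
#' @return a [Biostrings::DNAStringSet] with the requested region, except
#'   `strandOrdinal`, which decodes the index region back to its integer
#'   ordinal.
#' @examples
#' st <- assembleStrands(encodeSequence(randomBits(400), "R0-B9"))
#' strandOrdinal(st)
#' @export
strandPayload <- function(strands) {
    Biostrings::subseq(strands, start = 21L + .INDEX_LEN,
                       end = Biostrings::width(strands) - 21L)
}

#' @rdname strandPayload
#' @export
strandIndex <- function(strands) {
    Biostrings::subseq(strands, start = 21L, width = .INDEX_LEN)
}

#' @rdname strandPayload
#' @export
strandOrdinal <- function(strands) {
    vapply(as.character(strandIndex(strands)), function(s) {
        sum(simpleUnmap(s) * 2L^(15:0))
    }, numeric(1), USE.NAMES = FALSE)
}

#' Positional sequence identity percentage
#'
#' Compares a read against its reference position by position and returns
#' `100 * matches / reference length`. Unequal lengths are compared over
#' the shorter sequence and the length difference counts as errors (the
#' fixed strand layout makes alignment unnecessary).
#'
#' @param read read sequence (character or [Biostrings::DNAString]).
#' @param reference reference sequence.
#' @return identity percentage on the 0-100 scale.
#' @examples
#' sequenceIdentity("ACGTT", "ACGTA")  # 80
#' @export
sequenceIdentity <- function(read, reference) {
    r <- .asSeqChar(read)
    ref <- .asSeqChar(reference)
    if (nchar(ref) == 0L)
        stop("undefined metric: empty reference")
    if (nchar(r) == 0L)
        stop("undefined metric: empty read")
    n <- min(nchar(r), nchar(ref))
    matches <- sum(.seqChars(substr(r, 1L, n)) ==
                   .seqChars(substr(ref, 1L, n)))
    100 * matches / nchar(ref)
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that picks the format
#' from the file extension (`.fastq`/`.fq` read as FASTQ, qualities
#' dropped; anything else as FASTA).
#'
#' @param path input file.
#' @return a [Biostrings::DNAStringSet].
#' @export
readSequences <- function(path) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
        "fastq" else "fasta"
    Biostrings::readDNAStringSet(path, format = fmt)
}

#' Write sequences to FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet], [Biostrings::DNAString] or
#'   named character vector.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
    if (is(seqs, "XString"))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("seq_%d", seq_along(seqs) - 1L)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}
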