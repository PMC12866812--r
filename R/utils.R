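## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

## Coerce a bit payload to an integer 0/1 vector. Accepts an integer/numeric
## /logical vector or a single character string such as "1110011100".
.asBits <- function(bits) {
    if (is.character(bits)) {
        if (length(bits) != 1L)
            stop("a character bit string must be a single string")
        if (nchar(bits) == 0L)
            return(integer(0))
        ch <- strsplit(bits, "", fixed = TRUE)[[1L]]
        bad <- !(ch %in% c("0", "1"))
        if (any(bad))
            stop("invalid alphabet: bit strings may contain only 0 and 1 (found '",
                 ch[which(bad)[1L]], "')")
        return(as.integer(ch == "1"))
    }
    if (is.logical(bits))
        return(as.integer(bits))
    b <- as.integer(bits)
    if (anyNA(b) || any(b != 0L & b != 1L))
        stop("invalid alphabet: bit strings may contain only 0 and 1")
    b
}

.bitsToString <- function(bits) paste(bits, collapse = "")

## Coerce a DNA sequence to a plain uppercase character scalar over ACGT.
.asSeqChar <- function(seq) {
    if (is(seq, "XString") || is(seq, "XStringSet")) {
        if (is(seq, "XStringSet")) {
            if (length(seq) != 1L)
                stop("expected a single sequence")
            seq <- seq[[1L]]
        }
        seq <- as.character(seq)
    }
    if (!is.character(seq) || length(seq) != 1L)
        stop("expected a single DNA sequence (character or DNAString)")
    seq <- toupper(seq)
    if (nchar(seq) > 0L && grepl("[^ACGT]", seq))
        stop("invalid alphabet: sequence must be over {A,C,G,T}")
    seq
}

.seqChars <- function(seq) {
    if (nchar(seq) == 0L) character(0) else strsplit(seq, "", fixed = TRUE)[[1L]]
}

## Longest run of any single character (0 for the empty string).
.longestRun <- function(seq) {
    ch <- .seqChars(seq)
    if (length(ch) == 0L) return(0L)
    max(rle(ch)$lengths)
}

.lastBase <- function(unit) substr(unit, nchar(unit), nchar(unit))
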