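#' @include ruleTables.R bits.R
NULL

#' Encode a binary payload as a constrained DNA sequence
#'
#' Converts the payload to base-B digits with [bitsToDigits()] (guard bit
#' per the table) and emits the initiator followed by one encoding unit per
#' digit, each chosen from the table row of the current context (the last
#' emitted base). The emitted sequence respects the table's homopolymer
#' limit. For the positional `simple` scheme this reduces to [simpleMap()].
#'
#' @param bits payload bits (0/1 vector or a single "01" string).
#' @param table a [RuleTable], or a scheme id accepted by [buildRuleTable()].
#' @return a [Biostrings::DNAString] with the encoded sequence.
#' @examples
#' encodeSequence("1110011100", buildRuleTable("RInf-B4", guard = FALSE))
#' @seealso [decodeSequence()]
#' @export
encodeSequence <- function(bits, table) {
    if (!is(table, "RuleTable"))
        table <- buildRuleTable(table)
    if (nchar(table@initiator) == 0L)          # positional simple mapping
        return(simpleMap(bits))
    digits <- bitsToDigits(bits, table@radix, table@guard)
    unitMat <- do.call(rbind, table@rows[.BASES])   # 4 x radix lookup
    lastOf <- if (table@unitLen == 1L) unitMat else
        matrix(substr(unitMat, 2L, 2L), nrow = 4L,
               dimnames = dimnames(unitMat))
    units <- character(length(digits))
    ctx <- match(.lastBase(table@initiator), .BASES)
    for (k in seq_along(digits)) {
        u <- unitMat[ctx, digits[k] + 1L]
        units[k] <- u
        ctx <- match(lastOf[ctx, digits[k] + 1L], .BASES)
    }
    Biostrings::DNAString(paste0(table@initiator, paste(units, collapse = "")))
}

#' Decode a constrained DNA sequence back to its payload bits
#'
#' Exact inverse of [encodeSequence()]: strips the initiator, reads one
#' encoding unit per digit, inverts the context-dependent digit-to-unit
#' bijections, and converts the digit string back with [digitsToBits()].
#'
#' @param seq encoded sequence (character or [Biostrings::DNAString]).
#' @param table the [RuleTable] (or scheme id) used at encode time.
#' @param asString return bits as a single "01" string?
#' @return integer 0/1 vector (or string) with the payload bits.
#' @examples
#' tbl <- buildRuleTable("RInf-B4", guard = FALSE)
#' decodeSequence("ACCGTG", tbl, asString = TRUE)  # "1110011100"
#' @export
decodeSequence <- function(seq, table, asString = FALSE) {
    if (!is(table, "RuleTable"))
        table <- buildRuleTable(table)
    s <- .asSeqChar(seq)
    if (nchar(table@initiator) == 0L)
        return(simpleUnmap(s, asString = asString))
    ini <- table@initiator
    if (substr(s, 1L, nchar(ini)) != ini)
        stop("format error: sequence does not start with the initiator '",
             ini, "'")
    body <- substr(s, nchar(ini) + 1L, nchar(s))
    if (nchar(body) %% table@unitLen != 0L)
        stop("format error: sequence length is not initiator + k*",
             table@unitLen)
    n <- nchar(body) %/% table@unitLen
    if (n == 0L)
        stop("format error: no encoding units after the initiator")
    starts <- seq(1L, by = table@unitLen, length.out = n)
    units <- substring(body, starts, starts + table@unitLen - 1L)
    contexts <- c(.lastBase(ini),
                  if (n > 1L) .lastBase(units[-n]))
    digits <- integer(n)
    for (ctx in .BASES) {
        idx <- which(contexts == ctx)
        if (length(idx))
            digits[idx] <- match(units[idx], table@rows[[ctx]]) - 1L
    }
    bad <- which(is.na(digits))
    if (length(bad)) {
        k <- bad[1L]
        stop(sprintf(
            "corrupt sequence: unit '%s' at nt %d not allowed after context '%s'",
            units[k], nchar(ini) + (k - 1L) * table@unitLen + 1L, contexts[k]))
    }
    digitsToBits(digits, table@radix, guard = table@guard, asString = asString)
}

#' Positional 2-bit mapping between bits and nucleotides
#'
#' `simpleMap` converts consecutive bit pairs directly to bases
#' (00 to A, 01 to C, 10 to G, 11 to T); `simpleUnmap` inverts it.
#' No guard bit and no initiator are involved; an odd-length input is an
#' error (padding would break lossless inversion).
#'
#' @param bits payload bits (0/1 vector or a single "01" string) of even
#'   length.
#' @return `simpleMap`: a [Biostrings::DNAString]; `simpleUnmap`: integer
#'   0/1 vector (or string with `asString = TRUE`).
#' @examples
#' simpleMap("00011011")          # ACGT
#' simpleUnmap("ACGT", asString = TRUE)
#' @export
simpleMap <- function(bits) {
    b <- .asBits(bits)
    if (length(b) %% 2L != 0L)
        stop("padding error: simple mapping requires an even number of bits")
    if (length(b) == 0L)
        return(Biostrings::DNAString(""))
    hi <- b[seq(1L, length(b), by = 2L)]
    lo <- b[seq(2L, length(b), by = 2L)]
    Biostrings::DNAString(paste(.BASES[2L * hi + lo + 1L], collapse = ""))
}

#' @rdname simpleMap
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param asString return bits as a single "01" string?
#' @export
simpleUnmap <- function(seq, asString = FALSE) {
    s <- .asSeqChar(seq)
    idx <- match(.seqChars(s), .BASES) - 1L
    bits <- as.integer(rbind(idx %/% 2L, idx %% 2L))
    if (asString) .bitsToString(bits) else bits
}
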