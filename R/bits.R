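#' @include utils.R
NULL

#' Convert a bit string to base-B digits
#'
#' Interprets the (optionally guarded) bit string as a single big integer,
#' most significant bit first, and returns its canonical base-`radix`
#' representation, most significant digit first. With `guard = TRUE` a 1-bit
#' is prepended before conversion so that leading payload zeros survive the
#' integer round trip; the guard also makes the digit count a function of
#' the bit length alone (a guarded 16384-bit payload always yields 4097
#' base-16 digits).
#'
#' @param bits payload bits: an integer/logical 0-1 vector or a single
#'   string such as `"1110011100"`.
#' @param radix integer base B >= 2.
#' @param guard prepend the guard 1-bit before conversion?
#' @return integer vector of digits in `[0, radix)`, most significant first.
#' @examples
#' bitsToDigits("1110011100", 4)            # 3 2 1 3 0
#' bitsToDigits("1110011100", 4, guard = TRUE)  # 1 3 2 1 3 0
#' @seealso [digitsToBits()]
#' @export
bitsToDigits <- function(bits, radix, guard = FALSE) {
    if (!is.numeric(radix) || length(radix) != 1L || radix < 2)
        stop("invalid radix: must be a single integer >= 2")
    b <- .asBits(bits)
    if (guard)
        b <- c(1L, b)
    if (length(b) == 0L)
        stop("bits must be non-empty when guard = FALSE")
    .cpp_bits_to_digits(b, as.integer(radix))
}

#' Recover the bit string from base-B digits
#'
#' Exact inverse of [bitsToDigits()]. With `guard = TRUE` the leading guard
#' 1-bit of the reconstructed binary value is stripped, which restores the
#' original bit length including leading zeros; a guarded value whose binary
#' form does not start with 1 signals corruption. Without the guard the
#' minimal (no leading zero) binary representation is returned.
#'
#' @param digits integer vector of digits, most significant first.
#' @param radix integer base B >= 2 of `digits`.
#' @param guard was the guard bit prepended at encode time?
#' @param asString return a single "01" string instead of an integer vector?
#' @return the payload bits.
#' @examples
#' digitsToBits(c(3, 2, 1, 3, 0), 4, asString = TRUE)  # "1110011100"
#' @export
digitsToBits <- function(digits, radix, guard = FALSE, asString = FALSE) {
    if (!is.numeric(radix) || length(radix) != 1L || radix < 2)
        stop("invalid radix: must be a single integer >= 2")
    d <- as.integer(digits)
    if (length(d) == 0L)
        stop("digits must be non-empty")
    bits <- .cpp_digits_to_bits(d, as.integer(radix))
    if (guard) {
        if (bits[1L] != 1L)
            stop("corrupted digits: guarded value does not start with a 1-bit")
        bits <- bits[-1L]
    }
    if (asString) .bitsToString(bits) else bits
}

#' Uniform random payload bits
#'
#' Draws `n` independent uniform bits from the current R random number
#' stream (set a seed with [set.seed()] for reproducibility).
#'
#' @param n number of bits.
#' @return integer 0/1 vector of length `n`.
#' @examples
#' set.seed(1); randomBits(8)
#' @export
randomBits <- function(n) {
    sample(c(0L, 1L), n, replace = TRUE)
}
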