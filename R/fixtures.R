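#' @include utils.R
NULL

#' Elementary cellular automaton pattern matrix
#'
#' Generates a binary test image by iterating a 3-input/1-output logic rule
#' (elementary cellular automaton in the Wolfram numbering): cell
#' `(r+1, c)` is bit `4a + 2b + d` of `rule`, where `(a, b, d)` are the
#' row-`r` cells at columns `c-1`, `c`, `c+1` with circular boundary.
#' Rule 204 is the identity; rules 0 and 255 give constant rows after the
#' first. Black pixels are 1-bits throughout the package.
#'
#' @param rule rule number in 0-255.
#' @param nRows,nCols matrix dimensions.
#' @param init first row: `"random"` (uniform bits from the current RNG
#'   stream), `"center"` (single centred 1), or an explicit 0/1 vector of
#'   length `nCols`.
#' @return integer 0/1 matrix of dimension `nRows` x `nCols`.
#' @examples
#' set.seed(0)
#' m <- ecaMatrix(182, 16, 16)
#' @export
ecaMatrix <- function(rule, nRows, nCols, init = "random") {
    if (!is.numeric(rule) || length(rule) != 1L || rule < 0 || rule > 255 ||
        rule != floor(rule))
        stop("range error: rule number must be an integer in 0..255")
    if (nRows < 1L || nCols < 1L)
        stop("matrix dimensions must be positive")
    row0 <- if (is.character(init)) {
        switch(match.arg(init, c("random", "center")),
            random = sample(c(0L, 1L), nCols, replace = TRUE),
            center = {
                r <- integer(nCols)
                r[(nCols + 1L) %/% 2L] <- 1L
                r
            })
    } else {
        b <- .asBits(init)
        if (length(b) != nCols)
            stop("explicit first row must have nCols bits")
        b
    }
    lut <- as.integer(intToBits(rule)[1:8])   # lut[k+1] = output for input k
    m <- matrix(0L, nRows, nCols)
    m[1L, ] <- row0
    if (nRows > 1L) {
        for (r in seq_len(nRows - 1L)) {
            cur <- m[r, ]
            left <- c(cur[nCols], cur[-nCols])     # circular boundary
            right <- c(cur[-1L], cur[1L])
            m[r + 1L, ] <- lut[4L * left + 2L * cur + right + 1L]
        }
    }
    m
}

#' Flatten a bit matrix to a bit string and back
#'
#' `flattenBits` reads a binary matrix in row-major order (origin top-left);
#' `reshapeBits` fills a matrix row-major from a bit string, truncating any
#' surplus trailing bits (a 16392-bit decoded string reshaped to 128 x 128
#' drops exactly 8 bits).
#'
#' @param matrix integer 0/1 matrix.
#' @return `flattenBits`: integer 0/1 vector; `reshapeBits`: 0/1 matrix.
#' @examples
#' flattenBits(matrix(c(1, 0, 0, 0), 2, byrow = TRUE))  # 1 0 0 0
#' @export
flattenBits <- function(matrix) {
    as.integer(t(matrix))
}

#' @rdname flattenBits
#' @param bits bits (0/1 vector or single "01" string).
#' @param nRows,nCols target dimensions.
#' @export
reshapeBits <- function(bits, nRows, nCols) {
    b <- .asBits(bits)
    if (length(b) < nRows * nCols)
        stop("length error: need at least ", nRows * nCols, " bits, got ",
             length(b))
    matrix(b[seq_len(nRows * nCols)], nRows, nCols, byrow = TRUE)
}

#' Read and write portable bitmap (PBM P1) images
#'
#' Plain-text PBM: `1` is a black pixel and maps to a 1-bit.
#'
#' @param path file path.
#' @return `readPBM`: integer 0/1 matrix; `writePBM` invisibly returns
#'   `path`.
#' @examples
#' f <- tempfile(fileext = ".pbm")
#' writePBM(ecaMatrix(204, 4, 5, init = "center"), f)
#' readPBM(f)
#' @export
readPBM <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)                 # strip comments
    tok <- unlist(strsplit(paste(lines, collapse = " "), "[ \t]+"))
    tok <- tok[nzchar(tok)]
    if (length(tok) < 3L || tok[1L] != "P1")
        stop("not a plain PBM (P1) file: ", path)
    nCols <- as.integer(tok[2L])
    nRows <- as.integer(tok[3L])
    bits <- as.integer(unlist(strsplit(paste(tok[-(1:3)], collapse = ""), "")))
    if (length(bits) < nRows * nCols || any(!(bits %in% c(0L, 1L))))
        stop("malformed PBM raster in ", path)
    matrix(bits[seq_len(nRows * nCols)], nRows, nCols, byrow = TRUE)
}

#' @rdname readPBM
#' @param matrix integer 0/1 matrix to write.
#' @export
writePBM <- function(matrix, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P1", paste(ncol(matrix), nrow(matrix))), con)
    apply(matrix, 1L, function(r) writeLines(paste(r, collapse = " "), con))
    invisible(path)
}

#' Import a bitmap image as a bit matrix
#'
#' Reads `.pbm` (P1) directly; `.png` is imported via the `png` package,
#' converted to luminance and thresholded at 0.5 (darker than mid-grey
#' becomes a 1-bit, matching the black-pixel-is-1 convention).
#'
#' @param path image path (`.pbm` or `.png`).
#' @return integer 0/1 matrix.
#' @export
readImageBits <- function(path) {
    if (grepl("\\.pbm$", path, ignore.case = TRUE))
        return(readPBM(path))
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
            stop("PNG import requires the 'png' package")
        img <- png::readPNG(path)
        if (length(dim(img)) == 3L)
            img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] +
                   0.114 * img[, , 3L]
        return(matrix(as.integer(img < 0.5), nrow(img), ncol(img)))
    }
    stop("unsupported image format: ", path)
}
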