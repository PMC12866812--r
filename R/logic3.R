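#' @include AllClasses.R utils.R
NULL

.INPUT_LABELS <- c("000", "001", "010", "011", "100", "101", "110", "111")

#' 3-input/1-output logic-scan statistics of a binary matrix
#'
#' Scans the measurable region of an n x m binary matrix: every horizontal
#' 3-bit input `(r, c), (r, c+1), (r, c+2)` with `r < n` is paired with the
#' output bit below its centre, `(r+1, c+1)`, giving `(n-1)(m-2)`
#' evaluations. For each of the eight inputs the zero-output ratio
#' \eqn{\alpha = N_0/(N_0+N_1)} and the occurrence fraction
#' \eqn{\beta = (N_0+N_1)/\sum(N_0+N_1)} are computed; a perfectly random
#' matrix has \eqn{\alpha = 0.5} and \eqn{\beta = 0.125} everywhere, so the
#' RMS summaries are deviations from those expectations:
#' `rmsAlpha` averages \eqn{(\alpha - 0.5)^2} over inputs that occur
#' (\eqn{\alpha} is undefined elsewhere) and `rmsBeta` averages
#' \eqn{(\beta - 0.125)^2} over all eight inputs. `centered = FALSE`
#' instead returns the literal root mean squares of \eqn{\alpha} and
#' \eqn{\beta}.
#'
#' @param matrix integer 0/1 matrix with at least 2 rows and 3 columns.
#' @param centered measure RMS about the random-matrix expectations
#'   (default) rather than about zero?
#' @return a [LogicStats].
#' @examples
#' set.seed(1)
#' logicStats(matrix(rbinom(100, 1, 0.5), 10, 10))
#' @export
logicStats <- function(matrix, centered = TRUE) {
    m <- as.matrix(matrix)
    storage.mode(m) <- "integer"
    if (!all(m %in% c(0L, 1L)))
        stop("matrix must be binary (0/1)")
    nr <- nrow(m); nc <- ncol(m)
    if (nr < 2L || nc < 3L)
        stop("size error: matrix must be at least 2 x 3")
    inRows <- seq_len(nr - 1L)
    inCols <- seq_len(nc - 2L)
    input <- 4L * m[inRows, inCols, drop = FALSE] +
             2L * m[inRows, inCols + 1L, drop = FALSE] +
                  m[inRows, inCols + 2L, drop = FALSE]
    output <- m[inRows + 1L, inCols + 1L, drop = FALSE]
    n0 <- tabulate(input[output == 0L] + 1L, nbins = 8L)
    n1 <- tabulate(input[output == 1L] + 1L, nbins = 8L)
    names(n0) <- names(n1) <- .INPUT_LABELS
    tot <- n0 + n1
    alpha <- n0 / tot                     # NaN where the input never occurs
    beta <- tot / sum(tot)
    if (centered) {
        rmsA <- sqrt(mean((alpha[tot > 0] - 0.5)^2))
        rmsB <- sqrt(mean((beta - 0.125)^2))
    } else {
        rmsA <- sqrt(mean(alpha[tot > 0]^2))
        rmsB <- sqrt(mean(beta^2))
    }
    new("LogicStats",
        n0 = stats::setNames(as.numeric(n0), .INPUT_LABELS),
        n1 = stats::setNames(as.numeric(n1), .INPUT_LABELS),
        alpha = alpha, beta = beta, rmsAlpha = rmsA, rmsBeta = rmsB)
}
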