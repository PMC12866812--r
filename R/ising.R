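#' @include AllClasses.R codec.R fixtures.R
NULL

#' Spin matrix of an encoded sequence
#'
#' Simple-unmaps the sequence to bits (A to 00, C to 01, G to 10, T to 11),
#' keeps the first `nRows * nCols` bits, reshapes them row-major and maps
#' 1-bits to spin +1, 0-bits to spin -1. An 8196-nt sequence yields 16392
#' bits of which the first 16384 fill a 128 x 128 lattice.
#'
#' @param seq encoded sequence (character or [Biostrings::DNAString]).
#' @param nRows,nCols lattice dimensions (default 128 x 128).
#' @return integer matrix of spins (+1/-1).
#' @examples
#' toSpinMatrix(strrep("T", 8), 2, 8)
#' @export
toSpinMatrix <- function(seq, nRows = 128L, nCols = 128L) {
    bits <- simpleUnmap(seq)
    if (length(bits) < nRows * nCols)
        stop("length error: sequence provides ", length(bits),
             " bits, need ", nRows * nCols)
    2L * reshapeBits(bits, nRows, nCols) - 1L
}

#' Spin and nearest-neighbour pair sums of a spin lattice
#'
#' Computes \eqn{\sum_i \sigma_i}, the pair sum
#' \eqn{\sum_{\langle i,j\rangle} \sigma_i \sigma_j} over unordered
#' 4-connected nearest-neighbour pairs, and the counts
#' \eqn{N_T = N M}, \eqn{N_n = (N-1)M + (M-1)N},
#' \eqn{N_t = 12(N-1)(M-1) - 4} for an N x M lattice.
#'
#' @param spins matrix of spins (+1/-1), or of bits (0/1, converted).
#' @return a [SpinSums].
#' @examples
#' spinSums(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))  # the worked 2x2
#' @export
spinSums <- function(spins) {
    m <- as.matrix(spins)
    if (all(m %in% c(0, 1)))             # accept a bit matrix
        m <- 2 * m - 1
    if (!all(m %in% c(-1, 1)))
        stop("spins must be +1/-1 (or bits 0/1)")
    nr <- nrow(m); nc <- ncol(m)
    if (nr < 2L || nc < 2L)
        stop("size error: lattice must be at least 2 x 2")
    sumPair <- sum(m[-nr, ] * m[-1L, ]) + sum(m[, -nc] * m[, -1L])
    new("SpinSums",
        sumSpin = sum(m),
        sumPair = sumPair,
        nNodes = nr * nc,
        nConnections = (nr - 1) * nc + (nc - 1) * nr,
        nTouching = 12 * (nr - 1) * (nc - 1) - 4)
}

#' Inverse-Ising randomness factors
#'
#' Mean-field inversion of the lattice statistics. The polarization factor
#' is the exact normalised magnetisation \eqn{\gamma = \sum_i \sigma_i /
#' N_T}. Writing \eqn{c = \sum\sigma_i\sigma_j / N_n} for the mean
#' nearest-neighbour correlation, the interaction factor is the mean-field
#' coupling estimate
#' \deqn{\lambda = (c - \gamma^2) / (1 - \gamma^2)^2,}
#' the connected neighbour correlation normalised by the squared
#' single-site variance (range \eqn{[-1, \infty)}: \eqn{-1} for a
#' checkerboard, 0 for an uncorrelated lattice, large for clustered
#' lattices), and the bias factor is the mean-field local field
#' \deqn{h = \mathrm{atanh}(\gamma) - \bar z\,\lambda\,\gamma,}
#' with \eqn{\bar z = 2 N_n / N_T} the mean coordination number. On a fully
#' polarised lattice (\eqn{|\gamma| = 1}) \eqn{\lambda} is undefined
#' (`NaN`) and \eqn{h} is \eqn{\pm\infty}. A different closed form can be
#' supplied via `formula` (a function of the [SpinSums]).
#'
#' @param sums a [SpinSums], or a spin/bit matrix (passed to [spinSums()]).
#' @param formula optional function `(sums) -> c(lambda =, h =)` replacing
#'   the mean-field closed forms.
#' @return an [IsingParams].
#' @examples
#' isingParams(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
#' @export
isingParams <- function(sums, formula = NULL) {
    if (!is(sums, "SpinSums"))
        sums <- spinSums(sums)
    gamma <- sums@sumSpin / sums@nNodes
    if (!is.null(formula)) {
        lh <- formula(sums)
        return(new("IsingParams", gamma = gamma,
                   lambda = unname(lh[["lambda"]]), h = unname(lh[["h"]]),
                   sums = sums))
    }
    corr <- sums@sumPair / sums@nConnections
    if (abs(gamma) == 1) {               # fully polarised: coupling undefined
        lambda <- NaN
        h <- atanh(gamma)
    } else {
        lambda <- (corr - gamma^2) / (1 - gamma^2)^2
        zbar <- 2 * sums@nConnections / sums@nNodes
        h <- atanh(gamma) - zbar * lambda * gamma
    }
    new("IsingParams", gamma = gamma, lambda = lambda, h = h, sums = sums)
}
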