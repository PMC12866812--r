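#' @include utils.R
NULL

#' RuleTable: a randomized DNA base sequence design rule
#'
#' A design rule of the R_N-B# family (or the degenerate `simple` scheme).
#' A rule converts a guarded binary payload to base-B digits and emits one
#' encoding unit (nucleotide monomer or dimer) per digit, chosen from a
#' context-dependent digit-to-unit bijection, where the context is the last
#' emitted base. The subscript N is the maximum allowable homopolymer run
#' length in the emitted sequence (`Inf`, 2 or 1).
#'
#' @slot scheme scheme identifier, one of `"simple"`, `"RInf-B16"`,
#'   `"RInf-B4"`, `"R1-B12"`, `"R0-B9"`, `"R0-B3"` (or `"custom"`).
#' @slot unitLen encoding unit length in nt (1 or 2).
#' @slot radix numerical base B of the digit string (3, 4, 9, 12 or 16).
#' @slot maxRun maximum homopolymer run length permitted in output
#'   (`Inf`, 2 or 1).
#' @slot initiator the arbitrary first unit seeding the context (e.g. `"AT"`);
#'   empty for the positional `simple` scheme.
#' @slot guard whether a leading 1-bit is prepended before radix conversion
#'   so that leading payload zeros survive the integer round trip.
#' @slot rows named list (contexts `A`,`C`,`G`,`T`) of character vectors;
#'   element `d + 1` of a row is the unit emitted for digit `d`.
#'
#' @seealso [buildRuleTable()], [encodeSequence()], [decodeSequence()]
#' @name RuleTable-class
#' @aliases RuleTable
#' @exportClass RuleTable
setClass("RuleTable",
    representation(
        scheme    = "character",
        unitLen   = "integer",
        radix     = "integer",
        maxRun    = "numeric",
        initiator = "character",
        guard     = "logical",
        rows      = "list"
    )
)

.validRuleTable <- function(object) {
    msg <- character(0)
    if (length(object@scheme) != 1L)
        msg <- c(msg, "'scheme' must be a single string")
    if (!(object@unitLen %in% c(1L, 2L)))
        msg <- c(msg, "'unitLen' must be 1 or 2")
    if (object@radix < 2L)
        msg <- c(msg, "'radix' must be >= 2")
    if (!identical(sort(names(object@rows)), sort(.BASES)))
        msg <- c(msg, "'rows' must be a named list with contexts A, C, G, T")
    if (nchar(object@initiator) > 0L) {
        if (nchar(object@initiator) != object@unitLen)
            msg <- c(msg, "'initiator' must have unitLen characters")
        if (grepl("[^ACGT]", object@initiator))
            msg <- c(msg, "'initiator' must be over {A,C,G,T}")
    }
    if (length(msg) == 0L) {
        for (ctx in .BASES) {
            row <- object@rows[[ctx]]
            if (length(row) != object@radix) {
                msg <- c(msg, sprintf(
                    "row '%s' has %d units; must equal the radix (%d)",
                    ctx, length(row), object@radix))
                next
            }
            if (anyDuplicated(row))
                msg <- c(msg, sprintf("row '%s' is not a bijection (duplicated units)", ctx))
            if (any(nchar(row) != object@unitLen))
                msg <- c(msg, sprintf("row '%s' has units of the wrong length", ctx))
            if (any(grepl("[^ACGT]", row)))
                msg <- c(msg, sprintf("row '%s' has units outside {A,C,G,T}", ctx))
        }
    }
    ## Run-length guarantee: with unit length <= 2 and maxRun <= 2 any
    ## over-long run spans at most two consecutive units, so checking every
    ## context-consistent pair of units (plus initiator + first unit) suffices.
    if (length(msg) == 0L && is.finite(object@maxRun)) {
        units <- unique(unlist(object@rows, use.names = FALSE))
        firsts <- c(units, if (nchar(object@initiator)) object@initiator)
        for (u1 in firsts) {
            for (u2 in object@rows[[.lastBase(u1)]]) {
                if (.longestRun(paste0(u1, u2)) > object@maxRun) {
                    msg <- c(msg, sprintf(
                        "units '%s'+'%s' violate the homopolymer limit %d",
                        u1, u2, object@maxRun))
                }
            }
        }
        if (length(msg) > 3L) msg <- c(msg[1:3], "...")
    }
    if (length(msg)) msg else TRUE
}

setValidity("RuleTable", .validRuleTable)

#' MSDCurve: mean squared (angular) displacement versus lag
#'
#' Mean squared displacement (translational model) or mean squared angular
#' displacement about one axis (rotational model) as a function of the lag
#' \eqn{\Delta n} within overlapping windows of an encoded sequence.
#'
#' @slot lags integer lags \eqn{\Delta n = 1, \ldots,} window.
#' @slot values mean squared (angular) displacement at each lag, in units of
#'   \eqn{L^2} per lag (translational) or \eqn{rad^2} (angular).
#' @slot window window length in nt.
#' @slot stride offset between successive window origins in nt.
#' @slot nWindows number of windows actually averaged.
#' @slot kind `"translational"` or `"angular"`.
#' @slot axis axis label for angular curves (`"X"`, `"Y"`, `"Z"`) or `NA`.
#'
#' @seealso [msdCurve()], [msadCurves()], [fitTranslational()], [fitRotational()]
#' @name MSDCurve-class
#' @aliases MSDCurve
#' @exportClass MSDCurve
setClass("MSDCurve",
    representation(
        lags     = "integer",
        values   = "numeric",
        window   = "integer",
        stride   = "integer",
        nWindows = "integer",
        kind     = "character",
        axis     = "character"
    )
)

setValidity("MSDCurve", function(object) {
    msg <- character(0)
    if (length(object@lags) != length(object@values))
        msg <- c(msg, "'lags' and 'values' must have equal length")
    if (any(object@values < -1e-12))
        msg <- c(msg, "'values' must be non-negative")
    if (!(object@kind %in% c("translational", "angular")))
        msg <- c(msg, "'kind' must be 'translational' or 'angular'")
    if (length(msg)) msg else TRUE
})

#' TranslationalFit: velocity and diffusion coefficient from an MSD curve
#'
#' Parameters of the short-lag MSD model
#' \eqn{\langle(\Delta r)^2\rangle = 4D\,\Delta n + V^2\,\Delta n^2},
#' fitted with both coefficients constrained non-negative.
#'
#' @slot V velocity (self-propulsion) in L/nt.
#' @slot D diffusion coefficient in L^2/nt.
#' @slot residual root-mean-square fit residual.
#'
#' @seealso [fitTranslational()]
#' @name TranslationalFit-class
#' @aliases TranslationalFit
#' @exportClass TranslationalFit
setClass("TranslationalFit",
    representation(V = "numeric", D = "numeric", residual = "numeric"))

#' RotationalFit: angular velocity and rotational diffusion from MSAD curves
#'
#' Per-axis parameters of the MSAD model
#' \eqn{\langle(\Delta\theta)^2\rangle = 2D_R\,\Delta n + \omega^2\,\Delta n^2}
#' and their Euclidean magnitudes
#' \eqn{\omega = (\omega_X^2+\omega_Y^2+\omega_Z^2)^{1/2}},
#' \eqn{D_R = (D_{RX}^2+D_{RY}^2+D_{RZ}^2)^{1/2}}.
#'
#' @slot omegaAxis named angular velocity per axis, rad/nt.
#' @slot drAxis named rotational diffusion coefficient per axis, rad^2/nt.
#' @slot omega magnitude of the angular velocity, rad/nt.
#' @slot dR magnitude of the rotational diffusion coefficient, rad^2/nt.
#' @slot residuals per-axis RMS fit residuals.
#'
#' @seealso [fitRotational()]
#' @name RotationalFit-class
#' @aliases RotationalFit
#' @exportClass RotationalFit
setClass("RotationalFit",
    representation(omegaAxis = "numeric", drAxis = "numeric",
                   omega = "numeric", dR = "numeric", residuals = "numeric"))

#' SpinSums: spin and nearest-neighbour pair sums of a spin lattice
#'
#' Bookkeeping sums of an N x M matrix of Ising spins (+1/-1) used by the
#' inverse-Ising factors: the total spin sum, the sum of products over
#' unordered 4-connected nearest-neighbour pairs, and the node/connection
#' counts \eqn{N_T = N M}, \eqn{N_n = (N-1)M + (M-1)N} and
#' \eqn{N_t = 12(N-1)(M-1) - 4}.
#'
#' @slot sumSpin \eqn{\sum_i \sigma_i}.
#' @slot sumPair \eqn{\sum_{\langle i,j\rangle} \sigma_i\sigma_j} over
#'   unordered nearest-neighbour pairs.
#' @slot nNodes total node count \eqn{N_T}.
#' @slot nConnections nearest-neighbour connection count \eqn{N_n}.
#' @slot nTouching touching connection count \eqn{N_t}.
#'
#' @seealso [spinSums()], [isingParams()]
#' @name SpinSums-class
#' @aliases SpinSums
#' @exportClass SpinSums
setClass("SpinSums",
    representation(sumSpin = "numeric", sumPair = "numeric",
                   nNodes = "numeric", nConnections = "numeric",
                   nTouching = "numeric"))

setValidity("SpinSums", function(object) {
    msg <- character(0)
    if (abs(object@sumSpin) > object@nNodes)
        msg <- c(msg, "|sumSpin| cannot exceed the node count")
    if (abs(object@sumPair) > object@nConnections)
        msg <- c(msg, "|sumPair| cannot exceed the connection count")
    if (length(msg)) msg else TRUE
})

#' IsingParams: inverse-Ising randomness factors
#'
#' The polarization factor \eqn{\gamma}, interaction factor \eqn{\lambda}
#' and bias factor \eqn{h} of a spin lattice, computed by mean-field
#' inversion from the spin and pair sums. \eqn{\gamma \in [-1, 1]},
#' \eqn{\lambda \in [-1, \infty)}, \eqn{h \in (-\infty, \infty)}.
#'
#' @slot gamma polarization factor \eqn{\gamma = \sum_i \sigma_i / N_T}.
#' @slot lambda interaction factor.
#' @slot h bias factor.
#' @slot sums the [SpinSums] the factors derive from.
#'
#' @seealso [isingParams()]
#' @name IsingParams-class
#' @aliases IsingParams
#' @exportClass IsingParams
setClass("IsingParams",
    representation(gamma = "numeric", lambda = "numeric", h = "numeric",
                   sums = "SpinSums"))

#' LogicStats: 3-input/1-output logic-scan randomness statistics
#'
#' Per-input statistics of the logic scan of a binary matrix: for each of
#' the eight 3-bit inputs, the zero-output ratio
#' \eqn{\alpha = N_0/(N_0+N_1)} and the input occurrence fraction
#' \eqn{\beta = (N_0+N_1)/\sum(N_0+N_1)}, with RMS deviations from the
#' perfectly-random expectations 0.5 and 0.125.
#'
#' @slot n0 named counts of 0-bit outputs per 3-bit input.
#' @slot n1 named counts of 1-bit outputs per 3-bit input.
#' @slot alpha named zero-output ratio per input (`NaN` where unobserved).
#' @slot beta named input occurrence fraction per input.
#' @slot rmsAlpha RMS deviation of alpha from 0.5 over observed inputs.
#' @slot rmsBeta RMS deviation of beta from 0.125 over all eight inputs.
#'
#' @seealso [logicStats()]
#' @name LogicStats-class
#' @aliases LogicStats
#' @exportClass LogicStats
setClass("LogicStats",
    representation(n0 = "numeric", n1 = "numeric",
                   alpha = "numeric", beta = "numeric",
                   rmsAlpha = "numeric", rmsBeta = "numeric"))

setValidity("LogicStats", function(object) {
    msg <- character(0)
    if (length(object@n0) != 8L || length(object@n1) != 8L)
        msg <- c(msg, "counts must be indexed by the 8 inputs 000..111")
    if (abs(sum(object@beta) - 1) > 1e-9)
        msg <- c(msg, "beta must sum to 1")
    if (length(msg)) msg else TRUE
})
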