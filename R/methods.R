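#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname RuleTable-class
#' @export
setMethod("schemeId", "RuleTable", function(x) x@scheme)

#' @rdname RuleTable-class
#' @export
setMethod("unitLength", "RuleTable", function(x) x@unitLen)

#' @rdname RuleTable-class
#' @export
setMethod("radixBase", "RuleTable", function(x) x@radix)

#' @rdname RuleTable-class
#' @export
setMethod("maxRun", "RuleTable", function(x) x@maxRun)

#' @rdname RuleTable-class
#' @export
setMethod("initiator", "RuleTable", function(x) x@initiator)

#' @rdname RuleTable-class
#' @export
setMethod("guardBit", "RuleTable", function(x) x@guard)

#' @rdname RuleTable-class
#' @export
setMethod("ruleRows", "RuleTable", function(x) x@rows)

setMethod("show", "RuleTable", function(object) {
    cat(sprintf("RuleTable '%s': base-%d, %d-nt units, max homopolymer %s\n",
                object@scheme, object@radix, object@unitLen,
                ifelse(is.finite(object@maxRun),
                       as.character(object@maxRun), "unbounded")))
    cat(sprintf("  initiator: %s   guard bit: %s\n",
                if (nchar(object@initiator)) object@initiator else "(none)",
                object@guard))
    if (object@scheme == "simple") {
        cat("  positional 2-bit mapping (00->A, 01->C, 10->G, 11->T)\n")
    } else {
        for (ctx in .BASES)
            cat(sprintf("  after %s: %s\n", ctx,
                        paste(object@rows[[ctx]], collapse = " ")))
    }
    invisible(NULL)
})

#' @rdname MSDCurve-class
#' @export
setMethod("msdValues", "MSDCurve", function(x) x@values)

#' @rdname MSDCurve-class
#' @export
setMethod("msdLags", "MSDCurve", function(x) x@lags)

#' @rdname MSDCurve-class
#' @export
setMethod("nWindows", "MSDCurve", function(x) x@nWindows)

setMethod("show", "MSDCurve", function(object) {
    lab <- if (object@kind == "angular")
        sprintf("MSAD curve (axis %s)", object@axis) else "MSD curve"
    cat(sprintf("%s: %d lags, window %d nt, stride %d, %d windows\n",
                lab, length(object@lags), object@window, object@stride,
                object@nWindows))
    cat("  values:", paste(signif(head(object@values, 6), 4), collapse = " "),
        if (length(object@values) > 6) "..." else "", "\n")
    invisible(NULL)
})

#' @rdname TranslationalFit-class
#' @export
setMethod("velocity", "TranslationalFit", function(x) x@V)

#' @rdname TranslationalFit-class
#' @export
setMethod("diffusionCoefficient", "TranslationalFit", function(x) x@D)

setMethod("show", "TranslationalFit", function(object) {
    cat(sprintf("TranslationalFit: V = %.4g L/nt, D = %.4g L^2/nt (rms resid %.3g)\n",
                object@V, object@D, object@residual))
    invisible(NULL)
})

#' @rdname RotationalFit-class
#' @export
setMethod("angularVelocity", "RotationalFit", function(x) x@omega)

#' @rdname RotationalFit-class
#' @export
setMethod("rotationalDiffusion", "RotationalFit", function(x) x@dR)

setMethod("show", "RotationalFit", function(object) {
    cat(sprintf("RotationalFit: omega = %.4g rad/nt, D_R = %.4g rad^2/nt\n",
                object@omega, object@dR))
    cat(sprintf("  per axis omega: %s\n",
                paste(sprintf("%s=%.4g", names(object@omegaAxis),
                              object@omegaAxis), collapse = ", ")))
    cat(sprintf("  per axis D_R:   %s\n",
                paste(sprintf("%s=%.4g", names(object@drAxis),
                              object@drAxis), collapse = ", ")))
    invisible(NULL)
})

setMethod("show", "SpinSums", function(object) {
    cat(sprintf(
        "SpinSums: sum(spin) = %g, sum(pair) = %g, N_T = %g, N_n = %g, N_t = %g\n",
        object@sumSpin, object@sumPair, object@nNodes, object@nConnections,
        object@nTouching))
    invisible(NULL)
})

#' @rdname IsingParams-class
#' @export
setMethod("polarizationFactor", "IsingParams", function(x) x@gamma)

#' @rdname IsingParams-class
#' @export
setMethod("interactionFactor", "IsingParams", function(x) x@lambda)

#' @rdname IsingParams-class
#' @export
setMethod("biasFactor", "IsingParams", function(x) x@h)

setMethod("show", "IsingParams", function(object) {
    cat(sprintf("IsingParams: gamma = %.4g, lambda = %.4g, h = %.4g\n",
                object@gamma, object@lambda, object@h))
    invisible(NULL)
})

#' @rdname LogicStats-class
#' @export
setMethod("alphaRatios", "LogicStats", function(x) x@alpha)

#' @rdname LogicStats-class
#' @export
setMethod("betaRatios", "LogicStats", function(x) x@beta)

#' @rdname LogicStats-class
#' @export
setMethod("rmsAlpha", "LogicStats", function(x) x@rmsAlpha)

#' @rdname LogicStats-class
#' @export
setMethod("rmsBeta", "LogicStats", function(x) x@rmsBeta)

setMethod("show", "LogicStats", function(object) {
    cat("LogicStats over 3-bit inputs:\n")
    print(round(rbind(alpha = object@alpha, beta = object@beta), 4))
    cat(sprintf("  RMS(alpha) = %.4g, RMS(beta) = %.4g\n",
                object@rmsAlpha, object@rmsBeta))
    invisible(NULL)
})
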