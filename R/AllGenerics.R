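#' @include AllClasses.R
NULL

#' @rdname RuleTable-class
#' @param x a `RuleTable` (or other dnastore S4 object for the shared accessors)
#' @export
setGeneric("schemeId", function(x) standardGeneric("schemeId"))

#' @rdname RuleTable-class
#' @export
setGeneric("unitLength", function(x) standardGeneric("unitLength"))

#' @rdname RuleTable-class
#' @export
setGeneric("radixBase", function(x) standardGeneric("radixBase"))

#' @rdname RuleTable-class
#' @export
setGeneric("maxRun", function(x) standardGeneric("maxRun"))

#' @rdname RuleTable-class
#' @export
setGeneric("initiator", function(x) standardGeneric("initiator"))

#' @rdname RuleTable-class
#' @export
setGeneric("guardBit", function(x) standardGeneric("guardBit"))

#' @rdname RuleTable-class
#' @export
setGeneric("ruleRows", function(x) standardGeneric("ruleRows"))

#' @rdname MSDCurve-class
#' @export
setGeneric("msdValues", function(x) standardGeneric("msdValues"))

#' @rdname MSDCurve-class
#' @export
setGeneric("msdLags", function(x) standardGeneric("msdLags"))

#' @rdname MSDCurve-class
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname TranslationalFit-class
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))

#' @rdname TranslationalFit-class
#' @export
setGeneric("diffusionCoefficient", function(x) standardGeneric("diffusionCoefficient"))

#' @rdname RotationalFit-class
#' @export
setGeneric("angularVelocity", function(x) standardGeneric("angularVelocity"))

#' @rdname RotationalFit-class
#' @export
setGeneric("rotationalDiffusion", function(x) standardGeneric("rotationalDiffusion"))

#' @rdname IsingParams-class
#' @export
setGeneric("polarizationFactor", function(x) standardGeneric("polarizationFactor"))

#' @rdname IsingParams-class
#' @export
setGeneric("interactionFactor", function(x) standardGeneric("interactionFactor"))

#' @rdname IsingParams-class
#' @export
setGeneric("biasFactor", function(x) standardGeneric("biasFactor"))

#' @rdname LogicStats-class
#' @export
setGeneric("alphaRatios", function(x) standardGeneric("alphaRatios"))

#' @rdname LogicStats-class
#' @export
setGeneric("betaRatios", function(x) standardGeneric("betaRatios"))

#' @rdname LogicStats-class
#' @export
setGeneric("rmsAlpha", function(x) standardGeneric("rmsAlpha"))

#' @rdname LogicStats-class
#' @export
setGeneric("rmsBeta", function(x) standardGeneric("rmsBeta"))
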