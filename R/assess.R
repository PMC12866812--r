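#' @include apt.R ising.R logic3.R seqstats.R strands.R
NULL

#' Run every randomness model across encoding schemes
#'
#' Encodes one payload with each requested scheme and scores the encoded
#' sequence with all three physics-based models plus the composition
#' metrics. Per scheme the report carries: sequence length, information
#' density (payload bits / sequence length), GC ratio, longest
#' homopolymer, the translational fit (V, D), the rotational fit
#' (omega, D_R), the inverse-Ising factors (gamma, lambda, h) and the
#' logic-scan RMS summaries. Deterministic given the payload and settings.
#'
#' @param bits payload bits (0/1 vector, single "01" string, or a 0/1
#'   matrix, which is flattened row-major).
#' @param schemes scheme ids (see [dnastoreSchemes()]).
#' @param window,nWindows MSD/MSAD window settings (see [msdCurve()]).
#' @param latticeRows,latticeCols spin-lattice shape for the inverse-Ising
#'   and logic models.
#' @return data.frame with one row per scheme.
#' @examples
#' set.seed(0)
#' assessAll(randomBits(512), schemes = c("simple", "R0-B9"),
#'           nWindows = 50, latticeRows = 16, latticeCols = 16)
#' @export
assessAll <- function(bits,
                      schemes = dnastoreSchemes(),
                      window = 20L, nWindows = 8000L,
                      latticeRows = 128L, latticeCols = 128L) {
    if (is.matrix(bits))
        bits <- flattenBits(bits)
    b <- .asBits(bits)
    if (length(b) == 0L)
        stop("empty payload: nothing to encode")
    if (length(schemes) == 0L)
        stop("no schemes requested")
    rows <- lapply(schemes, function(sc) {
        tbl <- buildRuleTable(sc)
        seq <- as.character(encodeSequence(b, tbl))
        msd <- msdCurve(seq, window = window, nWindows = nWindows)
        tfit <- fitTranslational(msd)
        rfit <- fitRotational(msadCurves(seq, window = window,
                                         nWindows = nWindows))
        spins <- toSpinMatrix(seq, latticeRows, latticeCols)
        ip <- isingParams(spins)
        ls <- logicStats((spins + 1L) %/% 2L)
        data.frame(
            scheme = schemeId(tbl),
            length_nt = nchar(seq),
            density_bits_nt = length(b) / nchar(seq),
            gc_ratio = gcRatio(seq),
            longest_homopolymer = longestHomopolymer(seq),
            V = velocity(tfit),
            D = diffusionCoefficient(tfit),
            omega = angularVelocity(rfit),
            D_R = rotationalDiffusion(rfit),
            gamma = polarizationFactor(ip),
            lambda = interactionFactor(ip),
            h = biasFactor(ip),
            rms_alpha = rmsAlpha(ls),
            rms_beta = rmsBeta(ls),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write an assessment report as JSON
#'
#' Serialises an [assessAll()] report with an embedded configuration echo
#' for provenance.
#'
#' @param report data.frame from [assessAll()].
#' @param path output path.
#' @param config named list echoed under `$config` (seed, window, shape...).
#' @return invisibly, `path`.
#' @export
writeReportJSON <- function(report, path, config = list()) {
    jsonlite::write_json(list(config = config, results = report), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeReportJSON
#' @export
readReportJSON <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}
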