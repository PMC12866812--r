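#' @include AllClasses.R utils.R
NULL

## 2D step vectors: one unit step L per nt.
.STEP2D <- matrix(c(1, 0,   # A = ( L, 0)
                    0, 1,   # C = ( 0, L)
                   -1, 0,   # G = (-L, 0)
                    0,-1),  # T = ( 0,-L)
                  nrow = 4L, byrow = TRUE, dimnames = list(.BASES, c("x","y")))

#' Translational active-particle trajectory of a sequence
#'
#' Maps a sequence to a 2D lattice trajectory: each nt moves the particle
#' one unit length L in the direction of its base (A right, C up, G left,
#' T down), starting from the origin.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @return numeric matrix with columns `x`, `y` (units of L) and one row
#'   per step, step 0 (the origin) first.
#' @examples
#' trajectory2D("ACACGGCGTG")   # ends at (-2, 2)
#' @export
trajectory2D <- function(seq) {
    s <- .asSeqChar(seq)
    if (nchar(s) == 0L)
        stop("empty sequence")
    idx <- match(.seqChars(s), .BASES)
    rbind(c(x = 0, y = 0),
          cbind(x = cumsum(.STEP2D[idx, 1L]), y = cumsum(.STEP2D[idx, 2L])))
}

## Cube vertex labeling: bases sit in antipodal pairs at the 8 vertices of
## the unit cube; every vertex's three edge-neighbours carry the three other
## bases (the unique antipodal 4-labeling up to rotation).
.CUBE_VERTICES <- matrix(c(
     1,  1,  1,   # A
    -1, -1, -1,   # A
    -1,  1,  1,   # C
     1, -1, -1,   # C
     1, -1,  1,   # G
    -1,  1, -1,   # G
     1,  1, -1,   # T
    -1, -1,  1),  # T
    ncol = 3L, byrow = TRUE,
    dimnames = list(rep(.BASES, each = 2L), c("x", "y", "z")))

## signed angle between projections of v1 -> v2 onto the plane
## perpendicular to each axis (columns X, Y, Z); +-pi/2 or 0 for edge moves
.axisAngles <- function(v1, v2) {
    ang <- function(u1, w1, u2, w2)
        atan2(u1 * w2 - w1 * u2, u1 * u2 + w1 * w2)
    c(X = ang(v1[2L], v1[3L], v2[2L], v2[3L]),
      Y = ang(v1[3L], v1[1L], v2[3L], v2[1L]),
      Z = ang(v1[1L], v1[2L], v2[1L], v2[2L]))
}

#' Rotational active-particle trajectory of a sequence
#'
#' Maps a sequence to a walk on the edges of a cube whose 8 vertices carry
#' the 4 bases in antipodal pairs. The particle starts at the first base's
#' vertex in the upper (z = +1) plane; each subsequent base either leaves
#' it in place (repeated base, zero angular increment -- homopolymers
#' freeze rotation) or moves it along the unique edge to a vertex carrying
#' that base. Each edge move produces a signed angular displacement of
#' pi/2 about exactly two axes (the angle between the before/after
#' positions projected onto the plane perpendicular to each axis).
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @return list with `vertices` (n x 3 matrix of cube vertices, one row per
#'   nt) and `angles` (n x 3 matrix of cumulative signed angles about X, Y,
#'   Z in radians; the first row is zero).
#' @examples
#' trajectory3D("AA")$angles     # stationary
#' @export
trajectory3D <- function(seq) {
    s <- .asSeqChar(seq)
    if (nchar(s) == 0L)
        stop("empty sequence")
    ch <- .seqChars(s)
    n <- length(ch)
    verts <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
    angles <- matrix(0, n, 3L, dimnames = list(NULL, c("X", "Y", "Z")))
    ## start at the first base's vertex in the upper plane
    cand <- .CUBE_VERTICES[rownames(.CUBE_VERTICES) == ch[1L], , drop = FALSE]
    verts[1L, ] <- cand[cand[, "z"] == 1, ]
    curBase <- ch[1L]
    for (k in seq_len(n - 1L)) {
        b <- ch[k + 1L]
        if (b == curBase) {                      # homopolymer: stationary
            verts[k + 1L, ] <- verts[k, ]
            angles[k + 1L, ] <- angles[k, ]
            next
        }
        cand <- .CUBE_VERTICES[rownames(.CUBE_VERTICES) == b, , drop = FALSE]
        dist <- rowSums(cand != matrix(verts[k, ], 2L, 3L, byrow = TRUE))
        nxt <- cand[dist == 1L, ]                # unique edge-adjacent vertex
        verts[k + 1L, ] <- nxt
        angles[k + 1L, ] <- angles[k, ] + .axisAngles(verts[k, ], nxt)
        curBase <- b
    }
    list(vertices = verts, angles = angles)
}

## windowed mean-square increment of a cumulative series:
## value(lag) = mean over window origins of (s[origin + lag] - s[origin])^2
.windowedMS <- function(series, window, stride, nWindows) {
    nSteps <- length(series) - 1L
    nAvail <- (nSteps - window) %/% stride + 1L
    if (nSteps < window || nAvail < 1L)
        stop("insufficient data: series has ", nSteps,
             " steps, window needs ", window)
    nW <- min(nWindows, nAvail)
    origins <- seq(1L, by = stride, length.out = nW)   # index into series
    vapply(seq_len(window), function(lag)
        mean((series[origins + lag] - series[origins])^2), numeric(1))
}

.newCurve <- function(values, window, stride, nW, kind, axis = NA_character_)
    new("MSDCurve", lags = seq_len(window), values = values,
        window = as.integer(window), stride = as.integer(stride),
        nWindows = as.integer(nW), kind = kind, axis = axis)

.nUsedWindows <- function(nSteps, window, stride, nWindows)
    min(nWindows, (nSteps - window) %/% stride + 1L)

#' Mean squared displacement over sliding windows
#'
#' Slides overlapping displacement windows along the sequence trajectory
#' and, for each lag \eqn{\Delta n \le} `window`, averages the squared
#' displacement from each window's own origin. With the defaults
#' (20-nt windows, 1-nt stride, 8000 windows) an 8020-nt sequence yields
#' exactly 8000 windows; if fewer windows are available than requested the
#' count is reduced to the maximum available.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param window window length in nt.
#' @param stride offset between window origins in nt.
#' @param nWindows number of windows to average.
#' @return an [MSDCurve] in units of L^2.
#' @examples
#' msdCurve(strrep("A", 100), nWindows = 50)   # ballistic: lag^2
#' @export
msdCurve <- function(seq, window = 20L, stride = 1L, nWindows = 8000L) {
    traj <- trajectory2D(seq)
    nSteps <- nrow(traj) - 1L
    if (nSteps < window)
        stop("insufficient data: sequence shorter than one window")
    nW <- .nUsedWindows(nSteps, window, stride, nWindows)
    vals <- .windowedMS(traj[, "x"], window, stride, nWindows) +
            .windowedMS(traj[, "y"], window, stride, nWindows)
    .newCurve(vals, window, stride, nW, "translational")
}

#' Mean squared angular displacement per axis
#'
#' Rotational analogue of [msdCurve()]: the same sliding-window average
#' applied to the cumulative signed angle about each axis of the
#' [trajectory3D()] walk. An n-nt sequence provides n-1 angular steps, so
#' an 8020-nt sequence yields exactly 8000 windows at the defaults.
#'
#' @inheritParams msdCurve
#' @return named list of three angular [MSDCurve]s (`X`, `Y`, `Z`), rad^2.
#' @examples
#' msadCurves(strrep("ATGC", 30), nWindows = 50)$Y
#' @export
msadCurves <- function(seq, window = 20L, stride = 1L, nWindows = 8000L) {
    traj <- trajectory3D(seq)
    ang <- traj$angles
    nSteps <- nrow(ang) - 1L
    if (nSteps < window)
        stop("insufficient data: sequence shorter than one window")
    nW <- .nUsedWindows(nSteps, window, stride, nWindows)
    stats::setNames(lapply(c("X", "Y", "Z"), function(ax)
        .newCurve(.windowedMS(ang[, ax], window, stride, nWindows),
                  window, stride, nW, "angular", ax)),
        c("X", "Y", "Z"))
}

## non-negative least squares on the basis {lag, lag^2}
.fitQuadLin <- function(lags, values, method = c("nnls", "ls")) {
    method <- match.arg(method)
    A <- cbind(lin = lags, quad = lags^2)
    if (all(values == 0)) {
        coefs <- c(lin = 0, quad = 0)
    } else if (method == "nnls") {
        coefs <- pracma::lsqnonneg(A, values)$x
    } else {
        coefs <- pmax(stats::coef(stats::lm.fit(A, values)), 0)
    }
    resid <- sqrt(mean((A %*% coefs - values)^2))
    list(lin = coefs[[1L]], quad = coefs[[2L]], residual = resid)
}

#' Fit velocity and diffusion coefficient to an MSD curve
#'
#' Least-squares fit of
#' \eqn{\langle(\Delta r)^2\rangle = 4D\,\Delta n + V^2\,\Delta n^2}
#' with both coefficients constrained non-negative (so \eqn{V =
#' \sqrt{\mathrm{quad}}} is real); `method = "ls"` uses ordinary least
#' squares with negative coefficients clipped to zero.
#'
#' @param curve an [MSDCurve] from [msdCurve()].
#' @param method `"nnls"` (default) or `"ls"`.
#' @return a [TranslationalFit] with `V` (L/nt) and `D` (L^2/nt).
#' @examples
#' fitTranslational(msdCurve(strrep("A", 100), nWindows = 50))  # V = 1, D = 0
#' @export
fitTranslational <- function(curve, method = c("nnls", "ls")) {
    stopifnot(is(curve, "MSDCurve"))
    if (length(curve@lags) < 2L)
        stop("need at least 2 curve points")
    f <- .fitQuadLin(curve@lags, curve@values, method)
    new("TranslationalFit", V = sqrt(f$quad), D = f$lin / 4,
        residual = f$residual)
}

#' Fit angular velocity and rotational diffusion to MSAD curves
#'
#' Per-axis non-negative fit of
#' \eqn{\langle(\Delta\theta)^2\rangle = 2D_R\,\Delta n + \omega^2\,\Delta n^2},
#' with magnitudes taken as the Euclidean norms of the per-axis components.
#'
#' @param curves named list of three angular [MSDCurve]s from
#'   [msadCurves()].
#' @param method `"nnls"` (default) or `"ls"`.
#' @return a [RotationalFit].
#' @examples
#' fitRotational(msadCurves(strrep("ATGC", 30), nWindows = 50))
#' @export
fitRotational <- function(curves, method = c("nnls", "ls")) {
    stopifnot(is.list(curves), length(curves) == 3L)
    axes <- names(curves)
    fits <- lapply(curves, function(cv) {
        stopifnot(is(cv, "MSDCurve"))
        .fitQuadLin(cv@lags, cv@values, method)
    })
    omegaAxis <- vapply(fits, function(f) sqrt(f$quad), numeric(1))
    drAxis <- vapply(fits, function(f) f$lin / 2, numeric(1))
    names(omegaAxis) <- names(drAxis) <- axes
    new("RotationalFit",
        omegaAxis = omegaAxis, drAxis = drAxis,
        omega = sqrt(sum(omegaAxis^2)), dR = sqrt(sum(drAxis^2)),
        residuals = vapply(fits, function(f) f$residual, numeric(1)))
}

#' Write trajectory and curve tables as TSV
#'
#' `writeTrajectoryTSV` writes step-by-step positions (2D: step, x, y; 3D:
#' step, cube vertex and cumulative angles); `writeCurveTSV` writes lag
#' versus MSD/MSAD values for one or more curves.
#'
#' @param traj result of [trajectory2D()] or [trajectory3D()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTrajectoryTSV <- function(traj, path) {
    tab <- if (is.list(traj)) {
        data.frame(step = seq_len(nrow(traj$vertices)) - 1L,
                   traj$vertices,
                   theta_x = traj$angles[, "X"],
                   theta_y = traj$angles[, "Y"],
                   theta_z = traj$angles[, "Z"])
    } else {
        data.frame(step = seq_len(nrow(traj)) - 1L, traj)
    }
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeTrajectoryTSV
#' @param curves an [MSDCurve] or named list of them (same lag grid).
#' @export
writeCurveTSV <- function(curves, path) {
    if (is(curves, "MSDCurve"))
        curves <- list(msd = curves)
    tab <- data.frame(lag = curves[[1L]]@lags)
    for (nm in names(curves))
        tab[[nm]] <- curves[[nm]]@values
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}
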