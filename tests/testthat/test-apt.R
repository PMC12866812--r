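test_that("2D trajectories follow the four unit vectors", {
  t1 <- trajectory2D("A")
  expect_equal(t1, rbind(c(x = 0, y = 0), c(x = 1, y = 0)))
  t2 <- trajectory2D("ACACGGCGTG")
  expect_equal(nrow(t2), 11)
  expect_equal(unname(t2[11, ]), c(-2, 2))
  t3 <- trajectory2D("AAAA")
  expect_equal(unname(t3[5, ]), c(4, 0))
  ## every step has unit length
  set.seed(31)
  s <- paste(sample(c("A","C","G","T"), 500, replace = TRUE), collapse = "")
  steps <- diff(trajectory2D(s))
  expect_true(all(rowSums(steps^2) == 1))
  expect_error(trajectory2D("ACGX"), "alphabet")
})

test_that("the cube labeling is antipodal with all-distinct neighbours", {
  ## every ordered base pair is reachable in one edge move (one coordinate
  ## flip), i.e. each vertex's three neighbours carry the three other bases
  for (b1 in c("A","C","G","T")) for (b2 in setdiff(c("A","C","G","T"), b1)) {
    tr <- trajectory3D(paste0(b1, b2))
    d <- sum(tr$vertices[1, ] != tr$vertices[2, ])
    expect_identical(d, 1L, info = paste(b1, b2))
  }
  ## walks never leave the cube and only traverse edges (or stay in place)
  set.seed(30)
  s <- paste(sample(c("A","C","G","T"), 400, replace = TRUE), collapse = "")
  tr <- trajectory3D(s)
  expect_true(all(tr$vertices %in% c(-1, 1)))
  flips <- rowSums(tr$vertices[-1, , drop = FALSE] !=
                   tr$vertices[-nrow(tr$vertices), , drop = FALSE])
  expect_true(all(flips %in% c(0L, 1L)))
})

test_that("3D moves rotate about exactly two axes by pi/2", {
  tr <- trajectory3D("AC")
  dtheta <- tr$angles[2, ] - tr$angles[1, ]
  expect_equal(sort(abs(unname(dtheta))), c(0, pi/2, pi/2))
  ## A -> C flips x: rotation about Y and Z, none about X
  expect_equal(unname(dtheta[["X"]]), 0)
  ## homopolymers freeze the particle
  trAA <- trajectory3D("AAAA")
  expect_true(all(trAA$angles == 0))
  expect_true(all(trAA$vertices[1, ] == t(trAA$vertices)))
})

test_that("a 4-periodic repeat accumulates angle about a single axis", {
  tr <- trajectory3D(strrep("ATGC", 10))
  ang <- tr$angles
  perStep <- diff(ang)
  ## one axis moves pi/2 every step in the same direction
  mono <- which(colSums(abs(abs(perStep) - pi/2) < 1e-12) == nrow(perStep) &
                abs(abs(colSums(perStep)) - nrow(perStep) * pi/2) < 1e-9)
  expect_length(mono, 1)
})

test_that("window bookkeeping matches the displacement-sequence scheme", {
  msd <- msdCurve(strrep("A", 8020))
  expect_identical(nWindows(msd), 8000L)
  expect_identical(msdLags(msd), 1:20)
  ## ballistic closed form
  expect_equal(msdValues(msd), (1:20)^2)
  ## shorter input reduces the window count to what is available
  msd2 <- msdCurve(strrep("A", 120))
  expect_identical(nWindows(msd2), 101L)
  expect_error(msdCurve("ACGT"), "insufficient")
  ## implementation agrees with an explicit loop oracle
  set.seed(32)
  s <- paste(sample(c("A","C","G","T"), 300, replace = TRUE), collapse = "")
  xy <- trajectory2D(s)
  expect_equal(msdValues(msdCurve(s, window = 10, nWindows = 50)),
               msdOracle(xy, 10, 50))
})

test_that("an unconstrained random sequence diffuses linearly", {
  set.seed(33)
  s <- paste(sample(c("A","C","G","T"), 1e5, replace = TRUE), collapse = "")
  ## non-overlapping windows give independent displacement sequences
  msd <- msdCurve(s, window = 20, stride = 20, nWindows = 4999)
  ## E[MSD(lag)] = lag for the 4-direction unit-step lattice walk;
  ## var of a squared lag-n displacement is ~ 2n(n-1), se = sqrt(var/n_w)
  lag <- msdLags(msd)
  se <- sqrt(2 * lag * lag / 4999)
  expect_true(all(abs(msdValues(msd) - lag) < 4 * se + 0.05))
})

test_that("fits recover closed-form curves to machine precision", {
  mk <- function(vals) new("MSDCurve", lags = 1:20, values = vals,
                           window = 20L, stride = 1L, nWindows = 1L,
                           kind = "translational", axis = NA_character_)
  ballistic <- fitTranslational(mk((1:20)^2))
  expect_equal(velocity(ballistic), 1, tolerance = 1e-10)
  expect_equal(diffusionCoefficient(ballistic), 0, tolerance = 1e-10)
  diffusive <- fitTranslational(mk(as.numeric(1:20)))
  expect_equal(velocity(diffusive), 0, tolerance = 1e-8)
  expect_equal(diffusionCoefficient(diffusive), 0.25, tolerance = 1e-8)
  zero <- fitTranslational(mk(rep(0, 20)))
  expect_equal(velocity(zero), 0)
  expect_equal(diffusionCoefficient(zero), 0)
  ## the NNLS fit never returns negative parameters on noisy curves
  set.seed(34)
  for (i in 1:20) {
    noisy <- fitTranslational(mk(pmax(1:20 + rnorm(20, 0, 2), 0)))
    expect_gte(velocity(noisy), 0)
    expect_gte(diffusionCoefficient(noisy), 0)
  }
})

test_that("rotational fits mirror the translational identities", {
  mkA <- function(vals, ax) new("MSDCurve", lags = 1:20, values = vals,
                                window = 20L, stride = 1L, nWindows = 1L,
                                kind = "angular", axis = ax)
  zero <- rep(0, 20)
  fit <- fitRotational(list(X = mkA((pi/2)^2 * (1:20)^2, "X"),
                            Y = mkA(zero, "Y"), Z = mkA(zero, "Z")))
  expect_equal(angularVelocity(fit), pi / 2, tolerance = 1e-10)
  expect_equal(rotationalDiffusion(fit), 0, tolerance = 1e-10)
  fit0 <- fitRotational(list(X = mkA(zero, "X"), Y = mkA(zero, "Y"),
                             Z = mkA(zero, "Z")))
  expect_equal(angularVelocity(fit0), 0)
  ## linear curves: 2 D_R per axis, Euclidean magnitude
  fitD <- fitRotational(list(X = mkA(as.numeric(1:20), "X"),
                             Y = mkA(as.numeric(1:20), "Y"),
                             Z = mkA(zero, "Z")))
  expect_equal(rotationalDiffusion(fitD), sqrt(2) * 0.5, tolerance = 1e-10)
})

test_that("MSAD windows and closed forms behave like the paper's scheme", {
  ## homopolymer: all three curves identically zero
  cs <- msadCurves(strrep("A", 100), nWindows = 50)
  for (cv in cs) expect_true(all(msdValues(cv) == 0))
  ## an 8020-nt input provides exactly 8000 angular windows
  set.seed(35)
  s <- paste(sample(c("A","C","G","T"), 8020, replace = TRUE), collapse = "")
  expect_identical(nWindows(msadCurves(s)$X), 8000L)
  ## 4-periodic face cycle: one axis ballistic at (pi/2)^2 lag^2
  cyc <- msadCurves(strrep("ATGC", 30), nWindows = 20)
  ball <- vapply(cyc, function(cv)
    isTRUE(all.equal(msdValues(cv), (pi/2)^2 * (1:20)^2)), logical(1))
  expect_identical(sum(ball), 1L)
  fit <- fitRotational(cyc)
  expect_equal(max(fit@omegaAxis), pi / 2, tolerance = 1e-8)
})
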