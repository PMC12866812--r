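worked <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)

test_that("the 2x2 worked configuration reproduces the printed sums", {
  s <- spinSums(worked)
  expect_equal(s@sumSpin, -2)
  expect_equal(s@sumPair, 0)
  expect_equal(s@nNodes, 4)
  expect_equal(s@nConnections, 4)
  expect_equal(s@nTouching, 8)
})

test_that("mean-field factors on the 2x2 worked configuration", {
  ip <- isingParams(worked)
  expect_equal(polarizationFactor(ip), -0.5)
  ## regression fixtures for the reconstructed closed forms: the coupling is
  ## the connected correlation over the squared site variance, the field the
  ## mean-field local field; magnitudes 4/9 and 0.9938
  expect_equal(interactionFactor(ip), -4 / 9, tolerance = 1e-12)
  expect_equal(round(abs(interactionFactor(ip)), 3), 0.444)
  expect_equal(biasFactor(ip), atanh(-0.5) - 2 * (-4 / 9) * (-0.5),
               tolerance = 1e-12)
  expect_equal(biasFactor(ip), -0.994, tolerance = 1e-3)
})

test_that("count formulas scale with the lattice shape", {
  set.seed(41)
  for (i in 1:10) {
    nr <- sample(2:40, 1); nc <- sample(2:40, 1)
    s <- spinSums(matrix(sample(0:1, nr * nc, replace = TRUE), nr, nc))
    expect_equal(s@nNodes, nr * nc)
    expect_equal(s@nConnections, (nr - 1) * nc + (nc - 1) * nr)
    expect_equal(s@nTouching, 12 * (nr - 1) * (nc - 1) - 4)
    expect_lte(abs(s@sumSpin), s@nNodes)
    expect_lte(abs(s@sumPair), s@nConnections)
  }
})

test_that("a 3x3 checkerboard is maximally anticorrelated", {
  cb <- outer(1:3, 1:3, function(r, c) (r + c) %% 2)
  s <- spinSums(cb)
  expect_equal(s@sumPair, -12)
  expect_equal(s@nConnections, 12)
  expect_equal(s@nTouching, 44)
  ip <- isingParams(cb)
  ## gamma = -1/9 (4 ones, 5 zeros); lambda near its lower bound -1
  expect_equal(polarizationFactor(ip), -1 / 9)
  expect_lt(interactionFactor(ip), -0.9)
  expect_gt(interactionFactor(ip), -1.1)
})

test_that("polarization symmetry and bounds", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(sample(0:1, 16 * 16, replace = TRUE), 16, 16)
    g <- polarizationFactor(isingParams(m))
    gc <- polarizationFactor(isingParams(1 - m))
    expect_equal(gc, -g)
    expect_lte(abs(g), 1)
  }
  ## balanced random lattice: gamma ~ 0 within 3/sqrt(N_T)
  set.seed(43)
  m <- matrix(sample(0:1, 128 * 128, replace = TRUE), 128, 128)
  expect_lt(abs(polarizationFactor(isingParams(m))), 3 / sqrt(128 * 128))
  ## fully polarised lattice: gamma = 1, coupling undefined
  ones <- isingParams(matrix(1, 4, 4))
  expect_equal(polarizationFactor(ones), 1)
  expect_true(is.nan(interactionFactor(ones)))
  expect_identical(biasFactor(ones), Inf)
})

test_that("sequences map to spin lattices through simple unmapping", {
  expect_identical(toSpinMatrix("A", 1, 2), matrix(c(-1L, -1L), 1))
  expect_identical(toSpinMatrix(strrep("T", 8192), 128, 128),
                   matrix(1L, 128, 128))
  ## an 8196-nt sequence provides 16392 bits; the first 16384 are used
  set.seed(44)
  s <- paste(sample(c("A","C","G","T"), 8196, replace = TRUE), collapse = "")
  m <- toSpinMatrix(s, 128, 128)
  expect_identical(dim(m), c(128L, 128L))
  bits <- simpleUnmap(s)
  expect_identical(as.integer((flattenBits((m + 1L) %/% 2L))),
                   bits[1:16384])
  expect_error(toSpinMatrix("ACGT", 128, 128), "length")
})
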