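allSchemes <- dnastoreSchemes()

test_that("the published 10-bit example encodes and decodes", {
  tbl <- buildRuleTable("RInf-B4", guard = FALSE)
  expect_identical(as.character(encodeSequence("1110011100", tbl)), "ACCGTG")
  expect_identical(decodeSequence("ACCGTG", tbl, asString = TRUE),
                   "1110011100")
})

test_that("encoded lengths are deterministic functions of the bit length", {
  set.seed(3)
  bits <- randomBits(16384)
  expected <- c(simple = 8192L, "RInf-B16" = 8196L, "RInf-B4" = 8194L,
                "R0-B9" = 10340L, "R0-B3" = 10339L)
  for (sc in names(expected))
    expect_identical(length(encodeSequence(bits, sc)), expected[[sc]],
                     info = sc)
  ## a second payload gives identical lengths (guard bit fixes digit count)
  bits2 <- randomBits(16384)
  for (sc in names(expected))
    expect_identical(length(encodeSequence(bits2, sc)), expected[[sc]])
})

test_that("every scheme round-trips random payloads exactly", {
  set.seed(123)
  for (sc in setdiff(allSchemes, "simple")) {
    tbl <- buildRuleTable(sc)
    for (i in 1:200) {
      bits <- randomBits(sample(1:2048, 1))
      expect_identical(decodeSequence(encodeSequence(bits, tbl), tbl), bits)
    }
  }
  for (i in 1:200) {                 # simple mapping: even lengths only
    bits <- randomBits(2 * sample(1:1024, 1))
    expect_identical(simpleUnmap(simpleMap(bits)), bits)
  }
})

test_that("run-length guarantees hold over fuzzed payloads", {
  set.seed(99)
  bound <- c("R1-B12" = 2L, "R0-B9" = 1L, "R0-B3" = 1L)
  for (sc in names(bound)) {
    tbl <- buildRuleTable(sc)
    runs <- vapply(1:1000, function(i)
      longestHomopolymer(encodeSequence(randomBits(sample(1:512, 1)), tbl)),
      integer(1))
    expect_true(all(runs <= bound[[sc]]), info = sc)
  }
})

test_that("empty guarded payloads reduce to the guard bit", {
  tbl <- buildRuleTable("R0-B9")
  s <- encodeSequence(integer(0), tbl)
  expect_identical(substr(as.character(s), 1, 2), "AT")
  expect_identical(length(s), 4L)          # initiator + one unit for value 1
  expect_identical(decodeSequence(s, tbl), integer(0))
})

test_that("corrupt or malformed sequences are rejected with positions", {
  tbl <- buildRuleTable("R0-B9")
  expect_error(decodeSequence("ATAA", tbl), "corrupt")   # homodimer unit
  expect_error(decodeSequence("AAAT", tbl), "initiator")
  expect_error(decodeSequence("GGATAC", tbl), "initiator")
  expect_error(decodeSequence("ATCAG", tbl), "format")
  ## corrupting one unit of a valid sequence is caught
  s <- as.character(encodeSequence(randomBits(64), tbl))
  sub <- sub("^(AT..)..", "\\1AA", s)      # homodimer cannot occur under R0
  expect_error(decodeSequence(sub, tbl), "corrupt")
})

test_that("simple mapping is the positional 2-bit code", {
  expect_identical(as.character(simpleMap("00011011")), "ACGT")
  expect_identical(as.character(simpleMap("")), "")
  expect_identical(simpleUnmap("ACGT", asString = TRUE), "00011011")
  expect_error(simpleMap("101"), "even")
  set.seed(5)
  bits <- randomBits(16384)
  expect_identical(length(simpleMap(bits)), 8192L)
})
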