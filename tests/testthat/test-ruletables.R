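schemes <- setdiff(dnastoreSchemes(), "simple")

test_that("shipped rule tables satisfy the unit-set constraints", {
  tbl <- buildRuleTable("R0-B9")
  for (ctx in c("A", "C", "G", "T")) {
    row <- ruleRows(tbl)[[ctx]]
    expect_length(row, 9)
    expect_false(any(duplicated(row)))
    expect_false(any(substr(row, 1, 1) == substr(row, 2, 2)))  # heterodimers
    expect_false(any(substr(row, 1, 1) == ctx))  # cannot extend the context
  }
  tbl12 <- buildRuleTable("R1-B12")
  for (row in ruleRows(tbl12)) {
    expect_length(row, 12)
    expect_false(any(substr(row, 1, 1) == substr(row, 2, 2)))
  }
  expect_length(ruleRows(buildRuleTable("RInf-B16"))$A, 16)
  expect_length(ruleRows(buildRuleTable("R0-B3"))$G, 3)
})

test_that("scheme metadata matches the design-rule family", {
  meta <- data.frame(
    scheme  = c("RInf-B16", "RInf-B4", "R1-B12", "R0-B9", "R0-B3"),
    unitLen = c(2L, 1L, 2L, 2L, 1L),
    radix   = c(16L, 4L, 12L, 9L, 3L),
    maxRun  = c(Inf, Inf, 2, 1, 1),
    init    = c("AT", "A", "AT", "AT", "A"))
  for (i in seq_len(nrow(meta))) {
    tbl <- buildRuleTable(meta$scheme[i])
    expect_identical(unitLength(tbl), meta$unitLen[i])
    expect_identical(radixBase(tbl), meta$radix[i])
    expect_equal(maxRun(tbl), meta$maxRun[i])
    expect_identical(initiator(tbl), meta$init[i])
    expect_true(guardBit(tbl))
  }
  expect_false(guardBit(buildRuleTable("simple")))
  ## short aliases resolve
  expect_identical(schemeId(buildRuleTable("R9")), "R0-B9")
})

test_that("tables violating the constraints are rejected", {
  ## duplicate unit breaks the bijection
  bad <- ruleRows(buildRuleTable("R0-B3"))
  bad$A <- c("C", "C", "T")
  expect_error(buildRuleTable("R0-B3", rows = bad), "bijection")
  ## unit equal to its context creates a homopolymer under max_run = 1
  bad <- ruleRows(buildRuleTable("R0-B3"))
  bad$A <- c("A", "C", "G")
  expect_error(buildRuleTable("R0-B3", rows = bad), "homopolymer")
  ## wrong cardinality
  bad <- ruleRows(buildRuleTable("R0-B9"))
  bad$A <- bad$A[1:8]
  expect_error(buildRuleTable("R0-B9", rows = bad), "radix")
})

test_that("JSON serialisation is bit-exact", {
  path <- withr::local_tempfile(fileext = ".json")
  for (sc in schemes) {
    tbl <- buildRuleTable(sc)
    writeRuleTableJSON(tbl, path)
    back <- readRuleTableJSON(path)
    expect_identical(ruleRows(back), ruleRows(tbl))
    expect_identical(initiator(back), initiator(tbl))
    expect_equal(maxRun(back), maxRun(tbl))
    expect_identical(guardBit(back), guardBit(tbl))
  }
})

test_that("row overrides are honoured and validated", {
  ## legal override: swap two units in one context of R0-B3
  rows <- ruleRows(buildRuleTable("R0-B3"))
  rows$A <- c("G", "C", "T")
  tbl <- buildRuleTable("R0-B3", rows = rows)
  expect_identical(schemeId(tbl), "custom")
  bits <- randomBits(64)
  expect_identical(decodeSequence(encodeSequence(bits, tbl), tbl), bits)
})
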