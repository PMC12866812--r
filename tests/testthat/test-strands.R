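test_that("strand assembly follows the 20+8+57+21 layout", {
  set.seed(8)
  payload <- paste(sample(c("A","C","G","T"), 57, replace = TRUE),
                   collapse = "")
  st <- assembleStrands(payload)
  expect_length(st, 1)
  expect_identical(Biostrings::width(st), 106L)
  full <- as.character(st[[1]])
  expect_identical(substr(full, 1, 20), unname(primerRegions()["forward"]))
  expect_identical(substr(full, 86, 106), unname(primerRegions()["reverse"]))
  expect_identical(as.character(strandPayload(st)[[1]]), payload)
  expect_identical(strandOrdinal(st), 0)
})

test_that("long payloads split into ceiling(n/57) indexed strands", {
  set.seed(9)
  seq <- as.character(encodeSequence(randomBits(16384), "R0-B9"))
  expect_identical(nchar(seq), 10340L)
  st <- assembleStrands(seq)
  expect_length(st, 182)                       # 181 full + one 23-nt chunk
  expect_identical(strandOrdinal(st), as.numeric(0:181))
  w <- S4Vectors::mcols(st)$payloadWidth
  expect_identical(w, c(rep(57L, 181), 23L))
  expect_identical(unique(Biostrings::width(st)[1:181]), 106L)
  ## payloads reassemble the original sequence
  expect_identical(paste(as.character(strandPayload(st)), collapse = ""), seq)
  ## two-chunk example
  st2 <- assembleStrands(strrep("AC", 57), chunk = 57)   # 114-nt payload
  expect_length(st2, 2)
  expect_identical(strandOrdinal(st2), c(0, 1))
})

test_that("sequence identity is the positional match percentage", {
  ref <- strrep("ACGTA", 12)                   # 60 nt
  expect_equal(sequenceIdentity(ref, ref), 100)
  read <- paste0(substr(ref, 1, 59), "C")      # one mismatch
  expect_equal(sequenceIdentity(read, ref), 100 * 59 / 60)
  ## 57-nt payload with one error: 98.2%
  p57 <- strrep("ACG", 19)
  p57err <- paste0("T", substr(p57, 2, 57))
  expect_equal(round(sequenceIdentity(p57err, p57), 1), 98.2)
  ## length mismatch counts as errors
  expect_equal(sequenceIdentity(substr(ref, 1, 30), ref), 50)
  expect_error(sequenceIdentity("ACGT", ""), "empty")
})

test_that("FASTA and FASTQ round trips preserve strands", {
  set.seed(10)
  st <- assembleStrands(as.character(encodeSequence(randomBits(800), "R0-B9")),
                        prefix = "R0-B9")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(st, fa)
  back <- readSequences(fa)
  expect_identical(as.character(back), as.character(st))
  expect_identical(names(back)[1], "R0-B9_0")
  ## minimal FASTQ is accepted (qualities ignored)
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@read1", as.character(st[[1]]), "+",
               strrep("I", 106)), fq)
  rd <- readSequences(fq)
  expect_equal(sequenceIdentity(rd[[1]], st[[1]]), 100)
})
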