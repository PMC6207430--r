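test_that("packaged FASTA + config load into a validated construct", {
  fa <- system.file("extdata", "uag_reporter_synthetic.fasta",
                    package = "stallscope")
  yml <- system.file("extdata", "uag_reporter_synthetic.yml",
                     package = "stallscope")
  c1 <- load_construct(fa, yml)
  expect_s3_class(c1, "reporter_construct")
  expect_identical(c1$anchor_peptide, "LEHHHHHH")
  expect_identical(c1$tail_length, 102L)
  expect_identical(c1$stall_offset %% 3L, 0L)
  expect_identical(c1$coding_sequence, uag_reporter()$coding_sequence)
})

test_that("construct invariants are enforced", {
  c1 <- reporter_construct("ATGTAGAAA", 3L)
  expect_identical(c1$tail_length, 3L)
  expect_error(reporter_construct("ATAGTAGAA", 4L), "multiple of 3")
  expect_error(reporter_construct("ATGAAAAAA", 3L), "orphan codon")
  expect_error(reporter_construct("ATGNAGTAG", 6L), "DNA alphabet")
  expect_error(reporter_construct("ATGTAGAAA", 3L, anchor_peptide = "K"),
               "anchor peptide")
})

test_that("translation follows the standard code and stops correctly", {
  c1 <- reporter_construct("ATGAAATAATAG", 9L)
  tr <- translate_from(c1, 0L)
  expect_identical(tr$residues, "MK")
  expect_identical(tr$terminator, "stop_codon")
  expect_identical(tr$stop_offset, 6L)
  expect_false(tr$stop_is_orphan)
})

test_that("the orphan codon stalls translation whichever way it is flagged", {
  c1 <- uag_reporter()
  st <- c1$stall_offset
  tr1 <- translate_from(c1, st, orphan_is_stop = FALSE)
  tr2 <- translate_from(c1, st, orphan_is_stop = TRUE)
  expect_identical(tr1$residues, "")
  expect_identical(tr2$residues, "")
  expect_true(tr1$stop_is_orphan)
  expect_false(tr2$stop_is_orphan)
})

test_that("diagnostic frames of the reporter decode as documented", {
  c1 <- uag_reporter()
  st <- c1$stall_offset
  expect_match(translate_from(c1, st + 19L, 38L)$residues, "^MVR")
  expect_match(translate_from(c1, st + 10L, 38L)$residues, "^GDPMVR")
  expect_match(translate_from(c1, st + 4L, 38L)$residues, "^ALGDPMVR")
  expect_identical(translate_from(c1, st + 3L, 38L)$residues, "GAR")
  expect_identical(translate_from(c1, st - 3L)$residues, "H")
  expect_identical(translate_from(c1, st - 6L)$residues, "HH")
  ## frame-0 readthrough reproduces the anchor as its suffix
  pre <- pre_stall_protein(c1)
  expect_match(pre, "LEHHHHHH$")
  ## the anchor is preceded by a tryptic K site
  expect_identical(substring(pre, nchar(pre) - 8L, nchar(pre) - 8L), "K")
})

test_that("translate_from never decodes at or past its reported stop", {
  c1 <- uag_reporter()
  for (o in c(0L, 3L, c1$stall_offset + c(-6L, -3L, 3L, 4L, 5L, 10L, 19L))) {
    tr <- translate_from(c1, o)
    if (tr$terminator == "stop_codon")
      expect_identical(tr$start_offset + 3L * nchar(tr$residues),
                       tr$stop_offset)
  }
})

test_that("stop landscape lists each tail stop in its frame", {
  ## tail carrying TAA, TGA and TAG in three different frame classes
  c0 <- reporter_construct(paste0("ATGTAG", "CTAACTGACTAGC"), 3L)
  ls0 <- stop_landscape(c0)
  expect_identical(nrow(ls0), 3L)
  expect_setequal(ls0$frame, 0:2)
  expect_setequal(ls0$codon, c("TAA", "TGA", "TAG"))
  expect_identical(ls0$codon[ls0$is_orphan], "TAG")
  expect_false(is.unsorted(ls0$stop_offset))
  expect_identical(nrow(stop_landscape(reporter_construct("ATGTAG", 3L))), 0L)
})

test_that("every tail-library entry terminates at a landscape stop or the cap", {
  c1 <- uag_reporter()
  ls <- stop_landscape(c1)
  cfg <- library_config()
  for (s in c(-6L, -3L, 1L, 3L, 4L, 5L, 10L, 19L, 25L)) {
    tr <- translate_from(c1, c1$stall_offset + s,
                         max_residues = cfg$max_tail_residues)
    if (tr$terminator == "stop_codon" && tr$stop_offset > c1$stall_offset)
      expect_true(tr$stop_offset %in% ls$stop_offset)
    else
      expect_true(tr$terminator %in% c("length_cap", "sequence_end") ||
                    tr$stop_offset == c1$stall_offset)
  }
})
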