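test_that("suppression library holds one full-length product per residue", {
  c1 <- uag_reporter()
  sup <- suppression_variants(c1)
  expect_identical(nrow(sup), 20L)
  expect_setequal(sup$suppressed_residue, stallscope:::CANONICAL_AA)
  q <- sup[sup$suppressed_residue == "Q", ]
  expect_true("LEHHHHHHQGAR" %in% digest(q)$peptide)
  ## immediate frame-0 stop after the orphan: entries are anchor + residue
  c0 <- reporter_construct("ATGAAACTGGAACACCACTAGTAAGGT", 18L,
                           anchor_peptide = "LEHH")
  sup0 <- suppression_variants(c0)
  expect_true(all(nchar(sup0$sequence) == nchar(pre_stall_protein(c0)) + 1L))
})

test_that("tail library covers the resume window with capped entries", {
  c1 <- uag_reporter()
  tl <- tail_library(c1)
  expect_true(all(nchar(tl$sequence) <= 38L))
  expect_false(any(grepl("\\*", tl$sequence)))
  s4 <- tl$sequence[tl$resume_offset == 4L]
  expect_match(s4, "^ALGDPMVR")
  expect_warning(cfg_small <- library_config(resume_window = c(-3L, 3L)),
                 "resume_window")
  expect_lte(nrow(tail_library(c1, cfg_small)), 7L)
  ## anchored product context carries the same tail
  expect_identical(tl$product[tl$resume_offset == 4L],
                   paste0(pre_stall_protein(c1), s4))
})

test_that("tagged library appends the ssrA tag at and after the stall", {
  c1 <- uag_reporter()
  tg <- tagged_variants(c1)
  t0 <- tg[tg$truncation == 0L, ]
  expect_identical(nrow(t0), 1L)
  expect_true("LEHHHHHHAANDENYALDD" %in% digest(t0)$peptide)
  t2 <- tg[tg$truncation == 2L & tg$resume_offset == 10L, ]
  expect_true("LEHHHHHHGDAANDENYALDD" %in% digest(t2)$peptide)
  tg_aa <- tagged_variants(uag_reporter(tag_variant = "AA"))
  expect_true(all(grepl("AANDENYALAA$", tg_aa$sequence)))
})

test_that("combinatorial library enumerates anchor+X^k exactly", {
  lib3 <- combinatorial_library(library_config())
  expect_identical(nrow(lib3), 8000L)
  expect_false(any(duplicated(lib3$sequence)))
  lib1 <- combinatorial_library(library_config(combinatorial_positions = 1L))
  expect_identical(nrow(lib1), 20L)
  expect_true("LEHHHHHHQ" %in% lib1$sequence)
})

test_that("digestion applies K/R rules with the proline exception", {
  d <- digest("MKPEPTIDERLEHHHHHH")
  expect_true("MKPEPTIDER" %in% d$peptide)     # KP left uncut
  expect_true("LEHHHHHH" %in% d$peptide)
  expect_identical(nrow(digest("MKR")), 0L)    # all fragments < 5 aa
})

test_that("digestion equals the brute-force substring oracle", {
  withr::with_seed(7L, {
    for (i in 1:25) {
      prot <- paste(sample(stallscope:::CANONICAL_AA,
                           sample(8:30, 1L), replace = TRUE), collapse = "")
      spec <- trypsin_spec(max_miscleavages = sample(0:3, 1L),
                           min_length = sample(1:6, 1L))
      expect_identical(sort(digest(prot, spec)$peptide),
                       digest_oracle(prot, spec))
    }
  })
})

test_that("library FASTA export is deterministic and round-trips", {
  c1 <- uag_reporter()
  sup <- suppression_variants(c1)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_library(sup, f1); write_library(sup, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- Biostrings::readAAStringSet(f1)
  expect_identical(length(back), 20L)
  expect_setequal(as.character(back), sup$sequence)
  expect_true(all(grepl("^suppression\\|", names(back))))
  fc <- tempfile(fileext = ".fasta")
  write_library(combinatorial_library(library_config()), fc)
  expect_identical(length(Biostrings::readAAStringSet(fc)), 8000L)
})

test_that("every reported C-terminal peptide is searchable in the libraries", {
  c1 <- uag_reporter()
  libs <- build_search_libraries(c1)
  pepset <- digest(libs$main)$peptide
  comb <- libs$combinatorial$sequence
  ids <- reporter_identifications()
  obs <- ids$sequence[ids$score >= 15]
  expect_true(all(obs %in% c(pepset, comb)))
  xxx <- xxx_identifications()
  expect_true(all(xxx$sequence %in% comb))
})
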