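c1 <- uag_reporter()

test_that("diagnostic peptides receive the documented minimal explanations", {
  ex <- explain("LEHHHHHHMVR", c1)
  expect_gt(length(ex), 0L)
  expect_identical(ex[[1L]]$n_junctions, 1L)
  expect_identical(ex[[1L]]$net_shift, 19)

  ex <- explain("LEHHHHHHH", c1)
  expect_identical(ex[[1L]]$n_junctions, 1L)
  expect_identical(ex[[1L]]$net_shift, -3)

  ex <- explain("LEHHHHHHQGAR", c1)
  expect_identical(ex[[1L]]$n_junctions, 0L)
  expect_identical(ex[[1L]]$suppressed_residue, "Q")

  ex <- explain("LEHHHHHHAANDENYALDD", c1)
  best <- ex[[1L]]
  expect_identical(best$tag_len, 11L)
  expect_identical(best$n_junctions, 0L)
  expect_identical(nrow(best$segments), 0L)   # tag directly at the stall
})

test_that("the double-His extension surfaces both slip readings", {
  ex <- explain("LEHHHHHHHH", c1)
  njs <- vapply(ex, `[[`, integer(1L), "n_junctions")
  nets <- vapply(ex, `[[`, numeric(1L), "net_shift")
  expect_identical(ex[[1L]]$n_junctions, 1L)
  expect_identical(ex[[1L]]$net_shift, -6)
  two_minus3 <- vapply(ex, function(e)
    e$n_junctions == 2L && all(e$segments$s == c(-3L, -3L)), logical(1L))
  expect_true(any(two_minus3))
})

test_that("classification follows the outcome taxonomy", {
  cases <- list(
    LEHHHHHH = "termination_or_release",
    LEHHHHHHQGAR = "suppression",
    LEHHHHHHYGAR = "suppression",
    LEHHHHHHMVR = "frameshift",
    LEHHHHHHGDPMVR = "frameshift",
    ALGDPMVR = "frameshift",
    LEHHHHHHAANDENYALDD = "tagged",
    LEHHHHHHGDAANDENYALDD = "tagged",
    LEHHHHHHQQR = "fidelity_loss_candidate")
  for (p in names(cases))
    expect_identical(classify(p, explain(p, c1)), cases[[p]],
                     label = paste("classify", p))
  expect_identical(classify("WWWWWW", explain("WWWWWW", c1)), "unexplained")
})

test_that("classification is order-independent in its explanation list", {
  p <- "LEHHHHHHHH"
  ex <- explain(p, c1)
  withr::with_seed(1L, {
    for (i in 1:5) expect_identical(classify(p, sample(ex)), "frameshift")
  })
})

test_that("explanations re-synthesize their peptide exactly", {
  peps <- c("LEHHHHHHMVR", "LEHHHHHHH", "LEHHHHHHHH", "LEHHHHHHQGAR",
            "LEHHHHHHGDPMVR", "ALGDPMVR", "INGINSTGR", "SVIPWFVK",
            "LEHHHHHHAANDENYALDD", "LEHHHHHHGDAANDENYALDD",
            "LEHHHHHHQQR", "LEHHHHHHSLK")
  for (p in peps) {
    for (e in explain(p, c1))
      expect_identical(resynthesize(p, e, c1), p,
                       label = paste("resynthesis of", p))
  }
})

test_that("shared residues of nested frameshift peptides map to the same mRNA", {
  m_pos <- function(p) {
    e <- explain(p, c1)[[1L]]
    segs <- e$segments
    hits <- integer(0)
    for (i in seq_len(nrow(segs))) {
      res <- strsplit(p, "")[[1L]]
      for (k in seq_len(segs$length[i]) - 1L)
        if (res[segs$pep_start[i] + k] == "M")
          hits <- c(hits, segs$s[i] + 3L * k)
    }
    hits
  }
  expect_identical(m_pos("ALGDPMVR"), 19L)
  expect_identical(m_pos("LEHHHHHHGDPMVR"), 19L)
  expect_identical(m_pos("LEHHHHHHMVR"), 19L)
})

test_that("inference agrees with the forward-enumeration oracle", {
  tiny <- tiny_construct()
  cfg2 <- inference_config(event_budget = 2L)
  anchored <- c("LEHH", "LEHHH", "LEHHHH", "LEHHQGAR", "LEHHQ", "LEHHGAR",
                "LEHHVR", "LEHHAANDENYALDD", "LEHHGAANDENYALDD", "LEHHW")
  for (p in anchored)
    expect_identical(explain_sig(explain(p, tiny, cfg2)),
                     explain_oracle(p, tiny, cfg2),
                     label = paste("oracle(anchored)", p))
  cfg1 <- inference_config(event_budget = 1L)
  unanchored <- c("GARVA", "ARVAG", "VRWCS", "GGGGG")
  for (p in unanchored)
    expect_identical(explain_sig(explain(p, tiny, cfg1)),
                     explain_oracle(p, tiny, cfg1),
                     label = paste("oracle(unanchored)", p))
})

test_that("non-canonical residues are rejected", {
  expect_error(explain("LEHB", c1), "non-canonical")
})

test_that("summaries aggregate categories, offsets and extent", {
  s1 <- summarize_identifications(
    data.frame(sequence = "LEHHHHHH", score = 99), c1)
  expect_identical(nrow(s1$peptides), 1L)
  expect_identical(s1$peptides$category, "termination_or_release")

  s <- summarize_identifications(reporter_identifications(), c1)
  expect_identical(s$n_filtered, 1L)
  expect_identical(unname(s$by_category[["suppression"]]), 4L)
  expect_true(all(c(-6, -3, 10, 19) %in%
                    as.numeric(names(s$by_offset))))
  expect_identical(s$max_downstream_extent, 82)
  expect_error(summarize_identifications(
    data.frame(sequence = character(0), score = numeric(0)), c1), "empty")
})

test_that("explanation JSON dump is written and parseable", {
  f <- tempfile(fileext = ".json")
  explanations_to_json(c("LEHHHHHHMVR", "LEHHHHHHQGAR"), c1, f)
  back <- jsonlite::read_json(f)
  expect_length(back, 2L)
  expect_identical(back[[1L]]$category, "frameshift")
})
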