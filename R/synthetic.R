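#' Translation-outcome model for stochastic simulation
#'
#' Probabilities of the fates of a ribosome stalled at the unassigned codon:
#' unmodified release (termination or ArfA/ArfB rescue), near-cognate
#' suppression (default mass on the observed suppressors Q, Y, D, V),
#' ribosomal frameshifting (support must include the observed -6, -3, +10,
#' +19 nt resumes), tmRNA tagging with a truncation-length distribution,
#' and loss of translational fidelity appending k >= 2 untemplated residues.
#' Within-class distributions default to uniform; the study's spectral
#' counting is not quantitative, so the across-class defaults are
#' conventional, not biological estimates.
#'
#' @param p_release,p_suppression,p_frameshift,p_tag,p_fidelity_loss class
#'   probabilities; must sum to 1.
#' @param suppressors named probability vector over suppressed residues.
#' @param frameshifts named probability vector over resume offsets (nt,
#'   bases-skipped convention).
#' @param tag_truncation probability vector over 0..len-1 decoded tail
#'   residues preceding the tag.
#' @param fidelity_geom_p geometric parameter for the number of untemplated
#'   residues beyond the minimum of 2.
#' @param fidelity_max cap on appended untemplated residues.
#' @return list of class `outcome_model`.
#' @export
outcome_model <- function(p_release = 0.20, p_suppression = 0.25,
                          p_frameshift = 0.25, p_tag = 0.20,
                          p_fidelity_loss = 0.10,
                          suppressors = c(Q = 0.25, Y = 0.25,
                                          D = 0.25, V = 0.25),
                          frameshifts = c(`-6` = 0.25, `-3` = 0.25,
                                          `10` = 0.25, `19` = 0.25),
                          tag_truncation = c(0.5, 0.25, 0.25),
                          fidelity_geom_p = 0.5,
                          fidelity_max = 8L) {
  p <- c(p_release, p_suppression, p_frameshift, p_tag, p_fidelity_loss)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("class probabilities must be nonnegative and sum to 1")
  if (abs(sum(suppressors) - 1) > 1e-8 || abs(sum(frameshifts) - 1) > 1e-8 ||
      abs(sum(tag_truncation) - 1) > 1e-8)
    stop("within-class probabilities must each sum to 1")
  structure(list(p_release = p_release, p_suppression = p_suppression,
                 p_frameshift = p_frameshift, p_tag = p_tag,
                 p_fidelity_loss = p_fidelity_loss,
                 suppressors = suppressors,
                 frameshifts = frameshifts,
                 tag_truncation = tag_truncation,
                 fidelity_geom_p = fidelity_geom_p,
                 fidelity_max = as.integer(fidelity_max)),
            class = "outcome_model")
}

#' Sample protein molecules from the outcome model
#'
#' Each molecule carries its true event provenance: outcome class,
#' suppressed residue, resume offset, tag truncation and the number of
#' mRNA-templated frameshift junctions (`NA` for loss-of-fidelity products,
#' whose untemplated extensions have no junction count).
#'
#' @param construct a `reporter_construct`.
#' @param model an `outcome_model`.
#' @param n number of molecules.
#' @param seed integer seed; identical seeds give identical pools.
#' @return data.frame with columns `molecule`, `sequence`, `outcome`,
#'   `suppressed`, `resume_offset`, `truncation`, `k_untemplated`,
#'   `n_junctions`.
#' @export
sample_outcomes <- function(construct, model, n, seed = 1L) {
  stopifnot(n >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  stall <- construct$stall_offset
  pre <- pre_stall_protein(construct)
  tag <- SSRA_TAGS[[construct$tag_variant]]
  cfg <- library_config()
  frame0_cont <- translate_from(construct, stall + 3L,
                                max_residues = cfg$max_tail_residues)$residues
  tail_of <- function(s, cap = cfg$max_tail_residues)
    translate_from(construct, stall + s, max_residues = cap)$residues

  classes <- sample(c("release", "suppression", "frameshift", "tagged",
                      "fidelity_loss"), n, replace = TRUE,
                    prob = c(model$p_release, model$p_suppression,
                             model$p_frameshift, model$p_tag,
                             model$p_fidelity_loss))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    row <- list(outcome = cl, suppressed = NA_character_,
                resume_offset = NA_integer_, truncation = NA_integer_,
                k_untemplated = NA_integer_, n_junctions = NA_integer_)
    if (cl == "release") {
      row$sequence <- pre
      row$n_junctions <- 0L
    } else if (cl == "suppression") {
      aa <- sample(names(model$suppressors), 1L, prob = model$suppressors)
      row$sequence <- paste0(pre, aa, frame0_cont)
      row$suppressed <- aa
      row$n_junctions <- 0L
    } else if (cl == "frameshift") {
      s <- as.integer(sample(names(model$frameshifts), 1L,
                             prob = model$frameshifts))
      row$sequence <- paste0(pre, tail_of(s))
      row$resume_offset <- s
      row$n_junctions <- 1L
    } else if (cl == "tagged") {
      t <- sample(seq_along(model$tag_truncation) - 1L, 1L,
                  prob = model$tag_truncation)
      if (t == 0L) {
        row$sequence <- paste0(pre, tag)
        row$n_junctions <- 0L
      } else {
        s <- as.integer(sample(names(model$frameshifts), 1L,
                               prob = model$frameshifts))
        row$sequence <- paste0(pre, substr(tail_of(s), 1L, t), tag)
        row$resume_offset <- s
        row$n_junctions <- 1L
      }
      row$truncation <- t
    } else {
      k <- min(2L + stats::rgeom(1L, model$fidelity_geom_p),
               model$fidelity_max)
      row$sequence <- paste0(pre, paste(sample(CANONICAL_AA, k,
                                               replace = TRUE),
                                        collapse = ""))
      row$k_untemplated <- k
    }
    out[[i]] <- row
  }
  data.frame(molecule = seq_len(n),
             sequence = vapply(out, `[[`, character(1L), "sequence"),
             outcome = classes,
             suppressed = vapply(out, `[[`, character(1L), "suppressed"),
             resume_offset = vapply(out, `[[`, integer(1L), "resume_offset"),
             truncation = vapply(out, `[[`, integer(1L), "truncation"),
             k_untemplated = vapply(out, `[[`, integer(1L), "k_untemplated"),
             n_junctions = vapply(out, `[[`, integer(1L), "n_junctions"),
             stringsAsFactors = FALSE)
}

## save/restore .Random.seed so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Digest a molecule pool into a search-engine-style identification table
#'
#' Digests each molecule with trypsin rules, detects each (molecule,
#' peptide) pair with probability `detect_prob`, and assigns scores from a
#' two-component Gaussian (correct versus noise identifications). Peptides
#' from the C-terminal region (those containing the anchor, plus everything
#' decoded after it) retain the molecule's true event provenance for
#' recovery experiments.
#'
#' @param pool output of [sample_outcomes()].
#' @param spec a `trypsin_spec`.
#' @param detect_prob per-peptide detection probability.
#' @param score_model list with `correct` (mean, sd), `noise` (mean, sd) and
#'   `p_noise`, the fraction of identifications drawn from the noise
#'   component. The study's validation threshold of 15 separates the default
#'   components.
#' @param seed integer seed.
#' @param anchor anchor residue string marking C-terminal-region peptides.
#' @return data.frame with columns `sequence`, `score`, `sample`,
#'   `molecule`, `is_cterm`, `true_outcome`, `true_n_junctions`.
#' @export
to_identifications <- function(pool, spec = trypsin_spec(),
                               detect_prob = 1,
                               score_model = list(correct = c(mean = 30,
                                                              sd = 5),
                                                  noise = c(mean = 8,
                                                            sd = 4),
                                                  p_noise = 0.05),
                               seed = 1L,
                               anchor = "LEHHHHHH") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)

  useq <- unique(pool$sequence)
  dig <- lapply(useq, function(s) unique(digest_one(s, spec)))
  idx <- match(pool$sequence, useq)
  lens <- lengths(dig)[idx]
  mol_of <- rep.int(seq_len(nrow(pool)), lens)
  pep <- unlist(dig[idx], use.names = FALSE)
  out <- data.frame(sequence = pep,
                    score = NA_real_,
                    sample = "synthetic",
                    molecule = pool$molecule[mol_of],
                    is_cterm = grepl(anchor, pep, fixed = TRUE),
                    true_outcome = pool$outcome[mol_of],
                    true_n_junctions = pool$n_junctions[mol_of],
                    stringsAsFactors = FALSE)
  out <- out[stats::runif(nrow(out)) <= detect_prob, , drop = FALSE]
  if (nrow(out)) {
    noise <- stats::runif(nrow(out)) < score_model$p_noise
    score <- ifelse(noise,
                    stats::rnorm(nrow(out), score_model$noise[["mean"]],
                                 score_model$noise[["sd"]]),
                    stats::rnorm(nrow(out), score_model$correct[["mean"]],
                                 score_model$correct[["sd"]]))
    out$score <- round(score, 2L)
  }
  rownames(out) <- NULL
  out
}

#' Generate a noisy logistic growth curve
#'
#' OD600(t) follows logistic growth from `od0` toward `capacity` at the
#' exponential rate implied by `doubling_time`, delayed by `lag`, with
#' additive Gaussian measurement noise.
#'
#' @param doubling_time minutes per doubling during exponential phase.
#' @param lag lag phase in minutes.
#' @param capacity carrying capacity (maximum OD600).
#' @param noise_sd standard deviation of additive OD noise.
#' @param od0 inoculum OD600.
#' @param timestep sampling interval, minutes.
#' @param horizon total duration, minutes.
#' @param seed integer seed.
#' @return data.frame of class `growth_curve` with `time` (min) and `od600`.
#' @export
growth_curve_generator <- function(doubling_time = 40, lag = 0,
                                   capacity = 2.5, noise_sd = 0.02,
                                   od0 = 0.05, timestep = 10,
                                   horizon = 960, seed = 1L) {
  if (doubling_time <= 0 || capacity <= 0 || od0 <= 0 || timestep <= 0 ||
      horizon <= 0 || noise_sd < 0)
    stop("growth parameters must be positive (noise_sd nonnegative)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 2L)
  times <- seq(0, horizon, by = timestep)
  r <- log(2) / doubling_time
  te <- pmax(times - lag, 0)
  od <- capacity / (1 + ((capacity - od0) / od0) * exp(-r * te))
  od <- od + stats::rnorm(length(od), 0, noise_sd)
  structure(data.frame(time = times, od600 = od), class = c("growth_curve",
                                                            "data.frame"))
}
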