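## Standard monoisotopic residue masses (Da) and physical constants,
## cross-checked against canonical tables before freezing.
RESIDUE_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)

## Average masses for the optional average-mass mode.
RESIDUE_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MONO <- 18.0105647
PROTON_MASS <- 1.0072765
CARBAMIDOMETHYL <- 57.02146

#' Mass-calculation configuration
#'
#' @param mass_scale "monoisotopic" (default) or "average".
#' @param fixed_mods named numeric vector of per-residue fixed modification
#'   masses; default carbamidomethylation of cysteine (+57.02146 Da), the
#'   fixed modification used in the proteomic search.
#' @param variable_mods optional named numeric vector applied to every
#'   matching residue when requested per call (e.g. oxidation `M` +15.99491).
#' @return list of class `mass_config`.
#' @export
mass_config <- function(mass_scale = c("monoisotopic", "average"),
                        fixed_mods = c(C = CARBAMIDOMETHYL),
                        variable_mods = NULL) {
  mass_scale <- match.arg(mass_scale)
  structure(list(mass_scale = mass_scale, fixed_mods = fixed_mods,
                 variable_mods = variable_mods),
            class = "mass_config")
}

residue_masses <- function(peptide, cfg) {
  res <- strsplit(peptide, "")[[1L]]
  if (length(res) == 0L) stop("empty peptide")
  tbl <- if (cfg$mass_scale == "monoisotopic") RESIDUE_MONO else RESIDUE_AVG
  unknown <- setdiff(res, names(tbl))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ","))
  m <- tbl[res]
  for (tgt in names(cfg$fixed_mods))
    m[res == tgt] <- m[res == tgt] + cfg$fixed_mods[[tgt]]
  unname(m)
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water, with fixed modifications applied.
#'
#' @param peptide residue string.
#' @param cfg a `mass_config`.
#' @return mass in Da.
#' @export
mono_mass <- function(peptide, cfg = mass_config()) {
  sum(residue_masses(peptide, cfg)) + WATER_MONO
}

#' Signed mass difference between two peptides
#'
#' @param p1,p2 residue strings.
#' @param cfg a `mass_config`.
#' @return `mono_mass(p1) - mono_mass(p2)` in Da.
#' @export
mass_diff <- function(p1, p2, cfg = mass_config()) {
  mono_mass(p1, cfg) - mono_mass(p2, cfg)
}

#' Singly-charged b/y fragment-ion series
#'
#' For manual spectrum validation: `b_i` is the first `i` residues plus a
#' proton; `y_i` is the last `i` residues plus water and a proton, so
#' `b_i + y_(n-i) = M + 2 * proton`.
#'
#' @param peptide residue string of length >= 2.
#' @param series "b" or "y".
#' @param cfg a `mass_config`.
#' @return numeric vector of the n-1 singly-charged m/z values.
#' @export
fragment_ions <- function(peptide, series = c("b", "y"),
                          cfg = mass_config()) {
  series <- match.arg(series)
  m <- residue_masses(peptide, cfg)
  n <- length(m)
  if (n < 2L) stop("fragment ions need a peptide of length >= 2")
  if (series == "b") cumsum(m[-n]) + PROTON_MASS
  else cumsum(rev(m)[-n]) + WATER_MONO + PROTON_MASS
}

#' Fragment-ion table for a peptide
#'
#' @param peptide residue string.
#' @param cfg a `mass_config`.
#' @return data.frame with ion label, series, index and m/z.
#' @export
ion_table <- function(peptide, cfg = mass_config()) {
  n <- nchar(peptide) - 1L
  data.frame(
    ion = c(paste0("b", seq_len(n)), paste0("y", seq_len(n))),
    series = rep(c("b", "y"), each = n),
    index = rep(seq_len(n), 2L),
    mz = c(fragment_ions(peptide, "b", cfg),
           fragment_ions(peptide, "y", cfg)))
}
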