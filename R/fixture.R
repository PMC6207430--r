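## Synthetic UAG reporter fixture.
##
## The study construct is an eGFP gene ending in a 6xHis tag immediately
## upstream of an unassigned UAG codon, followed by a 102-nt untranslated-in-
## frame-0 tail. The exact published tail sequence is shown only graphically,
## so the packaged fixture is a fully synthetic construct engineered to
## satisfy every textually stated property of the real one:
##
##   * frame-0 product ends K.LEHHHHHH (tryptic site before the anchor);
##   * frame-0 readthrough after the UAG decodes GAR then stops, so a
##     suppressed residue X yields tryptic peptide LEHHHHHH-X-GAR;
##   * the +1-shifted frame decodes A,L,G,D,P,M,V,R at offsets +4..+25,
##     giving the diagnostic peptides ALGDPMVR (s=+4), GDPMVR (s=+10) and
##     MVR (s=+19), and continues to a stop whose last decoded base lies
##     +82 nt past the UAG codon;
##   * backward slips re-reading the His codons give LEHHHHHHH (s=-3) and
##     LEHHHHHHHH (s=-6 or twice s=-3);
##   * the five loss-of-fidelity tripeptide extensions (EKP, QLD, QQR, SLK,
##     YQR after LEHHHHHH) are not decodable with a single junction anywhere
##     in the default +/- resume window, but are decodable with two.
##
## The upstream region is a shortened GFP-like C-terminus; only its tryptic
## anchor context matters for the analyses here.

FIXTURE_UPSTREAM_PROTEIN <- "MSKDPNEKRDHMVLLEFVTAAGITLGMDELYK"
FIXTURE_ANCHOR <- "LEHHHHHH"

FIXTURE_TAIL_NT <- paste0(
  "GGCGCTCGGTGATCCCATGGTTCGT",    # +3 GAR|TGA (frame 0); +4 ALGDPMVR (+1 frame)
  "CAAAAAAGCGCCCTGAGA",           # +28 QKSA... (+1); P at +38 before TGA at +41
  "TTAACCAAGATT",                 # D at +44 before TAA at +47; +52 K
  "AACGGTATCAACTCCACCGGCCGTTAA",  # +55 INGINSTGR, last base +82, then stop
  "ATGATAAACCGGGTTTACCA"          # inert remainder with frame-2 stops
)

## one fixed codon per residue keeps the fixture deterministic
FIXTURE_CODONS <- c(M = "ATG", S = "AGC", K = "AAA", D = "GAT", P = "CCG",
                    N = "AAC", E = "GAA", R = "CGT", H = "CAC", V = "GTT",
                    L = "CTG", F = "TTC", T = "ACC", A = "GCT", G = "GGT",
                    I = "ATT", Y = "TAC", Q = "CAA", W = "TGG", C = "TGC")

reverse_translate <- function(protein) {
  paste(FIXTURE_CODONS[strsplit(protein, "")[[1L]]], collapse = "")
}

#' Synthetic UAG reporter construct
#'
#' Builds the packaged synthetic reporter: a GFP-like upstream region ending
#' in the tryptic anchor K.LEHHHHHH, the unassigned UAG codon, and a 102-nt
#' downstream tail engineered to reproduce every textually documented
#' property of the study construct (see the package vignette). The same
#' construct ships as `inst/extdata/uag_reporter_synthetic.fasta`.
#'
#' @param tag_variant ssrA tag variant ("DD" default, as in the mass-spec
#'   strains; "AA" is wild type).
#' @return a `reporter_construct`.
#' @export
uag_reporter <- function(tag_variant = "DD") {
  up <- reverse_translate(paste0(FIXTURE_UPSTREAM_PROTEIN, FIXTURE_ANCHOR))
  reporter_construct(
    coding_sequence = paste0(up, "TAG", FIXTURE_TAIL_NT),
    stall_offset = nchar(up),
    name = "uag_reporter_synthetic",
    orphan_codon = "TAG",
    tag_variant = tag_variant,
    anchor_peptide = FIXTURE_ANCHOR
  )
}

#' Identified C-terminal peptides of the UAG reporter (synthetic transcription)
#'
#' A search-engine-style identification table for the peptides the study
#' reports from the C-terminus of the UAG-ending reporter: the unmodified
#' anchor, the four near-cognate suppression products (Q/Y/D/V), backward
#' (-3/-6) and forward (+10/+19) frameshift products, free tail fragments
#' from all three shifted frame classes (the deepest ending +82 nt past the
#' UAG codon), and ssrA DD-tagged peptides at and downstream of the stall.
#' Sequences outside the anchor region are synthetic: they follow the
#' packaged synthetic tail, not the unpublished figure sequence. Scores are
#' plausible Andromeda-like values on the study's 0-100ish scale.
#'
#' @return data.frame with columns `sequence`, `score`, `sample`.
#' @export
reporter_identifications <- function() {
  path <- system.file("extdata", "reporter_identifications_synthetic.csv",
                      package = "stallscope", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Validated anchor+XXX tripeptide extensions (synthetic transcription)
#'
#' The score-validated peptides of form LEHHHHHH-XXX searched with the
#' separate combinatorial library: the five extensions the study attributes
#' to loss of translational fidelity (EKP, QLD, QQR, SLK, YQR) plus the
#' frameshift-explainable MVR extension. The `trypsin_caveat` flag marks
#' peptides ending in K/R that may have been cleaved from longer products.
#'
#' @return data.frame with columns `sequence`, `score`, `sample`,
#'   `trypsin_caveat`.
#' @export
xxx_identifications <- function() {
  path <- system.file("extdata", "xxx_identifications_synthetic.csv",
                      package = "stallscope", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
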