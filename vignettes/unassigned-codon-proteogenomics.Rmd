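---
title: "Inferring translational outcomes at an unassigned stop codon"
author: "stallscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring translational outcomes at an unassigned stop codon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stallscope)
```

## The biological problem

In a genomically recoded *Escherichia coli* every UAG codon has been
rewritten to UAA and release factor 1 deleted, so UAG is decoded by neither
a tRNA nor a release factor: it is an *unassigned* (orphan) codon, and a
ribosome that reaches one stalls. A reporter — GFP carrying a C-terminal
6xHis tag immediately upstream of a UAG — turns the question "what happens
at the stall?" into a peptide-identification problem: whatever the ribosome
does next leaves a characteristic C-terminus that trypsin digestion and
tandem MS can read out. The candidate outcomes are

* **near-cognate suppression** — some tRNA decodes the UAG anyway,
  inserting one residue (Q, Y, D and V are observed) and translation
  continues in frame;
* **ribosomal frameshifting** — decoding resumes at an mRNA position offset
  by `s` nucleotides from the UAG ("bases skipped", negative = backward);
* **ribosomal rescue** — tmRNA-SmpB appends the ssrA degradation tag
  (AANDENYALAA, or the degradation-resistant AANDENYALDD mutant used for
  detection), while ArfA/ArfB release the peptide unmodified;
* **loss of translational fidelity** — untemplated residues are appended
  after the stall and translation terminates spontaneously.

This package implements the computational side of that experiment: the
theoretical search libraries, the mapping of observed peptides back to
mRNA events, supporting mass calculations, a stochastic generator of
outcome pools for validation, and the growth/blot/conjugation/titer
statistics used in the accompanying phenotypic assays.

## Coordinates and the reporter model

All positions are 0-based nucleotide offsets into the coding sequence;
frame 0 starts at index 0 and the orphan codon occupies
`[stall_offset, stall_offset + 3)`. A decoding resume at offset `r` is
reported as `s = r - stall_offset`: suppression is `s = 0`, in-frame
readthrough past the stall is `s = +3`, re-reading the last His codon is
`s = -3`. Translation uses the standard code on the DNA alphabet;
ambiguity codes are rejected. UAA/UGA always terminate; UAG never decodes —
depending on context it is either recorded as an ordinary stop
(`orphan_is_stop = TRUE`) or as a renewed stall.

### The packaged synthetic construct

The published reporter's 102-nt downstream tail is shown only graphically
in the original figures, so the packaged fixture (`uag_reporter()`,
mirrored in `inst/extdata/uag_reporter_synthetic.fasta`) is a **synthetic**
construct engineered to satisfy every property the text and tables state:

* the frame-0 product ends `...K.LEHHHHHH` (tryptic site before the
  anchor) and decodes `GAR` then a stop after the UAG, so suppression of
  residue X yields the tryptic peptide `LEHHHHHH-X-GAR`;
* the +1-shifted frame encodes A,L,G,D,P,M,V,R at offsets +4..+25, giving
  `ALGDPMVR` (s = +4), `GDPMVR` (s = +10) and `MVR` (s = +19), and runs on
  to a stop whose last decoded base is +82 nt past the UAG;
* backward slips re-reading His codons give `LEHHHHHHH` (s = -3) and
  `LEHHHHHHHH` (s = -6, or two -3 slips);
* the five anchor+XXX extensions attributed to fidelity loss (EKP, QLD,
  QQR, SLK, YQR) are **not** decodable with a single junction anywhere in
  the default resume window — the window contains no codon pair reading
  Q·R, L·K, K·P or L·D — but each has a two-junction reading (the window
  provides the needed single codons, including a proline and an aspartate
  each followed immediately by a stop so those readings can terminate).

The upstream region is a shortened GFP-like C-terminus; only its tryptic
context matters. Because the tail is synthetic, sequence-level identity
with the published tail is neither expected nor required — every analysis
here depends only on the constraints above, which are printed facts.
The bundled identification tables
(`reporter_identifications()`, `xxx_identifications()`) are likewise
synthetic transcriptions: the anchor-region peptides and the five fidelity
candidates are exactly the published ones; free tail fragments follow the
synthetic tail and carry plausible scores on the search engine's scale.

## Search libraries

`build_search_libraries()` produces the two libraries used to search the
MS data:

* **release** — the unmodified pre-stall product (ArfA/ArfB rescue or
  termination), so the bare anchor C-terminus is searchable;
* **suppression** — twenty full-length products, one canonical residue
  decoded at the UAG, continuing to the next stop or the 38-residue cap;
* **tail** — for every resume offset `s` in a window (default -9..+45 nt),
  the C-tail decoded from `stall + s` to the next non-orphan stop (an
  in-tail UAG stalls again and also ends the entry) or to 38 residues.
  The published library was organised by reading frame; generalising to
  every nucleotide offset makes single-junction explanations at the
  observed -6, -3, +10 and +19 representable, and the per-offset "bases
  skipped" bookkeeping mirrors how the peptides are reported. Each entry
  records both the free tail fragment (as the library lists it) and the
  anchored product context (upstream protein + anchor + tail), and
  digestion uses both, since observed peptides come in both forms
  (`ALGDPMVR` free, `LEHHHHHHMVR` anchored);
* **tagged** — anchor + `t` decoded tail residues + the full ssrA tag, for
  `t = 0..12` across the resume window (`t = 0` collapses to a single
  "tag at the stall" entry). The truncation bound keeps the library finite;
  observed tagged peptides carry at most a few decoded residues;
* **combinatorial** — the separate anchor+X^k library (default k = 3,
  20^3 = 8000 entries) used to find peptides no single reading of the
  transcript can produce.

The 38-residue cap is counted from the resume point (the alternative —
from the UAG — is not monotone in `s`; this choice is simpler and
configurable). Trypsin digestion cleaves after K/R except before P, emits
peptides spanning at most 3 missed cleavages with at least 5 residues
(both configurable), and is verified against a brute-force substring
enumeration in the test suite. FASTA export is deterministically ordered
so identical inputs are byte-identical.

## Event inference

`explain()` is the core algorithm. An observed peptide is decomposed into:

1. an **anchor** — the longest suffix of the frame-0 pre-stall product
   that prefixes the peptide (peptides with no anchor are mapped as free
   tail fragments, required to start at or after `stall - 9` so arbitrary
   GFP-internal peptides are not trivially "explained");
2. at most one **suppressed residue**, exactly at the orphan codon;
3. mRNA **segments** decoded with the standard code, separated by
   frameshift **junctions**; a junction may occur at any decoded-codon
   boundary (the fidelity-loss argument requires counting hypothetical
   post-resolution frameshifts) and resumes anywhere in the window;
4. an optional C-terminal **ssrA-tag suffix** (>= 3 tag residues, to avoid
   spurious tag calls on short suffixes).

A tag-free reading must also *terminate plausibly*: at a stop codon, at
the orphan (stall, then rescue or release), at the sequence end, or at a
tryptic K/R boundary not followed by proline (an internal peptide of a
longer product). This rule is load-bearing: without it, `LEHHHHHHH` would
be "explained" as His-suppression even though suppression implies
continued in-frame translation that would have appended `GAR` before the
next tryptic cut.

The search is exhaustive over junction counts up to a budget. By default
every explanation with at most **minimal + 1** junctions is returned, so
near-minimal ambiguity is surfaced rather than silently resolved — the
canonical case being `LEHHHHHHHH`, reported as a single -6 slip *and* as
two -3 slips. Results are ordered by (junction count, number of
suppression events, |net shift|, a deterministic key): ranking
suppression-bearing ties after pure-junction readings is a parsimony
choice — a single slip is a more economical reading than a suppression
plus a slip — and matches how every published example is interpreted.
`n_events` counts junctions only; suppression and tagging are outcome
categories, not frameshift events (the printed examples are consistent
with this reading).

`classify()` maps the explanation set to the outcome taxonomy, in order:
unmodified anchor product → `termination_or_release`; a junction-free,
tag-free reading with a suppressed residue → `suppression`; any tag match
→ `tagged`; minimal one junction → `frameshift`; otherwise
`fidelity_loss_candidate` (or `unexplained` when nothing fits the budget).
Junction-free *unanchored* tail fragments also classify as `frameshift`:
their tryptic boundary hides the upstream junction that put the ribosome
into that frame. Requiring the suppression reading to be tag-free prevents
a partial tag suffix plus a spurious suppressed residue from outranking a
full tag-at-the-stall reading.

`summarize_identifications()` applies the score threshold (default 15, the
study's manual-validation cut), explains and classifies each unique
peptide, and reports per-category counts, per-offset frameshift counts,
and the maximum downstream decoded extent — the 3'-most decoded nucleotide
past the stall over all returned explanations (+82 nt on the packaged
fixture and peptide set).

`explain()` is verified in two independent ways: every returned
explanation re-synthesises its peptide exactly from the construct
(soundness), and on a 39-nt toy construct the full explanation *set*
equals a forward generate-and-test enumeration over (tag suffix × anchor ×
junction boundary set × resume offsets × suppression position).

## Peptide masses

Monoisotopic residue masses and the water/proton constants are hard-coded
from canonical tables (cross-checked against an independent reference
implementation before freezing); carbamidomethyl-Cys (+57.02146 Da) is the
default fixed modification, matching the search settings. `mass_diff()`
reproduces the 35 Da (35.0048) Q→Y shift used to validate the
`LEHHHHHHQQR` / `LEHHHHHHYQR` pair, and `fragment_ions()` produces the
singly-charged b/y series (b_i + y_(n-i) = M + 2·proton) for manual
spectrum checks. Average-mass mode and variable modifications are
available but play no role in the analyses.

## Synthetic outcome pools

`sample_outcomes()` draws molecules from an `outcome_model()`: class
probabilities for release / suppression / frameshift / tagging / fidelity
loss, uniform within-class defaults (suppressors Q/Y/D/V; resume offsets
-6, -3, +10, +19; tag truncations 0–2), and a geometric (min 2) length for
untemplated fidelity tails. The study's spectral counting is not
quantitative, so the across-class defaults are conventional placeholders,
not biological estimates — they exist to give the inference something
truthful to recover. `to_identifications()` digests the pool, applies
Bernoulli detection and a two-component Gaussian score model (correct
versus noise, separated by the 15-point threshold), and keeps each
molecule's true provenance for recovery tests.

Two deliberate limitations: fidelity-loss products are untemplated, so
they carry no true junction count (`n_junctions = NA`) and are excluded
from the label-conservation property; and because a short random tail can
coincide with a legitimate one-junction reading (e.g. an untemplated
`HH` is indistinguishable from a -6 slip), classification of fidelity
products is intrinsically ambiguous — the published analysis faced the
same ambiguity, which is why its fidelity argument rests on peptides with
*no* one-junction reading. The frequency-recovery experiment therefore
runs at a four-class model (fidelity mass set to zero), where every
C-terminal signature is unambiguous; at n = 10,000 molecules all four
class frequencies are recovered within three binomial standard errors.
What passing these tests shows is that the pipeline's bookkeeping is
consistent end-to-end; it does not show anything about real MS data, which
add misidentification, intensity effects and co-eluting species that the
generator deliberately does not model.

## Assay statistics

`doubling_time()` estimates exponential-phase doubling time. Exactly
exponential data return the global log2-linear slope's reciprocal (exact
to machine precision). Noisy curves are fitted with a self-starting
logistic model (`SSlogis`) and the doubling time is `ln(2)·scal`; the fit
averages over the whole sigmoid, so additive plate-reader noise on low-OD
readings does not inflate the estimate. A sliding-window maximum-slope fit
(5 points above an OD floor of 0.02, both configurable) is retained as the
fallback when the logistic fit does not converge; used alone it is too
variance-prone at realistic noise (selecting the maximum over ~90 noisy
window slopes biases the rate upward by tens of percent at a doubling time
of 60 min with 0.02 OD noise), which is why the model fit is primary.
Curves showing less than one doubling above the floor are rejected rather
than extrapolated. The estimator is invariant to rescaling the OD readings.
The original growth-analysis code is unpublished MATLAB, so numerical
agreement with the published doubling times is not claimed — only the
defined computation, recovered within 5% across doubling times of 20/40/60
min on seeded noisy logistic curves.

Western-blot quantification follows the segmented calibration exactly as
described: separate linear fits over the 1–10 ng and 10–100 ng standards,
segment selected by the observed *intensity* (intensity is the
observable), extrapolation above the top standard (the brightest published
sample quantified as 136 ng), and below the 1 ng standard a line through
the 1 ng point and a zero-intensity blank. `conjugation_pct()` (86 picked
colonies by default), `pfu_per_ml()` and `relative_titer()` are the plain
plate-count computations; the published percentages and titers themselves
are wet-lab measurements and are not desk-reproducible.

## Problem sizes and numerical choices

The test suite and the analysis scripts use: the 225-nt packaged
construct; a 39-nt toy construct for oracle equivalence (junction budget 2
anchored, 1 unanchored — the enumeration spaces are exact there); 1000
random peptides for the mass identities; 10,000 molecules for frequency
recovery; and 30 seeded growth curves (3 doubling times × 10 seeds) for
doubling-time recovery. Ties in explanation ordering are broken by a
deterministic string key; all simulations take explicit integer seeds and
restore the caller's RNG state.

## Known limitations

* The packaged tail is constraint-faithful, not sequence-identical to the
  unpublished figure sequence; analyses that depend on the exact published
  tail (e.g. byte-level comparison with the deposited libraries) are out
  of scope.
* Suppression is modelled only at the orphan codon; misincorporation
  elsewhere is represented as junctions, not substitutions.
* One charge state, no isotope envelopes, no spectrum-level scoring; the
  package explains peptide *sequences*, not spectra.
* mRNA secondary structure and Shine–Dalgarno-like frameshift elements are
  not modelled; the frameshift inference is purely combinatorial.
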