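#!/usr/bin/env Rscript

# Map the identified C-terminal peptides back onto the reporter transcript
# and classify the translational event behind each: termination/release,
# near-cognate suppression, frameshifting (with net bases skipped), tmRNA
# tagging, or candidate loss of translational fidelity.

suppressPackageStartupMessages(library(stallscope))

dir.create("results", showWarnings = FALSE)
construct <- uag_reporter()

ids <- reporter_identifications()
s <- summarize_identifications(ids, construct, score_threshold = 15)
print(s)
cat("\nPer-peptide calls:\n")
print(s$peptides[, c("peptide", "category", "n_events", "net_shift",
                     "tagged", "extent")], row.names = FALSE)
utils::write.table(s$peptides, file.path("results", "peptide_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("\nnet frameshift offsets observed: %s nt\n",
            paste(names(s$by_offset), collapse = ", ")))
cat(sprintf("deepest decoded position: +%g nt past the UAG codon\n",
            s$max_downstream_extent))

## the separate anchor+XXX search: peptides that no single reading of the
## transcript (one junction at most) can explain
xxx <- xxx_identifications()
sx <- summarize_identifications(xxx, construct, score_threshold = 15)
hard <- sx$peptides[sx$peptides$category %in%
                      c("fidelity_loss_candidate", "unexplained"), ]
cat(sprintf("\nanchor+XXX peptides needing >=2 frameshift events: %d (%s)\n",
            nrow(hard), paste(hard$peptide, collapse = ", ")))
utils::write.table(sx$peptides, file.path("results", "xxx_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## manual-validation support: the Q/Y pair differs by a 35 Da shift
d <- mass_diff("LEHHHHHHYQR", "LEHHHHHHQQR")
cat(sprintf("mass shift LEHHHHHHYQR vs LEHHHHHHQQR: %.4f Da (rounds to %d)\n",
            d, round(d)))
explanations_to_json(s$peptides$peptide, construct,
                     file.path("results", "peptide_explanations.json"))
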