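#!/usr/bin/env Rscript

# Build the theoretical search libraries for the UAG reporter.
#
# The reporter stalls ribosomes at an unassigned UAG codon; the libraries
# enumerate every translational outcome whose product a tryptic digest
# could reveal: unmodified release, near-cognate suppression (20 residues),
# C-tails from every resume offset in -9..+45 nt, ssrA-tagged products,
# and the separate combinatorial anchor+XXX library used to detect loss of
# translational fidelity.

suppressPackageStartupMessages(library(stallscope))

dir.create("results", showWarnings = FALSE)
construct <- uag_reporter()
print(construct)

libs <- build_search_libraries(construct)
cat(sprintf("main library: %d entries (%s)\n", nrow(libs$main),
            paste(names(table(libs$main$category)),
                  table(libs$main$category), sep = "=", collapse = ", ")))
cat(sprintf("combinatorial library: %d entries\n", nrow(libs$combinatorial)))

write_library(libs$main, file.path("results", "main_library.fasta"))
write_library(libs$combinatorial,
              file.path("results", "combinatorial_library.fasta"))

peps <- digest(libs$main)
utils::write.table(peps, file.path("results", "main_library_peptides.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("tryptic peptide set: %d unique peptides (>=5 aa, <=3 miscleavages)\n",
            nrow(peps)))
for (p in c("LEHHHHHHQGAR", "ALGDPMVR", "LEHHHHHHGDAANDENYALDD"))
  cat(sprintf("  contains %-24s %s\n", p, p %in% peps$peptide))
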