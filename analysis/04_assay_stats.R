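#!/usr/bin/env Rscript

# Assay-statistics reproductions on synthetic inputs: growth-curve doubling
# time and maximum OD600, segmented western-blot calibration, conjugation
# percent transfer and relative phage titer.

suppressPackageStartupMessages(library(stallscope))

dir.create("results", showWarnings = FALSE)

## doubling-time recovery across conditions
rows <- list()
for (dt in c(20, 40, 60)) for (seed in 1:10) {
  g <- growth_curve_generator(doubling_time = dt, capacity = 2.5,
                              noise_sd = 0.02, seed = seed)
  est <- doubling_time(g)
  rows[[length(rows) + 1L]] <- data.frame(
    true_dt = dt, seed = seed, est_dt = round(est, 2),
    rel_err = round(abs(est - dt) / dt, 4),
    max_od = round(max_od(g, smooth = 5L), 3))
}
tab <- do.call(rbind, rows)
utils::write.table(tab, file.path("results", "growth_recovery.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("doubling-time recovery: max relative error %.3f over %d curves\n",
            max(tab$rel_err), nrow(tab)))

## growth impairment expressed as percent change, as reported for the assay
ref <- doubling_time(growth_curve_generator(doubling_time = 40, seed = 99L))
ind <- doubling_time(growth_curve_generator(doubling_time = 61, seed = 99L))
cat(sprintf("example percent increase in doubling time: %.1f%%\n",
            pct_change(ref, ind)))

## segmented blot calibration on a linear synthetic standard series
std <- data.frame(amount = c(1, 10, 50, 100),
                  intensity = 3 * c(1, 10, 50, 100))
cal <- calibration_curve(std)
for (i in c(1.5, 30, 225, 408))
  cat(sprintf("blot intensity %6.1f -> %6.2f ng\n", i, quantify_blot(cal, i)))

## conjugation and titer arithmetic
cat(sprintf("conjugation: 43/86 patched colonies -> %.0f%% transfer\n",
            conjugation_pct(43)))
cat(sprintf("relative titer: %.2e / %.2e = %.3f\n",
            pfu_per_ml(35, 1e6), pfu_per_ml(40, 1e6),
            relative_titer(pfu_per_ml(35, 1e6), pfu_per_ml(40, 1e6))))
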