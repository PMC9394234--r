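#!/usr/bin/env Rscript
# Clonality statistics on a synthetic diagnostic cohort.
#
# Generates the default validation-sized cohort (33 favorable / 17
# unfavorable patients, 500 nuclei each), runs the per-sample pipeline
# (encode -> filter -> tabulate), and compares clonal heterogeneity and
# specific gain rates between outcome arms: higher entropy (lower PMC) and
# higher trisomy-18/-10 rates are expected in the favorable arm.

library(clonefish)
dir.create("results", showWarnings = FALSE)

coh <- generate_cohort(cohort_spec(), seed = 7)
n <- nrow(coh$clinical)

stats <- do.call(rbind, lapply(seq_len(n), function(i) {
  fl <- filter_cells(coh$cells[[i]], sex = coh$clinical$sex[i])
  d <- tabulate_clones(fl$blasts)
  g <- gain_rates(fl$blasts)
  r <- setNames(g$rates$gain_pct, paste0("gain", g$rates$chromosome))
  data.frame(patient_id = coh$clinical$patient_id[i],
             arm = coh$clinical$arm[i],
             n_blasts = nrow(fl$blasts), n_clones = length(d$counts),
             pmc = d$pmc, entropy_bits = d$entropy, t(r),
             tt_4_10_17 = combined_trisomy_fraction(fl$blasts,
                                                    c("4", "10", "17")),
             qc_pass = qc_sample(fl$blasts)$pass,
             check.names = FALSE)
}))
utils::write.table(stats, "results/clonality_stats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("QC: %d/%d samples reach 200 informative hyperdiploid blasts\n",
            sum(stats$qc_pass), n))
for (v in c("entropy_bits", "pmc", "gain18", "gain10", "tt_4_10_17")) {
  cmp <- compare_groups(stats[[v]], stats$arm)
  cat(sprintf("%-12s favorable %6.2f vs unfavorable %6.2f  (t = %5.2f, p = %.3g)\n",
              v, cmp$means[["favorable"]], cmp$means[["unfavorable"]],
              cmp$statistic, cmp$p_value))
}
cat("Higher clonal heterogeneity and higher +18/+10 rates track the favorable arm.\n")
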