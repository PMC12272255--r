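#!/usr/bin/env Rscript
# Stage 4 — inter-network coupling.
#
# For each unordered pair of clustered networks: the mean cross-network
# correlation per participant, its group mean, and an exact binomial sign
# test, Bonferroni-corrected over the C(5,2) = 10 network pairs (adjusted
# level 0.005).

library(alans)

out <- "results"
cohort <- demo_cohort_config(rng_seed = 1L)

labels_df <- utils::read.delim(file.path(out, "cluster_labels.tsv"))
labels <- stats::setNames(paste0("C", labels_df$cluster), labels_df$region)

panel <- simulate_rest_timeseries(cohort)
stack <- panel_connectivity(panel, names(labels))

nets <- internetwork_tests(stack, labels, alpha_family = 0.05)
utils::write.table(nets, file.path(out, "internetwork.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("adjusted significance level: %.4g\n",
            attr(nets, "adjusted_alpha")))
for (i in seq_len(nrow(nets))) {
  cat(sprintf("  %s - %s: group r = %+.3f (%d+/%d-), p = %.3g%s\n",
              nets$network_a[i], nets$network_b[i], nets$group_r[i],
              nets$n_pos[i], nets$n_neg[i], nets$p[i],
              ifelse(nets$significant[i], " *", "")))
}
cat("wrote", file.path(out, "internetwork.tsv"), "\n")
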