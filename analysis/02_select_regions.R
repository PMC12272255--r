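#!/usr/bin/env Rscript
# Stage 2 — conjunction selection of lateralized regions.
#
# A pair contributes one region when the hemisphere favored by a significant
# left-right asymmetry is itself significantly activated (t > 0), both tests
# Bonferroni-corrected across the 185 pairs (per-test level 0.05/185
# ~ 2.7e-4; nominal conjunction level its square, ~ 7.3e-8).

library(alans)

out <- "results"
ct <- read_contrast_table(file.path(out, "contrasts.tsv"))
cfg <- pipeline_config(alpha_family = 0.05, n_pairs = 185)

sel <- select_regions(ct, cfg)
utils::write.table(sel, file.path(out, "selection.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth <- planted_truth(demo_cohort_config(1L))
hit <- setequal(sel$pair_id[sel$selected], truth$selected_regions$pair_id)
cat(sprintf("per-test alpha %.4g, conjunction alpha %.4g\n",
            attr(sel, "per_test_alpha"), attr(sel, "conjunction_alpha")))
cat(sprintf("selected %d regions (%d Right, %d Left); planted set recovered: %s\n",
            sum(sel$selected),
            sum(sel$hemisphere == "Right", na.rm = TRUE),
            sum(sel$hemisphere == "Left", na.rm = TRUE), hit))
cat("wrote", file.path(out, "selection.tsv"), "\n")
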