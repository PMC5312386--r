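#!/usr/bin/env Rscript
# Stage 2: normalize the screen plates and call proliferation hits.
#
# Loess surfaces (span 0.7, degree 1, robust family) are fitted per plate
# and condition on sample wells only, omitting control columns 1, 2, 23,
# 24. Hits are wells at least 3 Huber Proposal 2 SDs (winsorized at 1.5
# SD) from the library median of their condition; genes whose robust
# z-score moves by >= 2 between conditions are flagged as
# MYCN-dependent responses.

suppressPackageStartupMessages(library(wntitr))
dir.create("results/screen", showWarnings = FALSE, recursive = TRUE)

plates <- read_screen_csv("results/data/screen_plates.csv")
nm <- loess_normalize(plates, span = 0.7, excluded_cols = c(1, 2, 23, 24))
write.table(attr(nm, "fit_surface"), "results/screen/fitted_surfaces.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

hits <- call_hits(nm, threshold_sd = 3)
write_hit_table(hits, "results/screen/hit_table.tsv")

hi <- hits[hits$condition == "induced", ]
hu <- hits[hits$condition == "uninduced", ]
dr <- differential_response(hi, hu, delta_threshold = 2)
write.table(dr, "results/screen/differential_response.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim("results/data/screen_truth_spikes.tsv")
recall <- mean(hi$hit[hi$gene %in% truth$gene])
s <- nm[nm$well_type == "sample" & nm$condition == "induced", ]
cat(sprintf("spatial flatness after normalization: |cor(value, row)| = %.4f\n",
            abs(cor(s$normalized, s$row))))
cat(sprintf("hits: %d induced / %d un-induced (of %d genes)\n",
            sum(hi$hit), sum(hu$hit), nrow(hi)))
cat(sprintf("planted -6 sigma spikes recalled: %.0f%%\n", 100 * recall))
cat(sprintf("condition-dependent responses flagged: %d (all %d spikes among them: %s)\n",
            sum(dr$condition_dependent),
            nrow(truth),
            all(truth$gene %in% dr$gene[dr$condition_dependent])))
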