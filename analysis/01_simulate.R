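#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with planted ground truth.
#
# Emulated inputs: a 384-well RNAi viability screen read in un-induced and
# MYCN-induced conditions (960 genes, smooth spatial artifact of 1 log2
# unit peak-to-peak, noise SD 0.3 log2, 20 genes spiked at -6 sigma in the
# induced condition only); a signed regulator-target prior (10 regulators
# x 20 targets); and five DE contrasts in which one regulator (REG01) is
# planted as inhibited, mimicking beta-catenin repression under sustained
# MYCN overexpression.

suppressPackageStartupMessages(library(wntitr))
seed <- 1
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

spikes <- data.frame(gene = paste0("gene", 1:20), condition = "induced",
                     effect = -6)
scr <- simulate_screen(n_genes = 960, gradient_amplitude = 1, noise_sd = 0.3,
                       spikes = spikes, seed = seed)
write_screen_csv(scr$plates, "results/data/screen_plates.csv")
write.table(spikes, "results/data/screen_truth_spikes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

net <- simulate_network(n_regulators = 10, targets_per_regulator = 20,
                        seed = seed + 1)
write_network(net, "results/data/network.tsv")

activity <- expand.grid(regulator = unique(net$regulator),
                        contrast = paste0("contrast", 1:5),
                        stringsAsFactors = FALSE)
activity$state <- ifelse(activity$regulator == "REG01", -1L, 0L)
sim <- simulate_contrasts(net, activity, effect_mu = 2, noise_sd = 0.5,
                          seed = seed + 2)
write_de_table(sim$de, "results/data/de_tables.tsv")
write.table(activity, "results/data/contrast_truth_activity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("screen: %d wells over %d plates x 2 conditions (%d spiked genes)\n",
            nrow(scr$plates), length(unique(scr$plates$plate)), nrow(spikes)))
cat(sprintf("network: %d edges, %d regulators\n", nrow(net),
            length(unique(net$regulator))))
cat(sprintf("contrasts: %d tables, %d genes each; planted inhibited regulator REG01\n",
            length(unique(sim$de$contrast)), length(unique(sim$de$gene))))
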