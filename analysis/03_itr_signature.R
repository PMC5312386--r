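#!/usr/bin/env Rscript
# Stage 3: inferred-transcriptional-regulator scoring and signature
# construction.
#
# Every regulator is scored per contrast by the hypergeometric overlap of
# its targets with the DE set (padj <= 0.05) and by the activation
# z-score (|z| >= 2 calls activated/inhibited). The planted regulator's
# contributing genes seen in >= 2 contrasts become its gene signature,
# with majority-vote expected directions.

suppressPackageStartupMessages(library(wntitr))
dir.create("results/itr", showWarnings = FALSE, recursive = TRUE)

net <- read_network("results/data/network.tsv")
de <- read_de_table("results/data/de_tables.tsv")

itr <- infer_regulators(net, de, de_padj = 0.05, z_cutoff = 2)
write.table(as.data.frame(itr), "results/itr/itr_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

top <- itr[itr$rank == 1, c("contrast", "regulator", "overlap", "p", "z",
                            "state")]
cat("top-ranked regulator per contrast:\n")
print(top, row.names = FALSE, digits = 3)

sig <- build_signature(itr, "REG01", de, min_contrasts = 2)
write_signature(sig, "results/itr/signature.tsv")
write_signature_gmt(sig, "results/itr/signature.gmt")
cat(sprintf("\nsignature of REG01: %d genes (%d down, %d up, %d unknown direction)\n",
            nrow(sig), sum(sig$direction == -1), sum(sig$direction == 1),
            sum(sig$direction == 0)))

# direction-less ranking from a bound-gene list (ChIP-style input):
# the planted regulator's own targets as the query set
bound <- net$target[net$regulator == "REG01"][1:15]
bin <- rank_regulators_binary(net, bound, unique(de$gene))
write.table(bin, "results/itr/binary_overlap_ranking.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("binary overlap ranking: REG01 ranked %d of %d\n",
            bin$rank[bin$regulator == "REG01"], nrow(bin)))
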