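#!/usr/bin/env Rscript
# Preranked gene-set enrichment of the acquired-vs-naive and
# primary-vs-naive t-rankings over the planted module signatures plus
# random decoy sets.

library(icirwe)

sigs <- read_gmt("results/sim/signatures.gmt")

for (arm in c("acquired", "primary")) {
  de <- read.delim(sprintf("results/de_%s_vs_naive.tsv", arm))
  ranking <- setNames(de$t_stat, de$gene)
  gs <- preranked_enrichment(ranking, sigs, n_perm = 1000, seed = 7)
  out <- gs[order(gs$p_value), setdiff(names(gs), "leading_edge")]
  write.table(out, sprintf("results/gsea_%s_vs_naive.tsv", arm),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("%s vs naive, sets at q<0.05:\n", arm))
  hit <- out[out$q_value < 0.05, ]
  if (nrow(hit) == 0) cat("  (none)\n") else
    for (i in seq_len(nrow(hit)))
      cat(sprintf("  %-22s NES %+.2f  q %.3f\n", hit$set_name[i],
                  hit$nes[i], hit$q_value[i]))
}
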