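#!/usr/bin/env Rscript
# TMM/log-CPM normalization, immune signature scores with covariate-adjusted
# group means, and per-gene differential expression of acquired resistance
# vs treatment-naive.

library(icirwe)

tabs <- read_clinical_tables("results/sim")
counts <- read_count_matrix("results/sim/counts.tsv")
sigs <- read_gmt("results/sim/signatures.gmt")
lab <- read.csv("results/labels.csv", stringsAsFactors = FALSE)
pdl1 <- read.csv("results/pdl1_imputed.csv", stringsAsFactors = FALSE)

norm <- normalize_counts(counts)
grp <- lab$label[match(colnames(norm), lab$sample_id)]
grp <- ifelse(grp == "not_eot", "naive", grp)

sc <- signature_score(norm, sigs[c("ifng", "b_cell", "dc")])
covs <- data.frame(
  pdl1 = pdl1$pdl1_class[match(colnames(norm), pdl1$sample_id)],
  site = tabs$biopsies$tissue_site[match(colnames(norm),
                                         tabs$biopsies$sample_id)],
  stringsAsFactors = FALSE)
keep <- grp %in% c("naive", "primary", "acquired")
cat("covariate-adjusted signature means (naive / primary / acquired):\n")
rows <- list()
for (s in rownames(sc)) {
  adj <- adjusted_group_means(sc[s, keep], grp[keep],
                              covs[keep, , drop = FALSE])
  cat(sprintf("  %-7s %s\n", s,
              paste(sprintf("%s=%.2f", adj$means$group,
                            adj$means$adj_mean), collapse = "  ")))
  rows[[s]] <- cbind(signature = s, adj$means)
}
write.csv(do.call(rbind, rows), "results/signature_adjusted_means.csv",
          row.names = FALSE, quote = FALSE)

de_for <- function(arm) {
  k <- grp %in% c("naive", arm)
  fit_gene_linear_models(norm[, k],
                         factor(grp[k], levels = c("naive", arm)),
                         covariates = covs[k, , drop = FALSE])
}
for (arm in c("acquired", "primary")) {
  de <- de_for(arm)
  write.table(de, sprintf("results/de_%s_vs_naive.tsv", arm), sep = "\t",
              row.names = FALSE, quote = FALSE)
  top <- de[order(de$p_value)[1:5], ]
  cat(sprintf("\n%s vs naive: %d genes at q<0.05; top genes: %s\n", arm,
              sum(de$q_value < 0.05),
              paste(sprintf("%s (lfc %.2f)", top$gene, top$log2_fc),
                    collapse = ", ")))
}
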