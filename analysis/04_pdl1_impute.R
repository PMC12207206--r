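#!/usr/bin/env Rscript
# Impute missing PD-L1 IHC class from CD274 mRNA: fit the kappa-maximal
# thresholds for the >=1% and >=50% classes on biopsies with observed IHC,
# then classify the rest; observed IHC always wins.

library(icirwe)
library(jsonlite)

tabs <- read_clinical_tables("results/sim")
counts <- read_count_matrix("results/sim/counts.tsv")
norm <- normalize_counts(counts)
truth <- read_json("results/sim/truth.json", simplifyVector = TRUE)

cd274 <- norm["CD274", ]
obs <- setNames(tabs$biopsies$pdl1_ihc_class,
                tabs$biopsies$sample_id)[colnames(norm)]
imp <- impute_pdl1(cd274, obs)
write.csv(data.frame(sample_id = names(imp$classes),
                     pdl1_class = as.character(imp$classes),
                     imputed = attr(imp$classes, "imputed")),
          "results/pdl1_imputed.csv", row.names = FALSE, quote = FALSE)
write_json(list(
  ge1 = imp$model_ge1[c("threshold", "kappa", "accuracy", "sensitivity",
                        "specificity", "n_train")],
  ge50 = imp$model_ge50[c("threshold", "kappa", "accuracy", "sensitivity",
                          "specificity", "n_train")]),
  "results/pdl1_models.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("trained on %d observed biopsies; imputed %d\n",
            imp$n_train, imp$n_imputed))
cat(sprintf(">=1%%:  t = %.2f log2 CPM (generating boundary %.2f), kappa %.2f\n",
            imp$model_ge1$threshold, truth$cd274_thresholds[["ge1"]],
            imp$model_ge1$kappa))
cat(sprintf(">=50%%: t = %.2f log2 CPM (generating boundary %.2f), kappa %.2f\n",
            imp$model_ge50$threshold, truth$cd274_thresholds[["ge50"]],
            imp$model_ge50$kappa))
tc <- setNames(truth$patients$pdl1_class, truth$patients$sample_id)
cat(sprintf("3-class agreement with generating truth: %.1f%%\n",
            100 * mean(imp$classes == tc[names(imp$classes)])))
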