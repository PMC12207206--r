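# icirwe

Analysis machinery for characterizing **primary vs. acquired resistance to
immune checkpoint inhibitors (ICI)** in non-small cell lung cancer from
multimodal real-world data: clinical treatment timelines, bulk RNA-seq,
PD-L1 IHC, variant calls, and a single-cell reference.

Real-world cohorts record therapy lines and clinical-note progression
events rather than RECIST assessments, so the package derives everything
from timelines:

* **Resistance phenotyping.** A biopsy is an end-of-treatment (EOT) sample
  if collected within ±30 days of the ICI line's end (or ≥60 days after
  start when the end date is missing); it reflects resistance if the next
  line starts within 90 days of EOT or a progressive-disease event falls
  within 90 days of collection; resistant samples split into **primary**
  (ICI duration < 180 days) vs **acquired** (≥ 180 days).
* **Real-world endpoints.** OS from first-line start to death (censored at
  last follow-up); rwPFS counts progression/metastasis/death events in
  `[start + 14, end)`, censored at the treatment end or next-line start.
* **PD-L1 imputation.** Missing IHC class is imputed from CD274 mRNA by the
  threshold t maximizing Cohen's kappa, κ = (p_o − p_e)/(1 − p_e), scanned
  over all observed expression values, for the ≥1% and ≥50% classes.
* **Expression analytics.** TMM factors + log2 CPM, signature scores (mean
  log-scale expression over a gene set), covariate-adjusted group means
  (estimated marginal means), per-gene OLS differential expression with BH
  correction, and preranked GSEA (weighted running-sum ES, gene-label
  permutation NES).
* **Survival screening.** Per-gene Cox models (HR per log2 unit),
  cross-cohort intersection of concordant hits, and projection of hit sets
  onto single-cell pseudobulk cell types.
* **Synthetic cohorts.** A seeded generator plants resistance arms, immune
  modules, CD274–PD-L1 coupling, and prognostic co-expression modules with
  a ground-truth file, so the full pipeline is testable without licensed
  patient data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort; each is a thin driver over exported functions. For example:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_phenotype.R
Rscript analysis/04_pdl1_impute.R
```

prints

```
cohort: 300 patients, 2000 genes
planted arms:
        acquired eot_nonresistant            naive          primary
              60               60              120               60
phenotyping self-audit agreement: 1

filter cascade:
                 all                  eot resistance_evaluable
                 300                  180                  180
           resistant              primary             acquired
                 120                   60                   60
agreement with planted labels: 100.0%

trained on 185 observed biopsies; imputed 115
>=1%:  t = 13.27 log2 CPM (generating boundary 13.30), kappa 0.96
>=50%: t = 15.35 log2 CPM (generating boundary 15.30), kappa 0.99
3-class agreement with generating truth: 98.7%
```

i.e. the phenotyper recovers every planted arm exactly through the filter
cascade, and the kappa-optimal CD274 thresholds land within 0.05 log2 CPM
of the generating class boundaries. `analysis/05`–`07` continue with
differential expression (IFNγ genes up in acquired resistance, B-cell/DC
genes down in primary), enrichment (IFNγ NES +2.6 in acquired;
B-cell/DC NES −2.2 in primary), and the two-cohort Cox screen (29/30
planted prognostic genes recovered; favorable hits rank myeloid cell types
top in the single-cell projection). `run_pipeline()` executes the same
stages from one config with a machine-readable run report.

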