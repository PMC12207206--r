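# End-to-end orchestration over plain-file handoffs: every stage reads and
# writes inspectable files under the output directory and appends itself to
# a machine-readable run report.

#' Write a generated synthetic cohort to disk
#'
#' Emits the clinical CSVs (ISO dates), `counts.tsv`, the single-cell
#' matrices, `signatures.gmt` and `truth.json`.
#' @param sim output of [generate_rwe_cohort].
#' @param dir output directory.
#' @param epoch day-0 date for the ISO conversion.
#' @export
write_synth_cohort <- function(sim, dir, epoch = "2015-01-01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clinical_tables(sim, dir, epoch)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write_count_matrix(sim$sc$counts, file.path(dir, "sc_counts.tsv"))
  .write_csv(sim$sc$meta, file.path(dir, "sc_meta.csv"))
  write_gmt(sim$signatures, file.path(dir, "signatures.gmt"))
  truth <- sim$truth
  # short named vectors become JSON objects (names survive the round trip)
  for (nm in c("cd274_thresholds", "cd274_class_log2cpm"))
    truth[[nm]] <- as.list(truth[[nm]])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

.stage <- function(report, name, ...) {
  report$stages[[name]] <- list(stage = name, ...)
  report
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages, in dependency order: simulate, cohort_filter, endpoints,
#' phenotype, impute_pdl1, normalize, signatures, de, gsea, screen,
#' project. Any stage can be skipped via `config$stages`; outputs and a
#' machine-readable run report land under `outdir`.
#'
#' @param config a named list, or path to a YAML file, with optional
#'   elements `seed`, `synth` (overrides for [synth_config]), `stages`
#'   (character vector of stages to run), `n_perm` (enrichment
#'   permutations).
#' @param outdir output directory.
#' @return the run report (list), invisibly written to
#'   `outdir/run_report.json`.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("icirwe_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages_all <- c("simulate", "cohort_filter", "endpoints", "phenotype",
                  "impute_pdl1", "normalize", "signatures", "de", "gsea",
                  "screen", "project")
  stages <- if (is.null(config$stages)) stages_all
            else intersect(stages_all, config$stages)
  if (!is.null(config$stages) &&
      length(setdiff(config$stages, stages_all)) > 0)
    stop("unknown stage(s): ",
         paste(setdiff(config$stages, stages_all), collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_perm <- if (is.null(config$n_perm)) 1000L else as.integer(config$n_perm)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  cfg <- do.call(synth_config, c(config$synth, list(seed = seed)))
  cfg_file <- file.path(outdir, "config.yaml")
  yaml::write_yaml(list(seed = seed, stages = stages, n_perm = n_perm,
                        synth = config$synth), cfg_file)
  report <- list(config_hash = unname(tools::md5sum(cfg_file)),
                 seed = seed, stages = list())

  sim <- NULL
  for (st in stages) {
    res <- switch(st,
      simulate = {
        sim <- NULL
        sim <- generate_rwe_cohort(cfg)
        write_synth_cohort(sim, file.path(outdir, "sim"))
        list(n_patients = nrow(sim$patients),
             n_genes = nrow(sim$counts),
             audit_agreement = sim$truth$audit_agreement)
      },
      cohort_filter = {
        cc <- apply_cohort_criteria(sim$patients, sim$variants)
        list(n_included = length(cc$included),
             exclusions = as.list(cc$exclusion_counts))
      },
      endpoints = {
        os <- derive_endpoints(sim$patients, sim$therapy_lines,
                               sim$progression_events, "os")
        pfs <- derive_endpoints(sim$patients, sim$therapy_lines,
                                sim$progression_events, "rwpfs")
        out <- merge(os[, c("patient_id", "time_days", "event")],
                     pfs[, c("patient_id", "time_days", "event")],
                     by = "patient_id", suffixes = c("_os", "_rwpfs"))
        .write_csv(out, file.path(outdir, "outcomes.csv"))
        sim$outcomes_os <- os; sim$outcomes_rwpfs <- pfs
        list(n = nrow(out), os_events = sum(os$event),
             rwpfs_events = sum(pfs$event),
             os_median = km_estimate(os)$median)
      },
      phenotype = {
        lab <- phenotype_cohort(sim$biopsies, sim$therapy_lines,
                                sim$progression_events, sim$patients)
        .write_csv(lab, file.path(outdir, "labels.csv"))
        sim$labels <- lab
        c(list(cascade = as.list(attr(lab, "cascade"))))
      },
      impute_pdl1 = {
        norm0 <- normalize_counts(sim$counts)
        cd274 <- norm0["CD274", ]
        obs <- stats::setNames(sim$biopsies$pdl1_ihc_class,
                               sim$biopsies$sample_id)
        imp <- impute_pdl1(cd274, obs[colnames(norm0)])
        .write_csv(data.frame(sample_id = names(imp$classes),
                              pdl1_class = as.character(imp$classes),
                              imputed = attr(imp$classes, "imputed")),
                   file.path(outdir, "pdl1_imputed.csv"))
        sim$pdl1 <- imp
        list(n_train = imp$n_train, n_imputed = imp$n_imputed,
             kappa_ge1 = imp$model_ge1$kappa,
             kappa_ge50 = imp$model_ge50$kappa,
             threshold_ge1 = imp$model_ge1$threshold,
             threshold_ge50 = imp$model_ge50$threshold)
      },
      normalize = {
        norm <- normalize_counts(sim$counts)
        sim$norm <- norm
        list(n_genes = nrow(norm), n_samples = ncol(norm),
             tmm_factor_range = range(attr(norm, "tmm_factors")))
      },
      signatures = {
        sigs <- sim$signatures[c("ifng", "b_cell", "dc")]
        sc <- signature_score(sim$norm, sigs)
        lab <- sim$labels$label[match(colnames(sim$norm),
                                      sim$labels$sample_id)]
        grp <- ifelse(lab == "not_eot", "naive", lab)
        keep <- grp %in% c("naive", "primary", "acquired")
        covs <- data.frame(
          pdl1 = as.character(sim$pdl1$classes[colnames(sim$norm)]),
          site = sim$biopsies$tissue_site[match(colnames(sim$norm),
                                                sim$biopsies$sample_id)],
          stringsAsFactors = FALSE)
        adj <- lapply(rownames(sc), function(s)
          adjusted_group_means(sc[s, keep], grp[keep],
                               covs[keep, , drop = FALSE]))
        names(adj) <- rownames(sc)
        tab <- do.call(rbind, lapply(names(adj), function(s)
          cbind(signature = s, adj[[s]]$means)))
        .write_csv(tab, file.path(outdir, "signature_adjusted_means.csv"))
        sim$sig_scores <- sc; sim$groups <- grp
        list(signatures = rownames(sc),
             ifng_acquired_vs_naive = with(
               adj$ifng, means$adj_mean[means$group == "acquired"] -
                 means$adj_mean[means$group == "naive"]))
      },
      de = {
        keep <- sim$groups %in% c("naive", "acquired")
        de <- fit_gene_linear_models(sim$norm[, keep],
                                     factor(sim$groups[keep],
                                            levels = c("naive", "acquired")))
        utils::write.table(de, file.path(outdir, "de_acquired_vs_naive.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        sim$de <- de
        list(n_genes = nrow(de), n_q05 = sum(de$q_value < 0.05),
             top_gene = de$gene[which.max(abs(de$t_stat))])
      },
      gsea = {
        ranking <- stats::setNames(sim$de$t_stat, sim$de$gene)
        gs <- preranked_enrichment(ranking, sim$signatures,
                                   n_perm = n_perm, seed = seed + 10L)
        gs_out <- gs[, setdiff(names(gs), "leading_edge")]
        utils::write.table(gs_out, file.path(outdir, "gsea.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        sim$gsea <- gs
        list(n_sets = nrow(gs),
             ifng_nes = gs$nes[gs$set_name == "ifng"],
             ifng_q = gs$q_value[gs$set_name == "ifng"])
      },
      screen = {
        outc <- sim$outcomes_os
        outc$sample_id <- sim$truth$patients$sample_id[
          match(outc$patient_id, sim$truth$patients$patient_id)]
        scr <- per_gene_cox_screen(sim$norm, outc, screen_config(),
                                   cohort_id = "synthetic")
        utils::write.table(scr, file.path(outdir, "screen.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        sim$screen <- scr
        planted <- c(sim$truth$favorable, sim$truth$unfavorable)
        hits <- scr$gene[scr$converged & scr$p_value < 0.05]
        list(n_hits = length(hits),
             planted_recovered = sum(planted %in% hits),
             n_planted = length(planted))
      },
      project = {
        hits <- list(favorable = sim$truth$favorable,
                     unfavorable = sim$truth$unfavorable)
        pb <- pseudobulk_aggregate(sim$sc$counts, sim$sc$meta)
        proj <- project_hits_to_celltypes(hits, pb)
        .write_csv(proj$favorable$summary,
                   file.path(outdir, "celltype_projection_favorable.csv"))
        sim$projection <- proj
        list(favorable_top = proj$favorable$summary$cell_type[1],
             unfavorable_top = proj$unfavorable$summary$cell_type[1])
      })
    report <- .stage(report, st, result = res)
  }
  report$outputs <- sort(list.files(outdir, recursive = TRUE))
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(report, "state") <- sim
  invisible(report)
}
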