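# Per-gene Cox survival screen, cross-cohort intersection, score
# dichotomization, and projection of hit genes onto cell types.

#' Screen configuration for the per-gene Cox analysis
#' @param alpha per-cohort significance level.
#' @param endpoint `"os"` or `"rwpfs"` (bookkeeping).
#' @param covariates character vector of covariate column names.
#' @param subgroup optional named list, e.g. `list(pdl1_ihc_class = "lt1")`,
#'   filtering samples before the screen.
#' @export
screen_config <- function(alpha = 0.05, endpoint = c("os", "rwpfs"),
                          covariates = character(0), subgroup = NULL) {
  endpoint <- match.arg(endpoint)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(alpha = alpha, endpoint = endpoint,
                 covariates = covariates, subgroup = subgroup),
            class = "screen_config")
}

#' Per-gene Cox proportional-hazards screen
#'
#' For each gene, fits the endpoint on the gene's continuous log2 expression
#' (hazard ratio per log2 unit) plus any configured covariates, via
#' [survival::coxph]. Genes whose fit does not converge (or with constant
#' expression) are flagged and excluded from hits.
#'
#' @param norm gene-by-sample log2 expression matrix; columns must match
#'   `outcomes$sample_id`.
#' @param outcomes data.frame: `sample_id`, `time_days`, `event`, plus any
#'   covariate / subgroup columns named in `cfg`.
#' @param cfg a [screen_config].
#' @param cohort_id label carried into the results.
#' @return data.frame: gene, cohort_id, log_hr, hazard_ratio, p_value,
#'   direction (`favorable` iff HR < 1), converged; attribute
#'   `n_nonconverged`.
#' @export
per_gene_cox_screen <- function(norm, outcomes, cfg = screen_config(),
                                cohort_id = "cohort") {
  if (!is.null(cfg$subgroup)) {
    for (nm in names(cfg$subgroup))
      outcomes <- outcomes[!is.na(outcomes[[nm]]) &
                             outcomes[[nm]] %in% cfg$subgroup[[nm]], ,
                           drop = FALSE]
  }
  outcomes <- outcomes[outcomes$sample_id %in% colnames(norm), ,
                       drop = FALSE]
  if (sum(outcomes$event) < 10)
    stop("fewer than 10 events in the screened subgroup")
  m <- norm[, outcomes$sample_id, drop = FALSE]
  surv <- survival::Surv(outcomes$time_days, outcomes$event)
  covs <- NULL
  if (length(cfg$covariates) > 0) {
    covs <- as.data.frame(outcomes[, cfg$covariates, drop = FALSE])
  }
  genes <- rownames(m)
  log_hr <- p <- rep(NA_real_, length(genes))
  conv <- rep(FALSE, length(genes))
  for (i in seq_along(genes)) {
    x <- m[i, ]
    if (stats::sd(x) == 0) next
    dat <- data.frame(.x = x)
    if (!is.null(covs)) dat <- cbind(dat, covs)
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(surv ~ ., data = dat),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit)) next
    sm <- summary(fit)$coefficients
    if (is.na(sm[".x", "coef"]) || !is.finite(sm[".x", "coef"])) next
    log_hr[i] <- sm[".x", "coef"]
    p[i] <- sm[".x", "Pr(>|z|)"]
    conv[i] <- TRUE
  }
  out <- data.frame(gene = genes, cohort_id = cohort_id, log_hr = log_hr,
                    hazard_ratio = exp(log_hr), p_value = p,
                    direction = ifelse(log_hr < 0, "favorable",
                                       "unfavorable"),
                    converged = conv, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "n_nonconverged") <- sum(!conv)
  out
}

#' Intersect significant genes across two cohorts
#'
#' Hits are genes with p < alpha in both cohorts (converged fits only).
#' With `require_concordant_direction`, genes significant in both but with
#' opposite hazard directions are dropped and counted; the rest are
#' partitioned by their shared direction.
#'
#' @param results_a,results_b outputs of [per_gene_cox_screen].
#' @param alpha significance level applied in each cohort.
#' @param require_concordant_direction drop discordant-direction genes.
#' @return list: `favorable`, `unfavorable` (gene vectors), `discordant`,
#'   `n_hits_a`, `n_hits_b`.
#' @export
intersect_cohort_hits <- function(results_a, results_b, alpha = 0.05,
                                  require_concordant_direction = TRUE) {
  universe <- intersect(results_a$gene, results_b$gene)
  if (length(universe) == 0) stop("cohorts share no genes")
  a <- results_a[results_a$converged & !is.na(results_a$p_value) &
                   results_a$p_value < alpha, , drop = FALSE]
  b <- results_b[results_b$converged & !is.na(results_b$p_value) &
                   results_b$p_value < alpha, , drop = FALSE]
  common <- intersect(a$gene, b$gene)
  dir_a <- a$direction[match(common, a$gene)]
  dir_b <- b$direction[match(common, b$gene)]
  concordant <- dir_a == dir_b
  discordant <- common[!concordant]
  if (require_concordant_direction) common <- common[concordant]
  dir <- a$direction[match(common, a$gene)]
  list(favorable = common[dir == "favorable"],
       unfavorable = common[dir == "unfavorable"],
       discordant = discordant,
       n_hits_a = nrow(a), n_hits_b = nrow(b))
}

#' Dichotomize a signature score and compare survival between arms
#'
#' Splits samples at the median (default) or into tertile extremes, draws
#' Kaplan-Meier curves per arm, and reports the log-rank p-value and the
#' high-vs-low hazard ratio from a two-group Cox fit.
#'
#' @param scores named per-sample numeric vector (names = sample ids).
#' @param outcomes data.frame `sample_id`, `time_days`, `event`.
#' @param split `"median"` or `"tertile"` (top vs bottom tertile).
#' @param min_per_arm smallest allowed arm.
#' @return list: `km_high`, `km_low` ([km_estimate] outputs), `logrank_p`,
#'   `hazard_ratio` (high vs low), `n_high`, `n_low`.
#' @export
dichotomize_and_km <- function(scores, outcomes,
                               split = c("median", "tertile"),
                               min_per_arm = 10) {
  split <- match.arg(split)
  if (stats::sd(scores) == 0) stop("constant scores cannot be dichotomized")
  outcomes <- outcomes[outcomes$sample_id %in% names(scores), , drop = FALSE]
  s <- scores[outcomes$sample_id]
  if (split == "median") {
    grp <- ifelse(s > stats::median(s), "high", "low")
  } else {
    q <- stats::quantile(s, c(1 / 3, 2 / 3))
    grp <- ifelse(s >= q[2], "high", ifelse(s <= q[1], "low", NA))
  }
  keep <- !is.na(grp)
  outcomes <- outcomes[keep, , drop = FALSE]; grp <- grp[keep]
  if (min(table(grp)) < min_per_arm)
    stop("fewer than ", min_per_arm, " samples per arm after the split")
  sv <- survival::Surv(outcomes$time_days, outcomes$event)
  lr <- survival::survdiff(sv ~ grp)
  cx <- survival::coxph(sv ~ factor(grp, levels = c("low", "high")))
  list(km_high = km_estimate(outcomes[grp == "high", , drop = FALSE]),
       km_low = km_estimate(outcomes[grp == "low", , drop = FALSE]),
       logrank_p = stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE),
       hazard_ratio = unname(exp(stats::coef(cx))),
       n_high = sum(grp == "high"), n_low = sum(grp == "low"))
}

#' Project hit-gene partitions onto single-cell cell types
#'
#' Treats each partition (favorable / unfavorable) as a signature, scores it
#' per (patient, cell type) on the pseudobulk atlas, and ranks cell types by
#' median score. Genes absent from the atlas are reported.
#'
#' @param hits list with `favorable` and/or `unfavorable` gene vectors.
#' @param pb pseudobulk atlas ([pseudobulk_aggregate] output).
#' @return named list per partition: `summary` (cell types ranked by median
#'   score), `scores`, `n_detected`, `missing_genes`.
#' @export
project_hits_to_celltypes <- function(hits, pb) {
  parts <- hits[intersect(c("favorable", "unfavorable"), names(hits))]
  parts <- parts[vapply(parts, length, integer(1)) > 0]
  if (length(parts) == 0) stop("no hit genes to project")
  atlas_genes <- rownames(pb$counts)
  out <- lapply(names(parts), function(nm) {
    genes <- parts[[nm]]
    detected <- intersect(genes, atlas_genes)
    if (length(detected) == 0)
      stop("no '", nm, "' hit genes detectable in the atlas")
    prof <- celltype_signature_profile(pb, detected, sig_name = nm)
    list(summary = prof$summary, scores = prof$scores,
         n_detected = length(detected),
         missing_genes = setdiff(genes, atlas_genes))
  })
  names(out) <- names(parts)
  out
}
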