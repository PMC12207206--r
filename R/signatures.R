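# Gene-signature scoring and covariate-adjusted group means.

#' Signature score: mean log-scale normalized expression over a gene set
#'
#' @param norm normalized (log2 CPM) gene-by-sample matrix.
#' @param signature character vector of gene symbols, or a named list of
#'   such vectors.
#' @param sig_name label used in error messages when `signature` is a plain
#'   vector.
#' @return per-sample numeric vector with attribute `n_genes_used`, or a
#'   signatures-by-samples matrix when a list is given.
#' @export
signature_score <- function(norm, signature, sig_name = "signature") {
  if (is.list(signature)) {
    out <- t(vapply(names(signature), function(nm)
      signature_score(norm, signature[[nm]], sig_name = nm),
      numeric(ncol(norm))))
    colnames(out) <- colnames(norm)
    return(out)
  }
  genes <- unique(signature)
  present <- intersect(genes, rownames(norm))
  if (length(present) == 0)
    stop("signature '", sig_name, "' has no genes in the matrix")
  sc <- colMeans(norm[present, , drop = FALSE])
  attr(sc, "n_genes_used") <- length(present)
  sc
}

#' Covariate-adjusted group means of a signature score
#'
#' Fits `score ~ group + covariates` by least squares and reports estimated
#' marginal means per group: predictions averaged over a balanced reference
#' grid of covariate factor levels (numeric covariates held at their mean),
#' via the emmeans package. The group contrast is tested by the model's
#' t statistic.
#'
#' @param scores per-sample numeric scores.
#' @param group factor (or coercible) of group membership.
#' @param covariates optional data.frame of per-sample covariates.
#' @param weights `"equal"` for the balanced reference grid (default) or
#'   `"proportional"` to weight covariate levels by observed frequency.
#' @return list: `means` (data.frame group, adj_mean, se, df), `contrasts`
#'   (data.frame contrast, estimate, se, t, p_value), and the underlying
#'   `lm` fit.
#' @export
adjusted_group_means <- function(scores, group, covariates = NULL,
                                 weights = c("equal", "proportional")) {
  weights <- match.arg(weights)
  group <- factor(group)
  dat <- data.frame(.score = scores, .group = group)
  form <- .score ~ .group
  if (!is.null(covariates) && ncol(covariates) > 0) {
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c(".group", colnames(covariates)),
                               response = ".score")
  }
  fit <- stats::lm(form, data = dat)
  al <- stats::alias(fit)$Complete
  if (!is.null(al))
    stop("rank-deficient design; aliased: ",
         paste(rownames(al), collapse = ", "))
  emm <- emmeans::emmeans(fit, ".group", weights = weights)
  es <- as.data.frame(emm)
  means <- data.frame(group = es$.group, adj_mean = es$emmean, se = es$SE,
                      df = es$df, stringsAsFactors = FALSE)
  ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "none"))
  contrasts <- data.frame(contrast = ct$contrast, estimate = ct$estimate,
                          se = ct$SE, t = ct$t.ratio, p_value = ct$p.value,
                          stringsAsFactors = FALSE)
  list(means = means, contrasts = contrasts, fit = fit)
}
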