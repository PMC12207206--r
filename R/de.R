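# Per-gene covariate-adjusted differential expression, paired testing, and
# Benjamini-Hochberg adjustment.

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that p-values lie in (0, 1] and delegates to
#' [stats::p.adjust]. Stable under input reordering.
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Least-squares fit of every gene on a shared design; returns the
# coefficient, t, p and df for one focal column of the design.
.genewise_lm <- function(Y, X, focal, moderate = FALSE, d0 = 4) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  n <- nrow(X)
  df <- n - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  coefs <- xtx_inv %*% crossprod(X, t(Y))         # p x G
  res <- t(Y) - X %*% coefs
  s2 <- colSums(res^2) / df                       # per-gene residual variance
  cjj <- xtx_inv[focal, focal]
  if (moderate) {
    s0 <- mean(s2)
    s2_used <- (d0 * s0 + df * s2) / (d0 + df)
    df_used <- df + d0
  } else {
    s2_used <- s2
    df_used <- df
  }
  b <- coefs[focal, ]
  se <- sqrt(s2_used * cjj)
  t_stat <- ifelse(se > 0, b / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df_used), 1)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(coef = b, t = t_stat, p = p, df = df_used, flagged = se == 0)
}

#' Per-gene linear-model differential expression
#'
#' Fits `expression ~ group + covariates` per gene by least squares on the
#' log2 scale. The group coefficient is the log2 fold change (second factor
#' level vs first); t = coef/SE with df = n - rank. Optional variance
#' moderation shrinks each gene's residual variance toward the mean with a
#' fixed prior (d0 = 4), a simplified stand-in for full empirical-Bayes
#' estimation. Genes with zero residual variance get t = 0, p = 1 and are
#' flagged.
#'
#' @param norm gene-by-sample log2 expression matrix.
#' @param group two-level factor over samples.
#' @param covariates optional data.frame of per-sample covariates.
#' @param moderate shrink residual variances (default off: ordinary t).
#' @param d0 prior degrees of freedom for moderation.
#' @return data.frame: gene, log2_fc, t_stat, p_value, q_value, df, flagged.
#' @export
fit_gene_linear_models <- function(norm, group, covariates = NULL,
                                   moderate = FALSE, d0 = 4) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (min(table(group)) < 2) stop("need >= 2 samples per group")
  dat <- data.frame(.group = group)
  form <- ~.group
  if (!is.null(covariates) && ncol(covariates) > 0) {
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c(".group", colnames(covariates)))
  }
  X <- stats::model.matrix(form, dat)
  focal <- which(colnames(X) == paste0(".group", levels(group)[2]))
  fit <- .genewise_lm(norm, X, focal, moderate = moderate, d0 = d0)
  data.frame(gene = rownames(norm), log2_fc = unname(fit$coef),
             t_stat = unname(fit$t), p_value = unname(fit$p),
             q_value = bh_adjust(unname(fit$p)), df = fit$df,
             flagged = unname(fit$flagged),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Paired within-patient differential expression
#'
#' One-sample t-test per gene on the within-patient (post - pre)
#' differences: a documented simplification of intrapatient-correlation
#' modeling. Pairs with a missing pre or post sample are dropped and
#' reported.
#'
#' @param norm gene-by-sample log2 expression matrix.
#' @param pairs data.frame with columns `patient_id`, `pre`, `post` naming
#'   sample columns of `norm`.
#' @return data.frame as in [fit_gene_linear_models], with attribute
#'   `n_dropped`.
#' @export
paired_difference_test <- function(norm, pairs) {
  ok <- pairs$pre %in% colnames(norm) & pairs$post %in% colnames(norm)
  dropped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 complete pairs")
  D <- norm[, pairs$post, drop = FALSE] - norm[, pairs$pre, drop = FALSE]
  m <- rowMeans(D)
  s2 <- apply(D, 1, stats::var)
  se <- sqrt(s2 / n)
  t_stat <- ifelse(se > 0, m / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), n - 1), 1)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(gene = rownames(norm), log2_fc = unname(m),
                    t_stat = unname(t_stat), p_value = unname(p),
                    q_value = bh_adjust(unname(p)),
                    df = n - 1, flagged = unname(se == 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_dropped") <- dropped
  out
}
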