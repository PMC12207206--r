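# Between-sample count normalization: trimmed mean of M-values (TMM)
# scaling factors and log2 counts-per-million.

.quantile_factor <- function(counts, p = 0.75) {
  lib <- colSums(counts)
  apply(counts, 2, function(x) stats::quantile(x, p = p)) / lib
}

# Doubly trimmed, inverse-variance-weighted mean of gene-wise log ratios for
# one sample against the reference column.
.tmm_pair <- function(obs, ref, logratio_trim, sum_trim) {
  nO <- sum(obs); nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0) return(NA_real_)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  f <- 2^f
  if (is.na(f)) f <- 1
  f
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' The reference is the sample whose 75th-percentile count fraction is
#' closest to the mean across samples. For each sample, gene-wise log ratios
#' (M) and log abundances (A) against the reference are computed over genes
#' nonzero in both, doubly trimmed (30% on M, 5% on A by default), and the
#' factor is 2 to the inverse-variance-weighted mean of the retained M
#' values. Factors are rescaled so their geometric mean is 1. A sample
#' sharing no nonzero gene with the reference gets factor 1 with a warning.
#'
#' @param counts gene-by-sample matrix of non-negative counts (>= 2 samples).
#' @param logratio_trim,sum_trim trim fractions on M and A.
#' @return numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  if (any(colSums(counts) == 0)) stop("sample with zero library size")
  f75 <- .quantile_factor(counts)
  ref_i <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    .tmm_pair(counts[, j], counts[, ref_i], logratio_trim, sum_trim),
    numeric(1))
  if (any(is.na(f))) {
    warning(sum(is.na(f)), " sample(s) share no nonzero genes with the ",
            "reference; factor set to 1")
    f[is.na(f)] <- 1
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' value = log2( (count + prior_j) / (eff_j + 2 * prior_j) * 1e6 ) with
#' eff_j = factor_j * libsize_j. The pseudocount is expressed on the CPM
#' scale: prior_j = prior_count * eff_j / 1e6, i.e. `prior_count` counts per
#' million. Scaling the prior with the effective library size makes log-CPM
#' exactly invariant to doubling every count and to a sample being a scalar
#' multiple of another (composition invariance); for a library of exactly
#' one million the formula reduces to the plain
#' log2((count + prior) / (libsize + 2 prior) * 1e6).
#'
#' @param counts gene-by-sample count matrix.
#' @param factors per-sample scaling factors (defaults to all ones).
#' @param prior_count pseudocount per million reads.
#' @return matrix of log2 CPM values with attributes `tmm_factors` and
#'   `lib_sizes`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- factors * lib
  prior <- prior_count * eff / 1e6
  out <- log2(sweep(sweep(counts, 2, prior, "+"), 2,
                    eff + 2 * prior, "/") * 1e6)
  dimnames(out) <- dimnames(counts)
  attr(out, "tmm_factors") <- factors
  attr(out, "lib_sizes") <- lib
  out
}

#' TMM + log-CPM in one step
#' @inheritParams log_cpm
#' @param ... passed to [tmm_factors].
#' @export
normalize_counts <- function(counts, prior_count = 0.5, ...) {
  log_cpm(counts, tmm_factors(counts, ...), prior_count = prior_count)
}
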