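# PD-L1 IHC imputation from CD274 mRNA by exhaustive kappa-maximal
# threshold search.

#' Cohen's kappa for a 2x2 confusion table
#'
#' kappa = (p_o - p_e) / (1 - p_e) with p_o the observed agreement and p_e
#' the chance agreement from the marginals. Returns 0 for constant tables
#' (p_e = 1), where agreement beyond chance is undefined.
#'
#' @param confusion 2x2 matrix of counts: rows = predicted (positive,
#'   negative), columns = truth (positive, negative).
#' @return kappa in [-1, 1].
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (!all(dim(m) == c(2, 2))) stop("confusion must be a 2x2 table")
  if (any(m < 0)) stop("negative counts in confusion table")
  n <- sum(m)
  if (n == 0) stop("empty confusion table")
  po <- (m[1, 1] + m[2, 2]) / n
  pe <- (sum(m[1, ]) * sum(m[, 1]) + sum(m[2, ]) * sum(m[, 2])) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

.confusion_at <- function(expr, labels, t) {
  pred <- expr >= t
  matrix(c(sum(pred & labels), sum(pred & !labels),
           sum(!pred & labels), sum(!pred & !labels)),
         nrow = 2, byrow = TRUE)
}

.metrics <- function(m) {
  c(accuracy = (m[1, 1] + m[2, 2]) / sum(m),
    sensitivity = m[1, 1] / (m[1, 1] + m[2, 1]),
    specificity = m[2, 2] / (m[1, 2] + m[2, 2]))
}

#' Fit a kappa-optimal expression threshold for a binary IHC class
#'
#' Scans every candidate threshold (by default the sorted unique observed
#' expression values), classifying `expr >= t` as positive, and returns the
#' threshold maximizing Cohen's kappa against the observed labels; ties are
#' broken to the smallest threshold.
#'
#' @param expr numeric vector of per-sample CD274 expression (log2 CPM).
#' @param labels logical (or 0/1) vector: sample is in the target IHC class.
#' @param target_class `"ge50"` or `"ge1"` (bookkeeping only).
#' @param grid `"unique"` (observed values) or `"midpoints"` (midpoints
#'   between consecutive sorted unique values).
#' @return object of class `pdl1_threshold_model`: threshold, kappa,
#'   accuracy/sensitivity/specificity at the threshold, `n_train`, the grid.
#' @export
fit_expression_threshold <- function(expr, labels,
                                     target_class = c("ge50", "ge1"),
                                     grid = c("unique", "midpoints")) {
  target_class <- match.arg(target_class)
  grid <- match.arg(grid)
  labels <- as.logical(labels)
  if (length(expr) != length(labels)) stop("expr and labels must align")
  keep <- !is.na(expr) & !is.na(labels)
  expr <- expr[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2)
    stop("both classes must be present to fit a threshold")
  u <- sort(unique(expr))
  cand <- if (grid == "unique") u else (u[-1] + u[-length(u)]) / 2
  kappas <- vapply(cand, function(t)
    cohen_kappa(.confusion_at(expr, labels, t)), numeric(1))
  best <- which.max(kappas)  # first max = smallest-threshold tie-break
  m <- .confusion_at(expr, labels, cand[best])
  met <- .metrics(m)
  structure(list(target_class = target_class, threshold = cand[best],
                 kappa = kappas[best], accuracy = unname(met["accuracy"]),
                 sensitivity = unname(met["sensitivity"]),
                 specificity = unname(met["specificity"]),
                 n_train = length(expr), grid = cand,
                 grid_kappa = kappas),
            class = "pdl1_threshold_model")
}

#' Evaluate a fitted threshold on held-out data
#' @param model a `pdl1_threshold_model`.
#' @param expr,labels held-out expression and binary labels (both classes
#'   present).
#' @return named vector: accuracy, sensitivity, specificity.
#' @export
evaluate_threshold <- function(model, expr, labels) {
  labels <- as.logical(labels)
  if (length(expr) == 0) stop("empty evaluation set")
  if (length(unique(labels)) < 2)
    stop("both classes must be present for evaluation")
  .metrics(.confusion_at(expr, labels, model$threshold))
}

#' Three-class PD-L1 status from two binary threshold models
#'
#' `expr >= t_ge50` gives `ge50`; else `expr >= t_ge1` gives `r1_49`; else
#' `lt1`. An observed IHC class, when present, always overrides imputation.
#'
#' @param model_ge1,model_ge50 fitted `pdl1_threshold_model`s; the ge1
#'   threshold must not exceed the ge50 threshold.
#' @param expr numeric vector of CD274 expression.
#' @param observed optional character vector of observed IHC classes
#'   (`lt1`/`r1_49`/`ge50`, NA = unknown).
#' @return character vector of classes, with attribute `imputed` (logical).
#' @export
classify_pdl1 <- function(model_ge1, model_ge50, expr, observed = NULL) {
  t1 <- model_ge1$threshold; t50 <- model_ge50$threshold
  if (t1 > t50)
    stop("incoherent model pair: ge1 threshold exceeds ge50 threshold")
  cls <- ifelse(expr >= t50, "ge50", ifelse(expr >= t1, "r1_49", "lt1"))
  imputed <- rep(TRUE, length(cls))
  if (!is.null(observed)) {
    has <- !is.na(observed)
    cls[has] <- observed[has]
    imputed[has] <- FALSE
  }
  attr(cls, "imputed") <- imputed
  cls
}

#' Impute missing PD-L1 IHC classes across a cohort of biopsies
#'
#' Fits the two binary thresholds (>=1% and >=50%) on biopsies with observed
#' IHC and matched CD274 expression, then classifies the remainder.
#'
#' @param cd274 named numeric vector of CD274 log2-CPM, names = sample ids.
#' @param observed named character vector of observed IHC classes (NA where
#'   missing), same sample universe.
#' @return list: `classes` (named vector over all samples), `model_ge1`,
#'   `model_ge50`, `n_train`, `n_imputed`.
#' @export
impute_pdl1 <- function(cd274, observed) {
  stopifnot(!is.null(names(cd274)))
  observed <- observed[names(cd274)]
  train <- !is.na(observed)
  if (sum(train) < 2) stop("no training biopsies with observed PD-L1 IHC")
  m1 <- fit_expression_threshold(cd274[train],
                                 observed[train] %in% c("r1_49", "ge50"),
                                 target_class = "ge1")
  m50 <- fit_expression_threshold(cd274[train], observed[train] == "ge50",
                                  target_class = "ge50")
  cls <- classify_pdl1(m1, m50, cd274, observed)
  names(cls) <- names(cd274)
  list(classes = cls, model_ge1 = m1, model_ge50 = m50,
       n_train = sum(train), n_imputed = sum(!train))
}
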