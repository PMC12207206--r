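# Cohen's kappa, threshold search, and PD-L1 class imputation.

test_that("cohen_kappa matches hand computation on worked tables", {
  expect_equal(cohen_kappa(matrix(c(10, 0, 0, 10), 2)), 1)
  # a=20 b=5 c=10 d=15: p_o = 0.7, p_e = 0.5, kappa = 0.4
  expect_equal(cohen_kappa(matrix(c(20, 5, 10, 15), 2, byrow = TRUE)), 0.4)
  expect_equal(cohen_kappa(matrix(c(25, 25, 25, 25), 2)), 0)
  # constant table: chance agreement is 1, kappa defined as 0
  expect_equal(cohen_kappa(matrix(c(10, 0, 0, 0), 2, byrow = TRUE)), 0)
  expect_error(cohen_kappa(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("threshold search is exhaustive with smallest-threshold tie-break", {
  m <- fit_expression_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(m$threshold, 3)
  expect_equal(m$kappa, 1)
  expect_equal(m$accuracy, 1)
  # worked 6-point fixture: kappa(t=4) = 2/3 beats kappa(t=2) = 4/7
  m <- fit_expression_threshold(c(1, 2, 3, 4, 5, 6), c(0, 1, 0, 1, 1, 1))
  expect_equal(m$threshold, 4)
  expect_equal(m$kappa, 2 / 3)
  expect_equal(m$grid_kappa[m$grid == 2], 4 / 7)
  expect_error(fit_expression_threshold(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("fitted kappa equals cohen_kappa at the returned threshold and is the grid maximum", {
  set.seed(41)
  expr <- c(rnorm(60, 0, 1), rnorm(60, 1.5, 1))
  labels <- rep(c(0, 1), each = 60)
  m <- fit_expression_threshold(expr, labels)
  pred <- expr >= m$threshold
  conf <- matrix(c(sum(pred & labels), sum(pred & !labels),
                   sum(!pred & labels), sum(!pred & !labels)), 2,
                 byrow = TRUE)
  expect_equal(m$kappa, cohen_kappa(conf))
  rescan <- vapply(sort(unique(expr)), function(t) {
    p <- expr >= t
    cohen_kappa(matrix(c(sum(p & labels), sum(p & !labels),
                         sum(!p & labels), sum(!p & !labels)), 2,
                       byrow = TRUE))
  }, numeric(1))
  expect_true(all(m$kappa >= rescan - 1e-12))
})

test_that("well-separated classes are recovered with high sensitivity and specificity", {
  set.seed(42)
  expr <- c(rnorm(250, 0, 0.5), rnorm(250, 2, 0.5))
  labels <- rep(c(0, 1), each = 250)
  m <- fit_expression_threshold(expr, labels)
  expect_gte(m$sensitivity, 0.9)
  expect_gte(m$specificity, 0.9)
  expect_lt(abs(m$threshold - 1), 0.5)   # near the generating midpoint
})

test_that("permuting labels yields kappa centred on zero", {
  set.seed(43)
  expr <- c(rnorm(50, 0, 0.5), rnorm(50, 2, 0.5))
  labels <- rep(c(0, 1), each = 50)
  ks <- vapply(1:1000, function(i) {
    fit_expression_threshold(expr, sample(labels))$kappa
  }, numeric(1))
  # the fitted maximum is biased upward; the centre of the unfitted kappa
  # distribution is what must vanish, so permute predictions at a fixed cut
  pred <- expr >= 1
  k0 <- vapply(1:1000, function(i) {
    l <- sample(labels)
    cohen_kappa(matrix(c(sum(pred & l), sum(pred & !l),
                         sum(!pred & l), sum(!pred & !l)), 2, byrow = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(k0)), 0.05)
  expect_true(all(ks <= 1) && all(ks >= -1))
})

test_that("three-class combination respects coherence and observed IHC wins", {
  m1 <- structure(list(threshold = 2), class = "pdl1_threshold_model")
  m50 <- structure(list(threshold = 5), class = "pdl1_threshold_model")
  cls <- classify_pdl1(m1, m50, c(6, 3, 1))
  expect_equal(as.character(cls), c("ge50", "r1_49", "lt1"))
  cls <- classify_pdl1(m1, m50, c(9, 9), observed = c("lt1", NA))
  expect_equal(as.character(cls), c("lt1", "ge50"))
  expect_false(attr(cls, "imputed")[1])
  bad <- structure(list(threshold = 7), class = "pdl1_threshold_model")
  expect_error(classify_pdl1(bad, m50, 1), "incoherent")
})

test_that("held-out evaluation reproduces brute-force confusion metrics", {
  m <- fit_expression_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  ev <- evaluate_threshold(m, c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(unname(ev), c(1, 1, 1))
  # all-positive predictor on balanced labels
  lowm <- structure(list(threshold = -Inf), class = "pdl1_threshold_model")
  ev <- evaluate_threshold(lowm, c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(unname(ev), c(0.5, 1, 0))
  # 10-point fixture against a hand confusion count at t = 4
  expr <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  lab <- c(0, 0, 1, 0, 1, 1, 0, 1, 1, 1)
  m4 <- structure(list(threshold = 4), class = "pdl1_threshold_model")
  ev <- evaluate_threshold(m4, expr, lab)
  # pred+ = 7:4..10; TP=5 FP=2 FN=1 TN=2
  expect_equal(unname(ev["accuracy"]), 7 / 10)
  expect_equal(unname(ev["sensitivity"]), 5 / 6)
  expect_equal(unname(ev["specificity"]), 2 / 4)
  expect_error(evaluate_threshold(m4, numeric(0), numeric(0)), "empty")
})

test_that("cohort imputation trains on observed IHC and recovers the generating classes", {
  sim <- cached_sim()
  norm <- cached_sim("norm", function() normalize_counts(cached_sim()$counts))
  cd274 <- norm["CD274", ]
  obs <- stats::setNames(sim$biopsies$pdl1_ihc_class,
                         sim$biopsies$sample_id)[colnames(norm)]
  imp <- impute_pdl1(cd274, obs)
  truth <- stats::setNames(sim$truth$patients$pdl1_class,
                           sim$truth$patients$sample_id)[colnames(norm)]
  expect_gte(mean(imp$classes == truth), 0.9)
  # observed labels always pass through unchanged
  has <- !is.na(obs)
  expect_equal(unname(imp$classes[has]), unname(obs[has]))
  expect_true(imp$model_ge1$threshold < imp$model_ge50$threshold)
})
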