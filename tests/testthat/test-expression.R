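# TMM/log-CPM normalization, signature scoring, adjusted group means.

test_that("identical columns get unit TMM factors", {
  set.seed(50)
  a <- rnbinom(300, mu = 50, size = 5)
  m <- cbind(s1 = a, s2 = a, s3 = a)
  rownames(m) <- sprintf("g%03d", 1:300)
  expect_equal(unname(tmm_factors(m)), c(1, 1, 1))
})

test_that("a doubled column is composition-equivalent after normalization", {
  set.seed(51)
  a <- rnbinom(500, mu = 50, size = 5)
  m <- cbind(A = a, B = 2L * a)
  rownames(m) <- sprintf("g%03d", 1:500)
  n <- normalize_counts(m)
  expect_lt(max(abs(n[, "A"] - n[, "B"])), 1e-9)
})

test_that("TMM factors match the independent edgeR implementation on an NB fixture", {
  set.seed(52)
  G <- 400
  mu <- 2^rnorm(G, 5, 1.5)
  m <- cbind(s1 = rnbinom(G, mu = mu, size = 8),
             s2 = rnbinom(G, mu = 3 * mu, size = 8),
             s3 = rnbinom(G, mu = mu * c(rep(4, 80), rep(1, G - 80)),
                          size = 8),
             s4 = rnbinom(G, mu = 0.5 * mu, size = 8))
  rownames(m) <- sprintf("g%03d", 1:G)
  f <- tmm_factors(m)
  fe <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
  expect_equal(unname(f), fe, tolerance = 1e-10)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
})

test_that("log-CPM follows the stated formula and its invariances", {
  # library of exactly 1e6: value = log2((100 + 0.5)/(1e6 + 1) * 1e6)
  m <- matrix(c(100L, 999900L, 100L, 999900L), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  v <- log_cpm(m, factors = c(1, 1))
  expect_equal(v["a", "s1"], log2(100.5 / 1000001 * 1e6), tolerance = 1e-12)
  # all-zero gene is constant across equal-library samples
  m2 <- rbind(m, z = c(0L, 0L))
  v2 <- log_cpm(m2)
  expect_equal(v2["z", "s1"], v2["z", "s2"])
  # doubling every count everywhere leaves log-CPM unchanged
  expect_equal(log_cpm(m), log_cpm(2L * m), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(log_cpm(matrix(0L, 2, 2)), "zero library")
})

test_that("signature score is the mean over present genes and is linear", {
  norm <- matrix(c(4, 6, 2, 8), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sc <- signature_score(norm, c("g1", "g2"))
  expect_equal(as.numeric(sc), c(5, 5))
  # single-gene signature is that gene's row
  expect_equal(as.numeric(signature_score(norm, "g1")),
               unname(norm["g1", ]))
  # score(values + c) = score + c
  expect_equal(as.numeric(signature_score(norm + 3, c("g1", "g2"))),
               as.numeric(sc) + 3)
  expect_error(signature_score(norm, c("nope"), sig_name = "mysig"),
               "mysig")
  # an 18-gene set equals the column mean over those rows
  sim <- cached_sim()
  nrm <- cached_sim("norm", function() normalize_counts(cached_sim()$counts))
  ifng <- sim$signatures$ifng
  expect_equal(as.numeric(signature_score(nrm, ifng)),
               unname(colMeans(nrm[ifng, ])))
})

test_that("adjusted means reduce to raw means without/with balanced covariates", {
  sc <- c(1, 2, 3, 4)
  adj <- adjusted_group_means(sc, c("A", "A", "B", "B"))
  expect_equal(adj$means$adj_mean, c(1.5, 3.5))
  # perfectly balanced binary covariate: adjusted = raw means
  cov <- data.frame(site = c("x", "y", "x", "y"))
  adj2 <- suppressWarnings(   # exact fit on the 4-point fixture
    adjusted_group_means(sc, c("A", "A", "B", "B"), cov))
  expect_equal(adj2$means$adj_mean, c(1.5, 3.5))
})

test_that("unbalanced covariates match the hand normal-equations oracle", {
  set.seed(60)
  grp <- factor(rep(c("A", "B"), c(6, 6)))
  cov <- factor(c(rep("u", 5), "v", rep("v", 5), "u"))   # unbalanced
  y <- 2 + (grp == "B") * 1.5 + (cov == "v") * 0.8 + rnorm(12, 0, 0.3)
  X <- cbind(1, grp == "B", cov == "v")
  beta <- solve(t(X) %*% X, t(X) %*% y)
  # balanced reference grid: covariate levels weighted equally
  oracle_A <- beta[1] + 0.5 * beta[3]
  oracle_B <- beta[1] + beta[2] + 0.5 * beta[3]
  adj <- adjusted_group_means(y, grp, data.frame(cov = cov))
  expect_equal(adj$means$adj_mean, c(oracle_A, oracle_B), tolerance = 1e-10)
  # contrast t-statistic = coefficient / SE from the same fit
  s2 <- sum((y - X %*% beta)^2) / (12 - 3)
  se_b <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(abs(adj$contrasts$t), unname(beta[2] / se_b),
               tolerance = 1e-10)
})

test_that("rank-deficient designs error with the aliased column named", {
  sc <- c(1, 2, 3, 4)
  cov <- data.frame(dup = c("A", "A", "B", "B"))   # identical to group
  expect_error(adjusted_group_means(sc, c("A", "A", "B", "B"), cov),
               "aliased")
})
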