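# Per-gene Cox screen, cross-cohort intersection, dichotomized KM,
# cell-type projection.

sim_screen_data <- function(n = 200, G = 20, beta = 1.0, seed = 100,
                            h0 = 0.005, horizon = 2000) {
  set.seed(seed)
  X <- matrix(rnorm(n * G), n, G,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("g%02d", 1:G)))
  lp <- beta * X[, 1]
  tt <- rexp(n, h0 * exp(lp))
  ev <- tt <= horizon
  outcomes <- data.frame(sample_id = rownames(X),
                         time_days = as.integer(pmin(tt, horizon)) + 1L,
                         event = ev, stringsAsFactors = FALSE)
  list(norm = t(X), outcomes = outcomes)
}

test_that("a planted log-HR of 1.0 is recovered within [0.7, 1.3] and significant", {
  d <- sim_screen_data()
  res <- per_gene_cox_screen(d$norm, d$outcomes)
  expect_gte(res$log_hr[1], 0.7)
  expect_lte(res$log_hr[1], 1.3)
  expect_lt(res$p_value[1], 0.05)
  expect_equal(res$direction[1], "unfavorable")
})

test_that("type-I error of the screen is calibrated under the null", {
  set.seed(101)
  ps <- unlist(lapply(1:25, function(r) {
    d <- sim_screen_data(n = 100, G = 40, beta = 0, seed = 1000 + r)
    per_gene_cox_screen(d$norm, d$outcomes)$p_value
  }))
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
})

test_that("constant-expression genes are flagged as non-convergent", {
  d <- sim_screen_data(G = 5)
  d$norm[2, ] <- 3.14
  res <- per_gene_cox_screen(d$norm, d$outcomes)
  expect_false(res$converged[2])
  expect_equal(attr(res, "n_nonconverged"), 1)
})

test_that("screen requires at least 10 events and honours subgroup filters", {
  d <- sim_screen_data(n = 30, G = 5)
  d$outcomes$event <- FALSE
  expect_error(per_gene_cox_screen(d$norm, d$outcomes), "10 events")
  d2 <- sim_screen_data(n = 100, G = 5)
  d2$outcomes$pdl1 <- rep(c("lt1", "ge50"), 50)
  res <- per_gene_cox_screen(
    d2$norm, d2$outcomes,
    screen_config(subgroup = list(pdl1 = "lt1")))
  expect_true(all(res$converged))
})

test_that("cohort intersection is idempotent, direction-aware, and tolerates disjoint hits", {
  d <- sim_screen_data(G = 30, beta = 1.2, seed = 102)
  res <- per_gene_cox_screen(d$norm, d$outcomes, cohort_id = "A")
  self <- intersect_cohort_hits(res, res)
  hits_a <- res$gene[res$converged & res$p_value < 0.05]
  expect_setequal(c(self$favorable, self$unfavorable), hits_a)
  expect_equal(length(self$discordant), 0)
  # hand-built discordant / disjoint cases
  mk <- function(genes, p, dir) data.frame(
    gene = genes, cohort_id = "x", log_hr = ifelse(dir == "favorable",
                                                   -1, 1),
    hazard_ratio = 1, p_value = p, direction = dir, converged = TRUE,
    stringsAsFactors = FALSE)
  a <- mk(c("a", "b", "c"), c(0.01, 0.01, 0.01),
          c("unfavorable", "unfavorable", "favorable"))
  b <- mk(c("b", "c", "d"), c(0.01, 0.01, 0.01),
          c("unfavorable", "unfavorable", "favorable"))
  ih <- intersect_cohort_hits(a, b)
  expect_equal(ih$unfavorable, "b")
  expect_equal(ih$discordant, "c")
  expect_equal(length(ih$favorable), 0)
  disj <- intersect_cohort_hits(mk("a", 0.01, "favorable"),
                                mk("a", 0.9, "favorable"))
  expect_equal(length(c(disj$favorable, disj$unfavorable)), 0)
})

test_that("median-split KM detects a halved hazard and rejects tiny arms", {
  set.seed(103)
  n <- 300
  score <- rnorm(n)
  names(score) <- sprintf("s%03d", 1:n)
  hr <- ifelse(score > stats::median(score), 0.5, 1)
  tt <- rexp(n, 0.004 * hr)
  outcomes <- data.frame(sample_id = names(score),
                         time_days = as.integer(pmin(tt, 2000)) + 1L,
                         event = tt <= 2000, stringsAsFactors = FALSE)
  res <- dichotomize_and_km(score, outcomes)
  expect_gte(res$hazard_ratio, 0.4)
  expect_lte(res$hazard_ratio, 0.65)
  expect_lt(res$logrank_p, 0.05)
  expect_error(dichotomize_and_km(score[1:10], outcomes[1:10, ]),
               "per arm")
  expect_error(dichotomize_and_km(rep(1, n), outcomes), "constant")
})

test_that("null scores give approximately uniform log-rank p-values", {
  set.seed(104)
  ps <- vapply(1:200, function(i) {
    n <- 60
    score <- rnorm(n); names(score) <- sprintf("s%02d", 1:n)
    tt <- rexp(n, 0.004)
    outcomes <- data.frame(sample_id = names(score),
                           time_days = as.integer(pmin(tt, 2000)) + 1L,
                           event = tt <= 2000, stringsAsFactors = FALSE)
    dichotomize_and_km(score, outcomes, min_per_arm = 5)$logrank_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("hit projection ranks planted myeloid structure top and errors on absent genes", {
  sim <- cached_sim()
  pb <- pseudobulk_aggregate(sim$sc$counts, sim$sc$meta)
  proj <- project_hits_to_celltypes(
    list(favorable = sim$truth$favorable,
         unfavorable = sim$truth$unfavorable), pb)
  expect_true(proj$favorable$summary$cell_type[1] %in%
                c("DC", "macrophage", "monocyte"))
  expect_true(proj$unfavorable$summary$cell_type[1] %in%
                c("ciliated", "tumor"))
  expect_error(project_hits_to_celltypes(list(favorable = c("NOPE1")), pb),
               "detectable")
  # composition oracle: summary equals manual score + median pipeline
  manual <- celltype_signature_profile(pb, sim$truth$favorable)
  expect_equal(proj$favorable$summary, manual$summary)
})
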