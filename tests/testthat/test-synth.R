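# The synthetic-cohort generator: determinism, planted structure,
# statistical faithfulness.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_patients = 40, n_genes = 300, n_sc_patients = 3,
                      seed = 110)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_synth_cohort(generate_rwe_cohort(cfg), d1)
  write_synth_cohort(generate_rwe_cohort(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("an all-acquired cohort phenotypes as all acquired", {
  cfg <- synth_config(n_patients = 50, n_genes = 300, n_sc_patients = 2,
                      arm_fractions = c(naive = 0, eot_nonresistant = 0,
                                        primary = 0, acquired = 1),
                      seed = 111)
  sim <- generate_rwe_cohort(cfg)
  lab <- phenotype_cohort(sim$biopsies, sim$therapy_lines,
                          sim$progression_events, sim$patients)
  expect_true(all(lab$label == "acquired"))
})

test_that("cascade counts equal planted arm sizes on a mixed cohort", {
  sim <- cached_sim()
  lab <- phenotype_cohort(sim$biopsies, sim$therapy_lines,
                          sim$progression_events, sim$patients)
  cas <- attr(lab, "cascade")
  arms <- table(sim$truth$patients$arm)
  expect_equal(unname(cas["eot"]),
               sum(arms[c("eot_nonresistant", "primary", "acquired")]))
  expect_equal(unname(cas["resistant"]),
               sum(arms[c("primary", "acquired")]))
  expect_equal(unname(cas["primary"]), unname(arms["primary"]))
  expect_equal(unname(cas["acquired"]), unname(arms["acquired"]))
  expect_equal(sim$truth$audit_agreement, 1)
})

test_that("NB counts match the configured mean and dispersion within 10%", {
  cfg <- synth_config(n_patients = 150, n_genes = 1200, n_sc_patients = 2,
                      seed = 112)
  sim <- generate_expression(cfg, generate_cohort(cfg))
  counts <- sim$counts
  # use filler genes in the naive arm (no planted effects)
  filler <- grep("^GENE", rownames(counts), value = TRUE)
  naive <- sim$truth$patients$sample_id[sim$truth$patients$arm == "naive"]
  sub <- counts[filler, naive]
  # empirical gene means against the generating means (baseline x libfac)
  lf <- sim$truth$lib_factors[naive]
  expected <- outer(sim$truth$baseline[filler], lf)
  expect_lt(abs(mean(sub) / mean(expected) - 1), 0.1)
  # library-descaled moment estimate of the NB dispersion:
  # var(c/lf) = mu * E[1/lf] + disp * mu^2
  adj <- sweep(sub, 2, lf, "/")
  m <- rowMeans(adj); v <- apply(adj, 1, var)
  keep <- m > 20
  disp <- stats::median((v[keep] - m[keep] * mean(1 / lf)) / m[keep]^2)
  expect_lt(abs(disp - cfg$nb_dispersion), 0.1 * cfg$nb_dispersion)
})

test_that("with null prognostic effects the cohort KM tracks the exponential curve", {
  cfg <- synth_config(n_patients = 400, n_genes = 300, n_sc_patients = 2,
                      arm_fractions = c(naive = 0.5, eot_nonresistant = 0,
                                        primary = 0.25, acquired = 0.25),
                      prognostic_log_hr = 1e-9, beta_stage = 0,
                      seed = 113)
  sim <- generate_rwe_cohort(cfg)
  os <- derive_endpoints(sim$patients, sim$therapy_lines,
                         sim$progression_events, "os")
  km <- km_estimate(os)
  # compare to S(t) = exp(-h0 t) at quartile times with a simulation band
  for (tq in c(200, 400, 600)) {
    s_hat <- km$surv[max(which(km$time <= tq))]
    s_true <- exp(-cfg$h0 * tq)
    expect_lt(abs(s_hat - s_true), 3 * sqrt(s_true * (1 - s_true) / 400))
  }
})

test_that("the planted IFNg effect appears in signature-score differences near +1", {
  sim <- cached_sim()
  norm <- cached_sim("norm", function() normalize_counts(cached_sim()$counts))
  sc <- signature_score(norm, sim$signatures$ifng)
  arm <- sim$truth$patients$arm[match(colnames(norm),
                                      sim$truth$patients$sample_id)]
  d <- mean(sc[arm == "acquired"]) - mean(sc[arm == "naive"])
  expect_gte(d, 0.8)
  expect_lte(d, 1.2)
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(margin_days = 20), "margin_days too large")
  expect_error(synth_config(horizon = 0), "horizon")
  expect_error(synth_config(arm_fractions = c(naive = 0.5,
                                              eot_nonresistant = 0.2,
                                              primary = 0.2,
                                              acquired = 0.2)),
               "sum to 1")
  expect_error(synth_config(cd274_sd = 0), "positive")
})

test_that("fuzzed timelines are valid but unconstrained", {
  tls <- fuzz_timelines(200, seed = 114)
  for (tl in tls) {
    if (!is.na(tl$end_day)) expect_gte(tl$end_day, tl$start_day)
    if (!is.na(tl$death_day)) expect_gte(tl$death_day, tl$start_day)
    expect_gte(tl$last_followup_day, tl$start_day)
  }
})
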