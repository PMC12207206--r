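# Seeded generator of synthetic multimodal real-world-evidence cohorts:
# treatment timelines constructed strictly inside/outside the phenotyping
# rule windows (with a configurable margin of slack), negative-binomial
# expression with planted immune-module effects by resistance arm, CD274
# expression coupled to PD-L1 IHC class through known generating thresholds,
# survival coupled to planted prognostic co-expression modules, and a small
# single-cell compartment for pseudobulk work. Emits a truth file so every
# downstream module can be tested against known ground truth.

IFNG_18 <- c("CCL5", "CD27", "CD274", "CD276", "CD8A", "CMKLR1", "CXCL9",
             "CXCR6", "HLA-DQA1", "HLA-DRB1", "HLA-E", "IDO1", "LAG3",
             "NKG7", "PDCD1LG2", "PSMB10", "STAT1", "TIGIT")
BCELL_10 <- c("CD19", "CD22", "CD79A", "CD79B", "MS4A1", "BLK", "CR2",
              "FCRL2", "PAX5", "TNFRSF13B")
DC_10 <- c("CD1A", "CD1B", "CD1C", "CD1E", "CLEC10A", "FCER1A", "CLEC4C",
           "BATF3", "FLT3", "ZBTB46")
SC_CELL_TYPES <- c("tumor", "T_cell", "B_cell", "DC", "macrophage",
                   "monocyte", "ciliated")

#' Configuration for the synthetic-cohort generator
#'
#' @param n_patients cohort size.
#' @param arm_fractions named fractions (summing to 1) of planted resistance
#'   arms: `naive`, `eot_nonresistant`, `primary`, `acquired`.
#' @param n_genes size of the gene universe (includes the named immune and
#'   prognostic module genes).
#' @param module_effects named list of per-arm planted log2 effects for the
#'   immune modules (`ifng`, `b_cell`, `dc`).
#' @param nb_dispersion negative-binomial dispersion of the bulk counts.
#' @param baseline_log2_mean,baseline_log2_sd log-normal gene baseline.
#' @param lib_log_sd per-sample library-size log-sd.
#' @param cd274_base_count expected CD274 count in the lt1 class (before
#'   library scaling).
#' @param cd274_class_shifts named log2 shifts of CD274 by PD-L1 class.
#' @param cd274_sd log2-scale Gaussian sd of CD274 around its class mean.
#' @param pdl1_class_probs named sampling probabilities of the true class.
#' @param pdl1_observed_fraction fraction of biopsies with observed IHC.
#' @param n_prognostic number of planted prognostic genes (half favorable,
#'   half unfavorable), generated as two correlated co-expression modules.
#' @param prognostic_log_hr target marginal per-gene |log hazard ratio| per
#'   log2 expression unit.
#' @param prognostic_module_sd,prognostic_noise_sd latent module factor sd
#'   and gene-level noise sd (log2 scale).
#' @param h0 baseline hazard per day; `horizon` administrative censoring
#'   (days from line start); `beta_stage` log-HR of stage IV vs III.
#' @param margin_days slack (days) kept between every generated date and the
#'   nearest phenotyping rule boundary.
#' @param n_sc_patients,sc_cells_range single-cell compartment size.
#' @param seed RNG seed; each generation stage derives its own stream.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 300,
                         arm_fractions = c(naive = 0.4,
                                           eot_nonresistant = 0.2,
                                           primary = 0.2, acquired = 0.2),
                         n_genes = 2000,
                         module_effects = list(
                           ifng = c(acquired = 1.0),
                           b_cell = c(primary = -1.0),
                           dc = c(primary = -1.0)),
                         nb_dispersion = 0.1,
                         baseline_log2_mean = 5, baseline_log2_sd = 1.5,
                         lib_log_sd = 0.15,
                         cd274_base_count = 600,
                         cd274_class_shifts = c(lt1 = 0, r1_49 = 2,
                                                ge50 = 4),
                         cd274_sd = 0.5,
                         pdl1_class_probs = c(lt1 = 0.35, r1_49 = 0.35,
                                              ge50 = 0.30),
                         pdl1_observed_fraction = 0.6,
                         n_prognostic = 30,
                         prognostic_log_hr = 0.8,
                         prognostic_module_sd = 0.5,
                         prognostic_noise_sd = 0.2,
                         h0 = 1 / 600, horizon = 1095, beta_stage = 0.4,
                         margin_days = 2,
                         n_sc_patients = 10, sc_cells_range = c(8, 25),
                         seed = 1) {
  if (abs(sum(arm_fractions) - 1) > 1e-8)
    stop("arm_fractions must sum to 1")
  if (margin_days < 1) stop("margin_days must be >= 1")
  cfgp <- phenotype_config()
  if (2 * margin_days >= min(cfgp$eot_window_days,
                             cfgp$resistance_window_days))
    stop("margin_days too large for the phenotyping windows")
  if (horizon <= 0) stop("horizon must be positive")
  if (cd274_sd <= 0 || prognostic_module_sd <= 0 || prognostic_noise_sd <= 0)
    stop("all sds must be positive")
  structure(list(
    n_patients = n_patients, arm_fractions = arm_fractions,
    n_genes = n_genes, module_effects = module_effects,
    nb_dispersion = nb_dispersion, baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, lib_log_sd = lib_log_sd,
    cd274_base_count = cd274_base_count,
    cd274_class_shifts = cd274_class_shifts, cd274_sd = cd274_sd,
    pdl1_class_probs = pdl1_class_probs,
    pdl1_observed_fraction = pdl1_observed_fraction,
    n_prognostic = n_prognostic, prognostic_log_hr = prognostic_log_hr,
    prognostic_module_sd = prognostic_module_sd,
    prognostic_noise_sd = prognostic_noise_sd,
    h0 = h0, horizon = horizon, beta_stage = beta_stage,
    margin_days = margin_days, n_sc_patients = n_sc_patients,
    sc_cells_range = sc_cells_range, seed = seed),
    class = "synth_config")
}

# Gene universe: named immune/prognostic modules first, then fillers.
.gene_universe <- function(cfg) {
  nf <- cfg$n_prognostic %/% 2
  fav <- sprintf("FAV%02d", seq_len(nf))
  unf <- sprintf("UNF%02d", seq_len(cfg$n_prognostic - nf))
  named <- unique(c(IFNG_18, BCELL_10, DC_10, fav, unf))
  if (cfg$n_genes < length(named) + 10)
    stop("n_genes too small for the named module genes")
  fillers <- sprintf("GENE%04d", seq_len(cfg$n_genes - length(named)))
  list(genes = c(named, fillers),
       modules = list(ifng = IFNG_18, b_cell = BCELL_10, dc = DC_10),
       favorable = fav, unfavorable = unf)
}

#' Generate the clinical tables of a synthetic cohort
#'
#' Timelines are constructed per planted arm strictly inside or outside the
#' phenotyping windows with at least `margin_days` of slack, so applying the
#' phenotyping rules recovers the arms exactly. Death and follow-up days are
#' provisional until [generate_survival] merges the survival model in.
#'
#' @param cfg a [synth_config].
#' @return list: clinical tables (`patients`, `therapy_lines`,
#'   `progression_events`, `biopsies`) and `truth` (per-patient planted arm,
#'   PD-L1 class, observation flag, seed).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_patients
  m <- cfg$margin_days
  arms <- rep(names(cfg$arm_fractions),
              times = diff(round(cumsum(c(0, cfg$arm_fractions)) * n)))
  arms <- c(arms, rep(names(cfg$arm_fractions)[1], n - length(arms)))
  arms <- sample(arms)

  pid <- sprintf("P%04d", seq_len(n))
  sid <- sprintf("S%04d", seq_len(n))
  stage <- sample(c("III", "IV"), n, replace = TRUE, prob = c(0.3, 0.7))
  pdl1_true <- sample(names(cfg$pdl1_class_probs), n, replace = TRUE,
                      prob = cfg$pdl1_class_probs)
  pdl1_obs <- stats::runif(n) < cfg$pdl1_observed_fraction

  start <- sample(0:60, n, replace = TRUE)
  dur <- integer(n); collection <- integer(n)
  next_start <- rep(NA_integer_, n)
  ev_day <- rep(NA_integer_, n); ev_type <- rep(NA_character_, n)
  w_eot <- 30L; w_res <- 90L; d_acq <- 180L

  for (i in seq_len(n)) {
    a <- arms[i]
    if (a == "naive") {
      dur[i] <- sample(120:400, 1)
      collection[i] <- start[i] - sample(7:30, 1)
      if (stats::runif(1) < 0.4) {   # unrelated on-treatment progression
        ev_day[i] <- start[i] + sample((14 + m):(dur[i] - m), 1)
        ev_type[i] <- "progression"
      }
    } else if (a == "eot_nonresistant") {
      dur[i] <- sample(70:400, 1)
      collection[i] <- start[i] + dur[i] +
        sample(-(w_eot - m):(w_eot - m), 1)
      if (stats::runif(1) < 0.5)
        next_start[i] <- start[i] + dur[i] + w_res + m +
          sample(1:150, 1)
    } else {
      dur[i] <- if (a == "primary") sample(63:(d_acq - m - 1), 1)
                else sample((d_acq + m):400, 1)
      collection[i] <- start[i] + dur[i] +
        sample(-(w_eot - m):(w_eot - m), 1)
      trig_next <- stats::runif(1) < 0.7
      trig_evt <- stats::runif(1) < 0.7
      if (!trig_next && !trig_evt) trig_next <- TRUE
      if (trig_next)
        next_start[i] <- start[i] + dur[i] + sample(0:(w_res - m), 1)
      if (trig_evt) {
        ev_day[i] <- collection[i] + sample(0:(w_res - m), 1)
        ev_type[i] <- sample(c("progression", "metastasis"), 1)
      }
    }
  }

  patients <- data.frame(
    patient_id = pid, stage = stage, histology = "nonsquamous",
    diagnosis_year = sample(2016:2022, n, replace = TRUE),
    age_known = TRUE,
    pdl1_ihc_class = ifelse(pdl1_obs, pdl1_true, NA_character_),
    kras_mut = stats::runif(n) < 0.25,
    death_day = NA_integer_,
    last_followup_day = pmax(start + dur, collection,
                             ifelse(is.na(next_start), 0L, next_start)) + 30L,
    stringsAsFactors = FALSE)

  lines1 <- data.frame(
    patient_id = pid, line_number = 1L,
    regimen_class = sample(c("ici", "ici_chemo"), n, replace = TRUE),
    start_day = start, end_day = start + dur, stringsAsFactors = FALSE)
  has2 <- !is.na(next_start)
  lines2 <- data.frame(
    patient_id = pid[has2], line_number = 2L,
    regimen_class = sample(c("platinum_chemo", "other"), sum(has2),
                           replace = TRUE),
    start_day = next_start[has2],
    end_day = next_start[has2] + sample(30:200, sum(has2), replace = TRUE),
    stringsAsFactors = FALSE)
  therapy_lines <- rbind(lines1, lines2)
  therapy_lines <- therapy_lines[order(therapy_lines$patient_id,
                                       therapy_lines$start_day), ]
  rownames(therapy_lines) <- NULL

  hasev <- !is.na(ev_day)
  progression_events <- data.frame(
    patient_id = pid[hasev], day = ev_day[hasev],
    event_type = ev_type[hasev], stringsAsFactors = FALSE)

  biopsies <- data.frame(
    sample_id = sid, patient_id = pid, collection_day = collection,
    tissue_site = sample(TISSUE_SITES, n, replace = TRUE,
                         prob = c(0.45, 0.25, 0.1, 0.2)),
    pdl1_ihc_class = ifelse(pdl1_obs, pdl1_true, NA_character_),
    expression_column = sid, stringsAsFactors = FALSE)

  truth <- list(
    patients = data.frame(patient_id = pid, sample_id = sid, arm = arms,
                          pdl1_class = pdl1_true, pdl1_observed = pdl1_obs,
                          stage = stage, stringsAsFactors = FALSE),
    expected_label = c(naive = "not_eot",
                       eot_nonresistant = "eot_nonresistant",
                       primary = "primary", acquired = "acquired")[arms],
    seed = cfg$seed)

  list(patients = patients, therapy_lines = therapy_lines,
       progression_events = progression_events, biopsies = biopsies,
       truth = truth)
}

#' Generate bulk expression, CD274 coupling and the single-cell compartment
#'
#' Bulk counts are negative binomial around a log-normal gene baseline with
#' planted log2 module effects by arm; two correlated prognostic
#' co-expression modules (latent factor + gene noise) drive survival later;
#' CD274 is lognormal-Poisson around its PD-L1-class mean so the generating
#' class thresholds are well defined on the log2-CPM scale.
#'
#' @param cfg a [synth_config].
#' @param sim output of [generate_cohort] (its `truth` is extended).
#' @return `sim` extended with `counts` (gene x biopsy), `sc` (cell-level
#'   `counts` + `meta`), `signatures` (named gene lists incl. random decoy
#'   sets), and truth entries for modules, prognostic factors and CD274
#'   thresholds.
#' @export
generate_expression <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  uni <- .gene_universe(cfg)
  genes <- uni$genes
  G <- length(genes)
  n <- nrow(sim$truth$patients)
  arms <- sim$truth$patients$arm

  baseline <- 2^stats::rnorm(G, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  names(baseline) <- genes
  # planted module genes are detectably expressed by construction: a screen
  # can only ever find genes the assay measures above its noise floor
  named <- c(unlist(uni$modules, use.names = FALSE), uni$favorable,
             uni$unfavorable)
  baseline[named] <- 2^stats::rnorm(length(named), 6.5, 0.8)
  libfac <- exp(stats::rnorm(n, 0, cfg$lib_log_sd))

  eff <- matrix(0, G, n, dimnames = list(genes, sim$truth$patients$sample_id))
  for (mod in names(cfg$module_effects)) {
    for (arm in names(cfg$module_effects[[mod]])) {
      idx <- arms == arm
      eff[uni$modules[[mod]], idx] <-
        eff[uni$modules[[mod]], idx] + cfg$module_effects[[mod]][[arm]]
    }
  }
  # prognostic co-expression modules: latent factor per patient + gene noise
  mf <- stats::rnorm(n, 0, cfg$prognostic_module_sd)
  mu <- stats::rnorm(n, 0, cfg$prognostic_module_sd)
  for (g in uni$favorable)
    eff[g, ] <- eff[g, ] + mf + stats::rnorm(n, 0, cfg$prognostic_noise_sd)
  for (g in uni$unfavorable)
    eff[g, ] <- eff[g, ] + mu + stats::rnorm(n, 0, cfg$prognostic_noise_sd)

  mu_mat <- baseline * 2^eff
  mu_mat <- sweep(mu_mat, 2, libfac, "*")
  counts <- matrix(stats::rnbinom(G * n, mu = mu_mat,
                                  size = 1 / cfg$nb_dispersion),
                   G, n, dimnames = dimnames(eff))
  storage.mode(counts) <- "integer"

  # CD274 coupled to PD-L1 class (lognormal-Poisson; Poisson noise on the
  # log2 scale is negligible at this depth, so cd274_sd is the class sd)
  cls <- sim$truth$patients$pdl1_class
  shift <- cfg$cd274_class_shifts[cls]
  cd274_mu <- cfg$cd274_base_count *
    2^(shift + stats::rnorm(n, 0, cfg$cd274_sd)) * libfac
  counts["CD274", ] <- stats::rpois(n, cd274_mu)

  # generating class means / Bayes boundaries on the log2-CPM scale
  exp_lib <- sum(baseline)
  class_means <- log2(cfg$cd274_base_count *
                        2^cfg$cd274_class_shifts / exp_lib * 1e6)
  thresholds <- c(ge1 = mean(class_means[c("lt1", "r1_49")]),
                  ge50 = mean(class_means[c("r1_49", "ge50")]))

  # single-cell compartment with planted cell-type enrichment
  sc_pat <- sprintf("SCP%02d", seq_len(cfg$n_sc_patients))
  enrich <- matrix(0, G, length(SC_CELL_TYPES),
                   dimnames = list(genes, SC_CELL_TYPES))
  enrich[uni$favorable, c("DC", "macrophage", "monocyte")] <- 2
  enrich[uni$unfavorable, c("ciliated", "tumor")] <- 2
  enrich[uni$modules$b_cell, "B_cell"] <- 2
  enrich[uni$modules$ifng, "T_cell"] <- 1.5
  cells <- list(); meta <- list()
  ci <- 0
  for (p in sc_pat) for (ct in SC_CELL_TYPES) {
    nc <- sample(cfg$sc_cells_range[1]:cfg$sc_cells_range[2], 1)
    cmu <- baseline / 100 * 2^enrich[, ct]
    blk <- matrix(stats::rnbinom(G * nc, mu = cmu,
                                 size = 1 / cfg$nb_dispersion), G, nc)
    ids <- sprintf("C%05d", ci + seq_len(nc)); ci <- ci + nc
    colnames(blk) <- ids
    cells[[length(cells) + 1]] <- blk
    meta[[length(meta) + 1]] <- data.frame(cell_id = ids, patient_id = p,
                                           cell_type = ct,
                                           stringsAsFactors = FALSE)
  }
  sc_counts <- do.call(cbind, cells)
  rownames(sc_counts) <- genes
  storage.mode(sc_counts) <- "integer"
  sc_meta <- do.call(rbind, meta)

  # planted module signatures plus size-matched random decoy sets
  signatures <- c(uni$modules,
                  list(favorable_prognostic = uni$favorable,
                       unfavorable_prognostic = uni$unfavorable))
  for (k in 1:10)
    signatures[[sprintf("RANDOM%02d", k)]] <- sample(genes, 20)

  sim$counts <- counts
  sim$sc <- list(counts = sc_counts, meta = sc_meta)
  sim$signatures <- signatures
  sim$truth$modules <- uni$modules
  sim$truth$favorable <- uni$favorable
  sim$truth$unfavorable <- uni$unfavorable
  sim$truth$prognostic_factors <- data.frame(
    patient_id = sim$truth$patients$patient_id, favorable = mf,
    unfavorable = mu, stringsAsFactors = FALSE)
  sim$truth$cd274_class_log2cpm <- class_means
  sim$truth$cd274_thresholds <- thresholds
  sim$truth$baseline <- baseline
  sim$truth$lib_factors <- stats::setNames(libfac,
                                           sim$truth$patients$sample_id)
  sim
}

#' Generate survival coupled to the planted prognostic modules
#'
#' Event times are exponential with hazard
#' `h0 * exp(-g * favorable + g * unfavorable + beta_stage * stageIV)`
#' where the module coefficients `g` are scaled so the *marginal* per-gene
#' log hazard ratio is the configured `prognostic_log_hr`. Administrative
#' censoring at `horizon` days. Death days are merged into the patient and
#' event tables; deaths of eot_nonresistant patients are deferred past their
#' resistance window so the planted labels stay valid (count in
#' `truth$n_death_deferred`).
#'
#' @param cfg a [synth_config].
#' @param sim output of [generate_expression].
#' @return `sim` with updated `patients`, `progression_events`, and truth
#'   entries `lp` and `n_death_deferred`; runs a phenotyping self-audit into
#'   `truth$audit_agreement`.
#' @export
generate_survival <- function(cfg, sim) {
  set.seed(cfg$seed + 2L)
  if (cfg$horizon <= 0) stop("degenerate config: horizon must be positive")
  tp <- sim$truth$patients
  pf <- sim$truth$prognostic_factors
  att <- cfg$prognostic_module_sd^2 /
    (cfg$prognostic_module_sd^2 + cfg$prognostic_noise_sd^2)
  gam <- cfg$prognostic_log_hr / att
  lp <- -gam * pf$favorable + gam * pf$unfavorable +
    cfg$beta_stage * (tp$stage == "IV")
  haz <- cfg$h0 * exp(lp)
  if (any(!is.finite(haz))) stop("hazard overflow; check config scales")
  tt <- stats::rexp(nrow(tp), rate = haz)

  lines1 <- sim$therapy_lines[sim$therapy_lines$line_number == 1L, ]
  start <- lines1$start_day[match(tp$patient_id, lines1$patient_id)]
  coll <- sim$biopsies$collection_day[match(tp$sample_id,
                                            sim$biopsies$sample_id)]
  dead <- tt <= cfg$horizon
  # deaths inside the 14-day blanking window would make rwPFS exceed OS
  # (the death could neither count as an event nor move the censor bound);
  # valid real-world timelines start the clock after that window
  death_day <- ifelse(dead,
                      start + pmax(RWPFS_BLANKING_DAYS, round(tt)),
                      NA_integer_)

  # keep planted eot_nonresistant labels valid: death is itself a
  # progressive-disease event, so defer it past the resistance window
  w <- phenotype_config()$resistance_window_days
  min_death <- coll + w + cfg$margin_days + 1L
  defer <- dead & tp$arm == "eot_nonresistant" & death_day < min_death
  death_day[defer] <- min_death[defer]

  followup <- ifelse(dead, death_day, start + cfg$horizon)
  followup <- pmax(followup, sim$patients$last_followup_day - 30L)

  idx <- match(tp$patient_id, sim$patients$patient_id)
  sim$patients$death_day[idx] <- as.integer(death_day)
  sim$patients$last_followup_day[idx] <- as.integer(followup)

  dd <- !is.na(death_day)
  sim$progression_events <- rbind(
    sim$progression_events,
    data.frame(patient_id = tp$patient_id[dd],
               day = as.integer(death_day[dd]), event_type = "death",
               stringsAsFactors = FALSE))
  rownames(sim$progression_events) <- NULL

  sim$truth$lp <- lp
  sim$truth$n_death_deferred <- sum(defer)

  lab <- phenotype_cohort(sim$biopsies, sim$therapy_lines,
                          sim$progression_events, sim$patients)
  agree <- mean(lab$label[match(tp$sample_id, lab$sample_id)] ==
                  sim$truth$expected_label)
  if (agree < 1)
    warning("self-audit: phenotyping agrees with planted labels on only ",
            round(100 * agree, 1), "% of samples")
  sim$truth$audit_agreement <- agree
  sim
}

#' Generate a complete synthetic cohort (timelines, expression, survival)
#' @param cfg a [synth_config].
#' @return list with clinical tables, `counts`, `sc`, `signatures`, `truth`.
#' @export
generate_rwe_cohort <- function(cfg = synth_config()) {
  sim <- generate_cohort(cfg)
  sim <- generate_expression(cfg, sim)
  generate_survival(cfg, sim)
}

#' Random (unconstrained) timelines for oracle-equivalence fuzzing
#'
#' Unlike [generate_cohort], dates here are sampled freely (subject only to
#' hard validity: end >= start, death/follow-up >= start), so endpoint
#' derivations can be compared against a literal brute-force oracle on
#' boundary-rich inputs.
#'
#' @param n number of timelines.
#' @param seed RNG seed.
#' @return list of timelines; each has `start_day`, `end_day` (may be NA),
#'   `next_start` (may be NA), `death_day` (may be NA),
#'   `last_followup_day`, and `events` (data.frame day, event_type).
#' @export
fuzz_timelines <- function(n = 1000, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    start <- sample(0:100, 1)
    end <- if (stats::runif(1) < 0.7) start + sample(0:300, 1) else NA
    nxt <- if (stats::runif(1) < 0.5)
      max(start, if (is.na(end)) start else end) + sample(-20:150, 1)
    else NA
    if (!is.na(nxt) && nxt < start) nxt <- start + 1
    ne <- sample(0:4, 1)
    events <- data.frame(
      day = start + sample(-10:400, ne, replace = TRUE),
      event_type = sample(EVENT_TYPES, ne, replace = TRUE),
      stringsAsFactors = FALSE)
    death <- if (stats::runif(1) < 0.5) start + sample(0:500, 1) else NA
    followup <- start + sample(0:600, 1)
    list(start_day = start, end_day = end, next_start = nxt,
         death_day = death, last_followup_day = followup, events = events)
  })
}
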