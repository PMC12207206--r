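# Clinical table IO, date arithmetic, and cohort criteria.

make_fixture_tables <- function() {
  list(
    patients = data.frame(
      patient_id = c("P1", "P2", "P3"),
      stage = c("IV", "III", "IV"),
      histology = c("nonsquamous", "nonsquamous", "squamous"),
      diagnosis_year = c(2018L, 2019L, 2017L),
      age_known = c(TRUE, TRUE, FALSE),
      pdl1_ihc_class = c("ge50", NA, "lt1"),
      kras_mut = c(TRUE, FALSE, FALSE),
      death_day = c(400L, NA, 900L),
      last_followup_day = c(380L, 700L, 900L),
      stringsAsFactors = FALSE),
    therapy_lines = rbind(mk_line(10, 200, "P1"),
                          mk_line(0, NA, "P2"),
                          mk_line(5, 300, "P3")),
    progression_events = mk_events(c(150, 420), c("progression", "death"),
                                   "P1"),
    biopsies = rbind(mk_biopsy(190, "P1", "S1"), mk_biopsy(80, "P2", "S2"),
                     mk_biopsy(310, "P3", "S3")),
    variants = data.frame(
      patient_id = c("P1", "P2", "P3"),
      gene = c("KRAS", "EGFR", "KEAP1"),
      variant_class = c("snv_indel", "snv_indel", "snv_indel"),
      pathogenicity = c("pathogenic", "pathogenic", "vus"),
      stringsAsFactors = FALSE))
}

test_that("ISO dates convert to days from a configurable epoch", {
  expect_identical(days_from_epoch("2020-03-01", "2020-01-01"), 60L)
  expect_identical(days_from_epoch("2015-01-01"), 0L)
  expect_identical(days_to_iso(60L, "2020-01-01"), "2020-03-01")
  expect_true(is.na(days_from_epoch("not-a-date")))
})

test_that("clinical tables round-trip byte-identically through write/read", {
  tabs <- make_fixture_tables()
  d1 <- file.path(tempdir(), "rt1"); d2 <- file.path(tempdir(), "rt2")
  write_clinical_tables(tabs, d1)
  rt <- read_clinical_tables(d1)
  expect_equal(rt$patients, tabs$patients)
  expect_equal(rt$therapy_lines, tabs$therapy_lines)
  expect_equal(rt$biopsies, tabs$biopsies)
  expect_equal(rt$variants, tabs$variants)
  expect_equal(nrow(rt$parse_report), 0)
  write_clinical_tables(rt, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = f)
})

test_that("invariant-violating and unparseable rows are rejected with reasons", {
  d <- file.path(tempdir(), "badrows")
  tabs <- make_fixture_tables()
  write_clinical_tables(tabs, d)
  lines <- readLines(file.path(d, "therapy_lines.csv"))
  lines <- c(lines, "P9,1,ici,2016-05-01,2016-01-01",   # ends before start
             "P8,1,ici,garbage,")                       # unparseable date
  writeLines(lines, file.path(d, "therapy_lines.csv"))
  rt <- read_clinical_tables(d)
  expect_equal(nrow(rt$therapy_lines), 3)
  expect_setequal(rt$parse_report$reason,
                  c("end_day before start_day",
                    "missing/unparseable start_date"))
})

test_that("a missing mandatory column is a hard error naming the column", {
  d <- file.path(tempdir(), "badcol")
  write_clinical_tables(make_fixture_tables(), d)
  p <- utils::read.csv(file.path(d, "patients.csv"))
  p$stage <- NULL
  utils::write.csv(p, file.path(d, "patients.csv"), row.names = FALSE)
  expect_error(read_clinical_tables(d), "stage")
})

test_that("count matrices and GMT files round-trip", {
  m <- matrix(0:11, 3, 4, dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  storage.mode(m) <- "integer"
  f <- tempfile(fileext = ".tsv")
  write_count_matrix(m, f)
  expect_identical(read_count_matrix(f), m)
  sets <- list(one = c("A", "B"), two = c("C"))
  g <- tempfile(fileext = ".gmt")
  write_gmt(sets, g)
  expect_identical(read_gmt(g), sets)
})

test_that("pathogenicity filter counts only pathogenic short variants, KEAP1 excepted", {
  v <- data.frame(
    patient_id = c("P1", "P1", "P2", "P3"),
    gene = c("TP53", "KEAP1", "STK11", "ALK"),
    variant_class = c("snv_indel", "snv_indel", "snv_indel", "fusion"),
    pathogenicity = c("vus", "vus", "pathogenic", NA),
    stringsAsFactors = FALSE)
  alt <- derive_gene_alteration_status(v)
  expect_false(any(alt$gene == "TP53"))       # VUS short variant: not altered
  expect_true(any(alt$gene == "KEAP1"))       # all KEAP1 variants retained
  expect_true(any(alt$gene == "STK11"))       # pathogenic short variant
  expect_true(any(alt$gene == "ALK"))         # fusions always count
  vbad <- v; vbad$pathogenicity[1] <- "mystery"
  expect_warning(derive_gene_alteration_status(vbad), "unknown pathogenicity")
})

test_that("cohort criteria exclude actionable drivers and fusions, with first-rule attribution", {
  pats <- make_fixture_tables()$patients
  pats$age_known <- TRUE
  vars <- data.frame(
    patient_id = c("P2", "P3"),
    gene = c("EGFR", "ALK"),
    variant_class = c("snv_indel", "fusion"),
    pathogenicity = c("pathogenic", NA),
    stringsAsFactors = FALSE)
  cc <- apply_cohort_criteria(pats, vars,
                              cohort_config(allowed_histology =
                                              c("nonsquamous", "squamous")))
  expect_setequal(cc$included, "P1")
  pp <- cc$per_patient
  expect_equal(pp$excluded_by[pp$patient_id == "P2"], "driver")
  expect_equal(pp$excluded_by[pp$patient_id == "P3"], "fusion")
  # patient with no exclusions is included
  expect_true(pp$included[pp$patient_id == "P1"])
})

test_that("cohort filtering is idempotent, monotone, and counts sum to exclusions", {
  sim <- generate_cohort(synth_config(n_patients = 60, seed = 9))
  pats <- sim$patients
  pats$histology[1:5] <- "squamous"
  pats$diagnosis_year[6:8] <- 2014L
  cfg <- cohort_config()
  cc1 <- apply_cohort_criteria(pats, NULL, cfg)
  cc2 <- apply_cohort_criteria(pats[pats$patient_id %in% cc1$included, ],
                               NULL, cfg)
  expect_setequal(cc2$included, cc1$included)                  # idempotent
  expect_equal(sum(cc1$exclusion_counts),
               nrow(pats) - length(cc1$included))              # counts sum
  # adding a rule can only shrink the included set
  cfg2 <- cohort_config(min_diagnosis_year = 2018)
  cc3 <- apply_cohort_criteria(pats, NULL, cfg2)
  expect_true(all(cc3$included %in% cc1$included))
})
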