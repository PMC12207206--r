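# Clinical table IO: delimited files with ISO-8601 dates on disk, integer
# days from a configurable epoch in memory.

STAGES <- c("III", "IV")
HISTOLOGIES <- c("nonsquamous", "squamous")
REGIMEN_CLASSES <- c("ici", "ici_chemo", "platinum_chemo", "other")
EVENT_TYPES <- c("progression", "metastasis", "death")
TISSUE_SITES <- c("lung", "lymph_node", "liver", "other")
PDL1_CLASSES <- c("lt1", "r1_49", "ge50")
VARIANT_CLASSES <- c("snv_indel", "cnv", "fusion")
PATHOGENICITY <- c("pathogenic", "likely_pathogenic", "vus", "benign",
                   "likely_benign")

#' Convert ISO-8601 date strings to integer days from an epoch
#'
#' @param dates character vector of `YYYY-MM-DD` strings (NA/empty allowed).
#' @param epoch single ISO-8601 date string; day 0.
#' @return integer vector; NA where the input is missing or unparseable.
#' @export
days_from_epoch <- function(dates, epoch = "2015-01-01") {
  e <- as.Date(epoch)
  if (is.na(e)) stop("invalid epoch date: ", epoch)
  dates[!is.na(dates) & dates == ""] <- NA
  d <- as.Date(dates, format = "%Y-%m-%d")
  as.integer(d - e)
}

#' Convert integer days from an epoch back to ISO-8601 strings
#' @inheritParams days_from_epoch
#' @param days integer vector of days since `epoch`.
#' @export
days_to_iso <- function(days, epoch = "2015-01-01") {
  out <- rep(NA_character_, length(days))
  ok <- !is.na(days)
  out[ok] <- format(as.Date(epoch) + days[ok], "%Y-%m-%d")
  out
}

.require_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop("file '", file, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
}

.reject <- function(report, file, row, reason) {
  rbind(report, data.frame(file = file, row = row, reason = reason,
                           stringsAsFactors = FALSE))
}

.parse_logical <- function(x) {
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

# Read one raw csv as character columns so date parsing is under our control.
.read_raw <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = c("NA", ""))
}

#' Read the clinical tables of a cohort
#'
#' Reads `patients.csv`, `therapy_lines.csv`, `progression_events.csv`,
#' `biopsies.csv` and (if present) `variants.csv` from a directory. Dates are
#' ISO-8601 in the files and converted to integer days from `epoch`. Rows
#' violating a type invariant (e.g. a therapy line ending before it starts,
#' an unparseable date) are dropped and listed in the parse report; a missing
#' mandatory column is a hard error naming the column.
#'
#' @param dir directory containing the csv files.
#' @param epoch ISO-8601 date taken as day 0.
#' @return list with elements `patients`, `therapy_lines`,
#'   `progression_events`, `biopsies`, `variants` (NULL when absent) and
#'   `parse_report` (data.frame of dropped rows with reasons).
#' @export
read_clinical_tables <- function(dir, epoch = "2015-01-01") {
  report <- data.frame(file = character(), row = integer(),
                       reason = character(), stringsAsFactors = FALSE)

  ## patients ----------------------------------------------------------------
  pf <- file.path(dir, "patients.csv")
  raw <- .read_raw(pf)
  .require_columns(raw, c("patient_id", "stage", "histology",
                          "diagnosis_year", "age_known", "pdl1_ihc_class",
                          "kras_mut", "death_date", "last_followup_date"),
                   "patients.csv")
  pat <- data.frame(
    patient_id = raw$patient_id,
    stage = raw$stage,
    histology = raw$histology,
    diagnosis_year = suppressWarnings(as.integer(raw$diagnosis_year)),
    age_known = .parse_logical(raw$age_known),
    pdl1_ihc_class = raw$pdl1_ihc_class,
    kras_mut = .parse_logical(raw$kras_mut),
    death_day = days_from_epoch(raw$death_date, epoch),
    last_followup_day = days_from_epoch(raw$last_followup_date, epoch),
    stringsAsFactors = FALSE)
  bad <- duplicated(pat$patient_id)
  for (i in which(bad)) report <- .reject(report, "patients.csv", i,
                                          "duplicate patient_id")
  bad <- bad | !pat$stage %in% STAGES
  bad2 <- !pat$stage %in% STAGES
  for (i in which(bad2)) report <- .reject(report, "patients.csv", i,
                                           "unknown stage")
  bad3 <- !is.na(raw$last_followup_date) & is.na(pat$last_followup_day)
  for (i in which(bad3)) report <- .reject(report, "patients.csv", i,
                                           "unparseable last_followup_date")
  bad4 <- !is.na(raw$pdl1_ihc_class) & !raw$pdl1_ihc_class %in% PDL1_CLASSES
  for (i in which(bad4)) report <- .reject(report, "patients.csv", i,
                                           "unknown pdl1_ihc_class")
  pat <- pat[!(bad | bad3 | bad4), , drop = FALSE]
  rownames(pat) <- NULL

  ## therapy lines -----------------------------------------------------------
  tf <- file.path(dir, "therapy_lines.csv")
  raw <- .read_raw(tf)
  .require_columns(raw, c("patient_id", "line_number", "regimen_class",
                          "start_date", "end_date"), "therapy_lines.csv")
  lin <- data.frame(
    patient_id = raw$patient_id,
    line_number = suppressWarnings(as.integer(raw$line_number)),
    regimen_class = raw$regimen_class,
    start_day = days_from_epoch(raw$start_date, epoch),
    end_day = days_from_epoch(raw$end_date, epoch),
    stringsAsFactors = FALSE)
  bad <- is.na(lin$start_day)
  for (i in which(bad)) report <- .reject(report, "therapy_lines.csv", i,
                                          "missing/unparseable start_date")
  b2 <- !is.na(lin$end_day) & lin$end_day < lin$start_day
  for (i in which(b2)) report <- .reject(report, "therapy_lines.csv", i,
                                         "end_day before start_day")
  b3 <- !lin$regimen_class %in% REGIMEN_CLASSES
  for (i in which(b3)) report <- .reject(report, "therapy_lines.csv", i,
                                         "unknown regimen_class")
  lin <- lin[!(bad | b2 | b3), , drop = FALSE]
  lin <- lin[order(lin$patient_id, lin$start_day, lin$line_number), ,
             drop = FALSE]
  rownames(lin) <- NULL

  ## progression events ------------------------------------------------------
  ef <- file.path(dir, "progression_events.csv")
  raw <- .read_raw(ef)
  .require_columns(raw, c("patient_id", "event_date", "event_type"),
                   "progression_events.csv")
  evt <- data.frame(
    patient_id = raw$patient_id,
    day = days_from_epoch(raw$event_date, epoch),
    event_type = raw$event_type,
    stringsAsFactors = FALSE)
  bad <- is.na(evt$day)
  for (i in which(bad)) report <- .reject(report, "progression_events.csv", i,
                                          "missing/unparseable event_date")
  b2 <- !evt$event_type %in% EVENT_TYPES
  for (i in which(b2)) report <- .reject(report, "progression_events.csv", i,
                                         "unknown event_type")
  evt <- evt[!(bad | b2), , drop = FALSE]
  rownames(evt) <- NULL

  ## biopsies ----------------------------------------------------------------
  bf <- file.path(dir, "biopsies.csv")
  raw <- .read_raw(bf)
  .require_columns(raw, c("sample_id", "patient_id", "collection_date",
                          "tissue_site", "pdl1_ihc_class",
                          "expression_column"), "biopsies.csv")
  bio <- data.frame(
    sample_id = raw$sample_id,
    patient_id = raw$patient_id,
    collection_day = days_from_epoch(raw$collection_date, epoch),
    tissue_site = raw$tissue_site,
    pdl1_ihc_class = raw$pdl1_ihc_class,
    expression_column = raw$expression_column,
    stringsAsFactors = FALSE)
  bad <- duplicated(bio$sample_id)
  for (i in which(bad)) report <- .reject(report, "biopsies.csv", i,
                                          "duplicate sample_id")
  b2 <- is.na(bio$collection_day)
  for (i in which(b2)) report <- .reject(report, "biopsies.csv", i,
                                         "missing/unparseable collection_date")
  b3 <- !bio$tissue_site %in% TISSUE_SITES
  for (i in which(b3)) report <- .reject(report, "biopsies.csv", i,
                                         "unknown tissue_site")
  bio <- bio[!(bad | b2 | b3), , drop = FALSE]
  rownames(bio) <- NULL

  ## variants (optional file) ------------------------------------------------
  vf <- file.path(dir, "variants.csv")
  var <- NULL
  if (file.exists(vf)) {
    raw <- .read_raw(vf)
    .require_columns(raw, c("patient_id", "gene", "variant_class",
                            "pathogenicity"), "variants.csv")
    var <- data.frame(patient_id = raw$patient_id, gene = raw$gene,
                      variant_class = raw$variant_class,
                      pathogenicity = raw$pathogenicity,
                      stringsAsFactors = FALSE)
    bad <- !var$variant_class %in% VARIANT_CLASSES
    for (i in which(bad)) report <- .reject(report, "variants.csv", i,
                                            "unknown variant_class")
    b2 <- var$variant_class == "snv_indel" & is.na(var$pathogenicity)
    for (i in which(b2)) report <- .reject(report, "variants.csv", i,
                                           "snv_indel without pathogenicity")
    var <- var[!(bad | b2), , drop = FALSE]
    rownames(var) <- NULL
  }

  list(patients = pat, therapy_lines = lin, progression_events = evt,
       biopsies = bio, variants = var, parse_report = report)
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write clinical tables back to csv (inverse of [read_clinical_tables])
#'
#' Integer day columns are converted back to ISO-8601 dates. Writing then
#' re-reading is the identity on valid tables.
#' @param tables list as returned by [read_clinical_tables].
#' @param dir output directory (created if needed).
#' @param epoch ISO-8601 date taken as day 0.
#' @export
write_clinical_tables <- function(tables, dir, epoch = "2015-01-01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- tables$patients
  .write_csv(data.frame(
    patient_id = p$patient_id, stage = p$stage, histology = p$histology,
    diagnosis_year = p$diagnosis_year, age_known = p$age_known,
    pdl1_ihc_class = p$pdl1_ihc_class, kras_mut = p$kras_mut,
    death_date = days_to_iso(p$death_day, epoch),
    last_followup_date = days_to_iso(p$last_followup_day, epoch)),
    file.path(dir, "patients.csv"))
  l <- tables$therapy_lines
  .write_csv(data.frame(
    patient_id = l$patient_id, line_number = l$line_number,
    regimen_class = l$regimen_class,
    start_date = days_to_iso(l$start_day, epoch),
    end_date = days_to_iso(l$end_day, epoch)),
    file.path(dir, "therapy_lines.csv"))
  e <- tables$progression_events
  .write_csv(data.frame(
    patient_id = e$patient_id, event_date = days_to_iso(e$day, epoch),
    event_type = e$event_type),
    file.path(dir, "progression_events.csv"))
  b <- tables$biopsies
  .write_csv(data.frame(
    sample_id = b$sample_id, patient_id = b$patient_id,
    collection_date = days_to_iso(b$collection_day, epoch),
    tissue_site = b$tissue_site, pdl1_ihc_class = b$pdl1_ihc_class,
    expression_column = b$expression_column),
    file.path(dir, "biopsies.csv"))
  if (!is.null(tables$variants))
    .write_csv(tables$variants, file.path(dir, "variants.csv"))
  invisible(dir)
}

#' Read a gene-by-sample count matrix
#'
#' Supports a plain TSV (first column gene symbols, header row of sample ids)
#' or MatrixMarket (`.mtx`, with companion `genes.tsv` and `samples.tsv`
#' files next to it).
#' @param path path to `.tsv` or `.mtx` file.
#' @return integer matrix, genes in rows.
#' @export
read_count_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    d <- dirname(path)
    genes <- utils::read.table(file.path(d, "genes.tsv"),
                               stringsAsFactors = FALSE)[[1]]
    samples <- utils::read.table(file.path(d, "samples.tsv"),
                                 stringsAsFactors = FALSE)[[1]]
    dimnames(m) <- list(genes, samples)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("count matrix has negative entries")
  if (anyDuplicated(rownames(m))) stop("duplicate gene symbols in matrix")
  m
}

#' @rdname read_count_matrix
#' @param counts gene-by-sample matrix.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then gene symbols, all
#' tab-separated. Duplicate genes within a signature are removed.
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(ln, 1, 40))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("empty signature in GMT: ", f[1])
    out[[f[1]]] <- genes
  }
  out
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
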