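# Cohort inclusion/exclusion and variant-pathogenicity filtering.

#' Cohort inclusion/exclusion configuration
#'
#' Defaults reflect a real-world advanced-NSCLC ICI cohort: diagnosis after
#' 2015, stage III/IV, nonsquamous histology, known age, and exclusion of
#' patients with actionable driver alterations (EGFR/BRAF/MET) or pathogenic
#' fusions (ALK/ROS1/NTRK1/NTRK2).
#'
#' @param min_diagnosis_year patients must be diagnosed strictly after this
#'   year minus one (i.e. `diagnosis_year > min_diagnosis_year` is *not*
#'   required; inclusion is `diagnosis_year >= min_diagnosis_year`).
#' @param allowed_stages,allowed_histology permitted values.
#' @param require_age_known drop patients with unknown age.
#' @param excluded_driver_genes genes whose non-fusion alterations exclude a
#'   patient ("actionable" is operationalized as any pathogenic or likely
#'   pathogenic record in this list).
#' @param excluded_fusion_genes genes whose fusions exclude a patient.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(min_diagnosis_year = 2016,
                          allowed_stages = c("III", "IV"),
                          allowed_histology = "nonsquamous",
                          require_age_known = TRUE,
                          excluded_driver_genes = c("EGFR", "BRAF", "MET"),
                          excluded_fusion_genes = c("ALK", "ROS1", "NTRK1",
                                                    "NTRK2")) {
  if (length(excluded_driver_genes) == 0 || length(excluded_fusion_genes) == 0)
    stop("exclusion gene lists must be non-empty")
  structure(list(min_diagnosis_year = min_diagnosis_year,
                 allowed_stages = allowed_stages,
                 allowed_histology = allowed_histology,
                 require_age_known = require_age_known,
                 excluded_driver_genes = excluded_driver_genes,
                 excluded_fusion_genes = excluded_fusion_genes),
            class = "cohort_config")
}

#' Derive per-patient gene alteration status from variant calls
#'
#' A short variant (snv_indel) counts as an alteration only when annotated
#' pathogenic or likely pathogenic, except in KEAP1, where every short
#' variant is retained (the gene is poorly annotated). Copy-number and fusion
#' records always count. Records with an unknown pathogenicity value are
#' skipped with a warning.
#'
#' @param variants data.frame with columns `patient_id`, `gene`,
#'   `variant_class`, `pathogenicity`.
#' @return data.frame of altered `(patient_id, gene, variant_class)` rows
#'   (deduplicated), with attribute `n_skipped`.
#' @export
derive_gene_alteration_status <- function(variants) {
  if (is.null(variants) || nrow(variants) == 0) {
    out <- data.frame(patient_id = character(), gene = character(),
                      variant_class = character(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  known_path <- is.na(variants$pathogenicity) |
    variants$pathogenicity %in% PATHOGENICITY
  unknown <- variants$variant_class == "snv_indel" & !known_path
  if (any(unknown))
    warning(sum(unknown), " variant record(s) with unknown pathogenicity ",
            "value skipped")
  v <- variants[!unknown, , drop = FALSE]
  counts <- v$variant_class %in% c("cnv", "fusion") |
    (v$variant_class == "snv_indel" &
       (v$gene == "KEAP1" |
          v$pathogenicity %in% c("pathogenic", "likely_pathogenic")))
  out <- unique(v[counts, c("patient_id", "gene", "variant_class")])
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(unknown)
  out
}

#' Apply cohort inclusion/exclusion criteria
#'
#' A patient is included iff it passes every rule. Exclusions are attributed
#' to the first failing rule in the documented order: diagnosis year, stage,
#' histology, age known, driver mutation, fusion; counts therefore sum to
#' (input patients - included patients).
#'
#' @param patients patient table (see [read_clinical_tables]).
#' @param variants variant table, or NULL when genomic exclusions are not
#'   applied.
#' @param config a [cohort_config].
#' @return list with `included` (character vector of patient ids),
#'   `exclusion_counts` (named integer vector per rule) and `per_patient`
#'   (data.frame `patient_id`, `included`, `excluded_by`).
#' @export
apply_cohort_criteria <- function(patients, variants = NULL,
                                  config = cohort_config()) {
  alt <- derive_gene_alteration_status(variants)
  driver_pat <- unique(alt$patient_id[alt$variant_class != "fusion" &
                                        alt$gene %in%
                                        config$excluded_driver_genes])
  fusion_pat <- unique(alt$patient_id[alt$variant_class == "fusion" &
                                        alt$gene %in%
                                        config$excluded_fusion_genes])

  rules <- list(
    year = !is.na(patients$diagnosis_year) &
      patients$diagnosis_year >= config$min_diagnosis_year,
    stage = patients$stage %in% config$allowed_stages,
    histology = patients$histology %in% config$allowed_histology,
    age_known = if (config$require_age_known) patients$age_known
                else rep(TRUE, nrow(patients)),
    driver = !patients$patient_id %in% driver_pat,
    fusion = !patients$patient_id %in% fusion_pat)

  excluded_by <- rep(NA_character_, nrow(patients))
  for (rn in names(rules)) {
    fail <- !rules[[rn]] & is.na(excluded_by)
    excluded_by[fail] <- rn
  }
  per_patient <- data.frame(patient_id = patients$patient_id,
                            included = is.na(excluded_by),
                            excluded_by = excluded_by,
                            stringsAsFactors = FALSE)
  counts <- vapply(names(rules), function(rn)
    sum(excluded_by == rn, na.rm = TRUE), integer(1))
  list(included = patients$patient_id[is.na(excluded_by)],
       exclusion_counts = counts,
       per_patient = per_patient)
}
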