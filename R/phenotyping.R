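# Rule-based phenotyping of post-ICI biopsies.
#
# A biopsy is an end-of-treatment (EOT) sample when collected within a
# +/- 30-day window of the ICI (or ICI + chemo) line's end date, or -- when
# the end date is missing -- at least 60 days after the line's start. An EOT
# sample reflects resistance when the next treatment line starts within 90
# days of the EOT, or a progressive-disease event (progression, new
# metastasis, death) is recorded within 90 days of the sample collection
# date. Note the two clocks deliberately differ (EOT vs. collection day).
# Resistant samples split into primary (ICI duration < 180 days) and
# acquired (duration >= 180 days) resistance.

#' Phenotyping window configuration
#'
#' @param eot_window_days biopsy-to-EOT window (days, closed interval).
#' @param missing_end_min_days minimum days after start when the end date is
#'   missing.
#' @param resistance_window_days window for the next-line / progression
#'   clauses.
#' @param acquired_min_duration_days ICI duration separating primary from
#'   acquired resistance.
#' @return list of class `phenotype_config`.
#' @export
phenotype_config <- function(eot_window_days = 30L,
                             missing_end_min_days = 60L,
                             resistance_window_days = 90L,
                             acquired_min_duration_days = 180L) {
  v <- c(eot_window_days, missing_end_min_days, resistance_window_days,
         acquired_min_duration_days)
  if (any(v <= 0)) stop("all phenotyping windows must be positive")
  structure(list(eot_window_days = as.integer(eot_window_days),
                 missing_end_min_days = as.integer(missing_end_min_days),
                 resistance_window_days = as.integer(resistance_window_days),
                 acquired_min_duration_days =
                   as.integer(acquired_min_duration_days)),
            class = "phenotype_config")
}

#' Is a biopsy an end-of-treatment (EOT) sample?
#' @param sample one-row biopsy record.
#' @param ici_line one-row ICI or ICI+chemo therapy line.
#' @param cfg a [phenotype_config].
#' @return logical.
#' @export
classify_eot <- function(sample, ici_line, cfg = phenotype_config()) {
  if (sample$patient_id != ici_line$patient_id)
    stop("sample and therapy line belong to different patients")
  if (!ici_line$regimen_class %in% c("ici", "ici_chemo"))
    stop("classify_eot requires an ici or ici_chemo line")
  if (!is.na(ici_line$end_day)) {
    abs(sample$collection_day - ici_line$end_day) <= cfg$eot_window_days
  } else {
    sample$collection_day - ici_line$start_day >= cfg$missing_end_min_days
  }
}

#' Does an EOT sample reflect treatment resistance?
#'
#' Resistant iff the next line starts within the resistance window of the
#' EOT (clock: line end day), or a progression/metastasis/death event falls
#' within the resistance window of the sample collection day (clock:
#' collection day). Both windows are closed, lower-bounded at 0.
#'
#' @inheritParams classify_eot
#' @param next_line the subsequent therapy line (one row) or NULL.
#' @param events progression events of the same patient.
#' @return logical.
#' @export
classify_resistance <- function(sample, ici_line, next_line = NULL,
                                events = NULL, cfg = phenotype_config()) {
  w <- cfg$resistance_window_days
  by_next <- FALSE
  if (!is.null(next_line) && nrow(next_line) > 0 && !is.na(ici_line$end_day)) {
    gap <- next_line$start_day[1] - ici_line$end_day
    by_next <- !is.na(gap) && gap >= 0 && gap <= w
  }
  by_event <- FALSE
  if (!is.null(events) && nrow(events) > 0) {
    gaps <- events$day[events$event_type %in% EVENT_TYPES] -
      sample$collection_day
    by_event <- any(gaps >= 0 & gaps <= w)
  }
  by_next || by_event
}

#' Split a resistant sample into primary vs acquired resistance
#' @inheritParams classify_eot
#' @return `"primary"`, `"acquired"`, or `"unclassifiable"` when the line's
#'   end day is missing (duration undefined).
#' @export
classify_primary_acquired <- function(ici_line, cfg = phenotype_config()) {
  if (is.na(ici_line$end_day)) return("unclassifiable")
  dur <- ici_line$end_day - ici_line$start_day
  if (dur < cfg$acquired_min_duration_days) "primary" else "acquired"
}

# Latest ICI/ICI+chemo line starting on or before collection + eot window;
# invented plumbing -- the linkage is not part of the clinical rule set.
.link_ici_line <- function(sample, lines, cfg) {
  cand <- lines[lines$patient_id == sample$patient_id &
                  lines$regimen_class %in% c("ici", "ici_chemo") &
                  lines$start_day <= sample$collection_day +
                  cfg$eot_window_days, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand[which.max(cand$start_day), , drop = FALSE]
}

#' Phenotype every biopsy in a cohort
#'
#' Applies the EOT, resistance and primary/acquired rules to each biopsy,
#' linking each to the latest ICI line starting on or before
#' `collection_day + eot_window_days`. Patient death days, when a patient
#' table is supplied, are merged into the event list as death events.
#'
#' @param biopsies,therapy_lines,progression_events clinical tables.
#' @param patients optional patient table used to merge death days.
#' @param cfg a [phenotype_config].
#' @return data.frame `sample_id`, `patient_id`, `label`, `supporting_rule`,
#'   with attribute `cascade`: named counts at the filter stages (all ->
#'   EOT -> resistance-evaluable -> resistant -> primary/acquired).
#' @export
phenotype_cohort <- function(biopsies, therapy_lines, progression_events,
                             patients = NULL, cfg = phenotype_config()) {
  events <- progression_events
  if (!is.null(patients)) {
    dd <- patients[!is.na(patients$death_day), , drop = FALSE]
    if (nrow(dd) > 0)
      events <- rbind(events,
                      data.frame(patient_id = dd$patient_id,
                                 day = dd$death_day, event_type = "death",
                                 stringsAsFactors = FALSE))
  }
  n <- nrow(biopsies)
  label <- character(n); rule <- character(n)
  eot <- resist <- evaluable <- logical(n)
  for (i in seq_len(n)) {
    s <- biopsies[i, , drop = FALSE]
    line <- .link_ici_line(s, therapy_lines, cfg)
    if (is.null(line)) {
      label[i] <- "not_eot"; rule[i] <- "no_ici_line"
      next
    }
    if (!classify_eot(s, line, cfg)) {
      label[i] <- "not_eot"; rule[i] <- "outside_eot_window"
      next
    }
    eot[i] <- TRUE
    evaluable[i] <- !is.na(line$end_day)
    pl <- therapy_lines[therapy_lines$patient_id == s$patient_id, ,
                        drop = FALSE]
    nxt <- pl[pl$start_day > line$start_day, , drop = FALSE]
    nxt <- if (nrow(nxt) > 0) nxt[which.min(nxt$start_day), , drop = FALSE]
           else NULL
    ev <- events[events$patient_id == s$patient_id, , drop = FALSE]
    if (!classify_resistance(s, line, nxt, ev, cfg)) {
      label[i] <- "eot_nonresistant"; rule[i] <- "no_resistance_trigger"
      next
    }
    resist[i] <- TRUE
    label[i] <- classify_primary_acquired(line, cfg)
    rule[i] <- if (label[i] == "unclassifiable") "missing_end_day"
               else sprintf("ici_duration_%dd", line$end_day - line$start_day)
  }
  out <- data.frame(sample_id = biopsies$sample_id,
                    patient_id = biopsies$patient_id,
                    label = label, supporting_rule = rule,
                    stringsAsFactors = FALSE)
  attr(out, "cascade") <- c(
    all = n, eot = sum(eot), resistance_evaluable = sum(evaluable),
    resistant = sum(resist),
    primary = sum(label == "primary"), acquired = sum(label == "acquired"),
    unclassifiable = sum(label == "unclassifiable"))
  out
}
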