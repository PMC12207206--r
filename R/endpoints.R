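# Real-world survival endpoints derived from therapy-line timelines.
#
# OS runs from the anchor line's start to death, censored at last follow-up.
# rwPFS runs from the anchor line's start to the earliest qualifying
# progression/metastasis/death event; events qualify only when they occur at
# least 14 days after the start (clinical-note progression recorded earlier
# is considered carry-over from the prior line) and strictly before the
# treatment end date, or the next line's start when the end date is missing.
# Patients without a qualifying event are censored at that same bound, or at
# last follow-up when neither bound exists.

RWPFS_BLANKING_DAYS <- 14L

#' Derive real-world overall survival for one patient
#'
#' @param patient one-row patient record (needs `death_day`,
#'   `last_followup_day`).
#' @param line one-row therapy line supplying the anchor `start_day`.
#' @return data.frame row: `patient_id`, `endpoint`, `time_days`, `event`,
#'   `anchor_line`.
#' @export
derive_os <- function(patient, line) {
  start <- line$start_day
  if (is.na(start)) stop("anchor line has no start_day")
  if (!is.na(patient$death_day)) {
    if (patient$death_day < start)
      stop("inconsistent timeline: death before treatment start for ",
           patient$patient_id)
    time <- patient$death_day - start
    event <- TRUE
  } else {
    if (is.na(patient$last_followup_day))
      stop("no death and no follow-up for ", patient$patient_id)
    if (patient$last_followup_day < start)
      stop("inconsistent timeline: last follow-up before treatment start for ",
           patient$patient_id)
    time <- patient$last_followup_day - start
    event <- FALSE
  }
  data.frame(patient_id = patient$patient_id, endpoint = "os",
             time_days = as.integer(time), event = event,
             anchor_line = line$line_number, stringsAsFactors = FALSE)
}

#' Derive real-world progression-free survival for one therapy line
#'
#' The event window is `[start + 14, U)` with `U` the line's end day, or the
#' next line's start day when the end day is missing; the earliest qualifying
#' progression, metastasis or death event in the window is the event.
#' Otherwise the patient is censored at `U`, or at last follow-up when
#' neither bound exists. The patient's death day, when supplied, is merged
#' into the event list regardless of the progression-event table.
#'
#' @param line anchor therapy line (one row).
#' @param next_line the subsequent line (one row) or NULL.
#' @param events progression events for the same patient (columns `day`,
#'   `event_type`).
#' @param death_day optional death day to merge in.
#' @param last_followup_day fallback censoring day when the line has no end
#'   and there is no next line.
#' @return data.frame row as in [derive_os] with `endpoint = "rwpfs"`.
#' @export
derive_rwpfs <- function(line, next_line = NULL, events = NULL,
                         death_day = NA, last_followup_day = NA) {
  start <- line$start_day
  if (is.na(start)) stop("anchor line has no start_day")
  U <- if (!is.na(line$end_day)) line$end_day
       else if (!is.null(next_line) && nrow(next_line) > 0)
         next_line$start_day[1]
       else NA_integer_

  days <- integer(0)
  if (!is.null(events) && nrow(events) > 0)
    days <- events$day[events$event_type %in% EVENT_TYPES]
  if (!is.na(death_day)) days <- c(days, death_day)
  days <- days[days >= start + RWPFS_BLANKING_DAYS]
  if (!is.na(U)) days <- days[days < U]

  if (length(days) > 0) {
    t <- min(days) - start
    ev <- TRUE
  } else if (!is.na(U)) {
    t <- U - start
    ev <- FALSE
  } else {
    if (is.na(last_followup_day))
      stop("rwPFS undefined: no end date, no next line, no follow-up for ",
           line$patient_id)
    t <- last_followup_day - start
    ev <- FALSE
  }
  if (t < 0) stop("inconsistent timeline: negative rwPFS time for ",
                  line$patient_id)
  data.frame(patient_id = line$patient_id, endpoint = "rwpfs",
             time_days = as.integer(t), event = ev,
             anchor_line = line$line_number, stringsAsFactors = FALSE)
}

#' Derive an endpoint for every patient in a cohort
#'
#' Anchors at each patient's first-line treatment (smallest `line_number`,
#' ties broken by earliest start). Patients without any therapy line are
#' skipped and counted in the `skipped` attribute.
#'
#' @param patients,therapy_lines,progression_events clinical tables.
#' @param endpoint `"os"` or `"rwpfs"`.
#' @return data.frame of per-patient outcomes.
#' @export
derive_endpoints <- function(patients, therapy_lines, progression_events,
                             endpoint = c("os", "rwpfs")) {
  endpoint <- match.arg(endpoint)
  out <- vector("list", nrow(patients))
  skipped <- character(0)
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, , drop = FALSE]
    pl <- therapy_lines[therapy_lines$patient_id == p$patient_id, ,
                        drop = FALSE]
    if (nrow(pl) == 0) { skipped <- c(skipped, p$patient_id); next }
    pl <- pl[order(pl$line_number, pl$start_day), , drop = FALSE]
    anchor <- pl[1, , drop = FALSE]
    if (endpoint == "os") {
      out[[i]] <- derive_os(p, anchor)
    } else {
      nxt <- pl[pl$start_day > anchor$start_day, , drop = FALSE]
      nxt <- if (nrow(nxt) > 0) nxt[which.min(nxt$start_day), , drop = FALSE]
             else NULL
      ev <- progression_events[progression_events$patient_id == p$patient_id, ,
                               drop = FALSE]
      out[[i]] <- derive_rwpfs(anchor, nxt, ev, p$death_day,
                               p$last_followup_day)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' Thin wrapper around [survival::survfit] returning the step function and
#' the median survival defined as the smallest time with S(t) <= 0.5
#' (NA when never reached).
#'
#' @param outcomes data.frame with `time_days` and `event` columns.
#' @return list with `time`, `surv`, `n_risk`, `n_event`, `median`.
#' @export
km_estimate <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0)
    stop("km_estimate needs at least one outcome")
  fit <- survival::survfit(
    survival::Surv(outcomes$time_days, outcomes$event) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1]]
         else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med)
}
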