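# Independent oracles and shared fixtures.

# Literal brute-force rwPFS oracle: walk every candidate event day and apply
# the textual rules one clause at a time.
oracle_rwpfs <- function(tl) {
  start <- tl$start_day
  cand <- c()
  for (i in seq_len(nrow(tl$events))) {
    if (tl$events$event_type[i] %in% c("progression", "metastasis", "death"))
      cand <- c(cand, tl$events$day[i])
  }
  if (!is.na(tl$death_day)) cand <- c(cand, tl$death_day)
  qual <- c()
  for (d in cand) {
    ok <- d >= start + 14
    if (!is.na(tl$end_day)) {
      if (d >= tl$end_day) ok <- FALSE
    } else if (!is.na(tl$next_start)) {
      if (d >= tl$next_start) ok <- FALSE
    }
    if (ok) qual <- c(qual, d)
  }
  if (length(qual) > 0)
    return(list(time = min(qual) - start, event = TRUE))
  cens <- if (!is.na(tl$end_day)) tl$end_day
          else if (!is.na(tl$next_start)) tl$next_start
          else tl$last_followup_day
  list(time = cens - start, event = FALSE)
}

oracle_os <- function(tl) {
  if (!is.na(tl$death_day))
    list(time = tl$death_day - tl$start_day, event = TRUE)
  else
    list(time = tl$last_followup_day - tl$start_day, event = FALSE)
}

# run derive_rwpfs on a fuzz timeline
run_rwpfs <- function(tl, patient_id = "PX") {
  line <- data.frame(patient_id = patient_id, line_number = 1L,
                     regimen_class = "ici", start_day = tl$start_day,
                     end_day = if (is.na(tl$end_day)) NA_integer_
                               else tl$end_day)
  nxt <- if (is.na(tl$next_start)) NULL
         else data.frame(patient_id = patient_id, line_number = 2L,
                         regimen_class = "other",
                         start_day = tl$next_start, end_day = NA_integer_)
  derive_rwpfs(line, nxt, tl$events, tl$death_day, tl$last_followup_day)
}

# one-row record builders for rule tests
mk_line <- function(start, end = NA, patient = "P1", number = 1L,
                    regimen = "ici") {
  data.frame(patient_id = patient, line_number = number,
             regimen_class = regimen, start_day = as.integer(start),
             end_day = as.integer(end), stringsAsFactors = FALSE)
}
mk_biopsy <- function(collection, patient = "P1", id = "S1") {
  data.frame(sample_id = id, patient_id = patient,
             collection_day = as.integer(collection), tissue_site = "lung",
             pdl1_ihc_class = NA_character_, expression_column = id,
             stringsAsFactors = FALSE)
}
mk_events <- function(days, types = "progression", patient = "P1") {
  if (length(days) == 0)
    return(data.frame(patient_id = character(), day = integer(),
                      event_type = character(), stringsAsFactors = FALSE))
  data.frame(patient_id = patient, day = as.integer(days),
             event_type = rep(types, length.out = length(days)),
             stringsAsFactors = FALSE)
}

# session-wide cache for the default synthetic cohort (seeded)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key = "default", builder = function()
  generate_rwe_cohort(synth_config(seed = 101))) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- builder()
  .sim_cache[[key]]
}
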