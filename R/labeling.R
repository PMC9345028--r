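#' Blood-glucose decompensation categories
#'
#' Category scheme (mmol/L): `[3.9, 10]` nondecompensated (0), `< 3.9`
#' hypoglycemia (1), `(10, 13.9]` mild (2), `(13.9, 16.7]` moderate (3) and
#' `> 16.7` severe hyperglycemia (4). Boundaries are inclusive exactly as
#' stated; level-2 hypoglycemia (< 3.0) is merged into category 1.
#'
#' @param value BG values in mmol/L; must be positive
#' @return integer categories 0-4
#' @examples
#' categorize_bg(c(3.89, 3.9, 10, 10.01, 13.9, 13.91, 16.7, 16.71))
#' @export
categorize_bg <- function(value) {
  if (anyNA(value) || any(value <= 0))
    stop("BG values must be positive and non-missing", call. = FALSE)
  ifelse(value < 3.9, 1L,
         ifelse(value <= 10, 0L,
                ifelse(value <= 13.9, 2L,
                       ifelse(value <= 16.7, 3L, 4L))))
}

#' Category display names
#' @return named character vector, names are the category codes
#' @export
category_names <- function() {
  c("0" = "nondecompensated", "1" = "hypoglycemia",
    "2" = "mild hyperglycemia", "3" = "moderate hyperglycemia",
    "4" = "severe hyperglycemia")
}

#' Detect first decompensation events of a case
#'
#' Scans the BG measurements of one case and returns the first event per
#' category (1-4). Only the first event of each category counts. An event
#' whose time coincides with the first measurement of the case is flagged
#' `at_first_measurement`: with no prior data there is nothing to predict
#' from, and the category is voided for the case downstream.
#'
#' @param labs lab table of a single case (`analyte`, `value`, `time`)
#' @param bg_analyte name of the plain BG analyte (default `"glucose"`)
#' @param first_measurement `"any"` (default): the case's first measurement is
#'   the earliest timestamp of any analyte; `"bg"`: of the BG analyte only
#' @return data.frame with columns `category`, `event_time`, `bg_value`,
#'   `at_first_measurement`; zero rows if the case has no BG measurements
#' @export
detect_first_events <- function(labs, bg_analyte = "glucose",
                                first_measurement = c("any", "bg")) {
  first_measurement <- match.arg(first_measurement)
  stop_if_not_cols(labs, c("analyte", "value", "time"), "labs")
  bg <- labs[labs$analyte == bg_analyte & !is.na(labs$value), , drop = FALSE]
  empty <- data.frame(category = integer(0), event_time = labs$time[0],
                      bg_value = numeric(0), at_first_measurement = logical(0))
  if (nrow(bg) == 0) return(empty)
  bg <- bg[order(bg$time), , drop = FALSE]
  cat <- categorize_bg(bg$value)
  first_t <- if (first_measurement == "any") min(labs$time) else min(bg$time)
  out <- empty
  for (k in 1:4) {
    i <- which(cat == k)
    if (!length(i)) next
    i <- i[1]
    out <- rbind(out, data.frame(category = k, event_time = bg$time[i],
                                 bg_value = bg$value[i],
                                 at_first_measurement = bg$time[i] == first_t))
  }
  rownames(out) <- NULL
  out
}

#' Build the look-back window for one (case, category) instance
#'
#' For an event instance the window contains all laboratory data recorded
#' strictly before the event; for a control instance (category 0) it spans
#' the full stay. Windows are half-open `[admission, end)` in continuous time.
#'
#' @param cohort a `glyc_cohort`
#' @param case_id case identifier
#' @param category 1-4 for an event window, 0 for the control window
#' @param event_time event timestamp (required for event windows)
#' @return list of class `lookback_window` with elements `case_id`,
#'   `category`, `window_start`, `window_end`, `rows` (the lab rows) and
#'   `horizon_hours` (`NA` for controls)
#' @export
build_lookback <- function(cohort, case_id, category, event_time = NULL) {
  adm <- cohort$admissions[cohort$admissions$case_id == case_id, ]
  if (nrow(adm) != 1) stop("unknown case_id: ", case_id, call. = FALSE)
  labs <- cohort$labs[cohort$labs$case_id == case_id, , drop = FALSE]
  if (category == 0) {
    w_end <- adm$discharge_time
    rows <- labs
    horizon <- NA_real_
  } else {
    if (is.null(event_time))
      stop("event_time is required for an event window", call. = FALSE)
    w_end <- event_time
    rows <- labs[labs$time < event_time, , drop = FALSE]
    if (nrow(rows) == 0)
      stop("event coincides with the first measurements of the case; ",
           "no look-back window exists", call. = FALSE)
    horizon <- hours_between(max(rows$time), event_time)
  }
  structure(list(case_id = case_id, category = as.integer(category),
                 window_start = adm$admit_time, window_end = w_end,
                 rows = rows, horizon_hours = horizon),
            class = "lookback_window")
}

#' Prediction horizon of an event window
#'
#' Hours between the last predictor datum in the look-back window and the
#' event: the lead time an alert would provide.
#'
#' @param window a `lookback_window` (event instance)
#' @param event_time event timestamp; defaults to the window end
#' @return non-negative number of hours
#' @export
compute_horizon <- function(window, event_time = window$window_end) {
  if (nrow(window$rows) == 0)
    stop("empty look-back window: horizon undefined", call. = FALSE)
  hours_between(max(window$rows$time), event_time)
}

#' Label a cohort: events, look-back windows and horizons
#'
#' Runs first-event detection on every case and assembles the window
#' manifest: one row per (case, category) event instance whose event does not
#' coincide with the case's first measurement, plus one control row
#' (category 0, full stay) for every case without any event. Cases whose only
#' events were voided by the first-measurement rule contribute neither event
#' nor control instances.
#'
#' @param cohort a `glyc_cohort`
#' @param bg_analyte,first_measurement see [detect_first_events()]
#' @return object of class `glyc_labels`: list with `events` (all detected
#'   first events incl. the voided ones, flagged) and `manifest` (columns
#'   `case_id`, `category`, `window_start`, `window_end`, `horizon_hours`,
#'   `n_rows`)
#' @export
label_cohort <- function(cohort, bg_analyte = "glucose",
                         first_measurement = "any") {
  stopifnot(inherits(cohort, "glyc_cohort"))
  labs <- cohort$labs
  adm <- cohort$admissions
  bg <- labs[labs$analyte == bg_analyte & !is.na(labs$value), , drop = FALSE]
  events <- data.frame(case_id = character(0), category = integer(0),
                       event_time = labs$time[0], bg_value = numeric(0),
                       at_first_measurement = logical(0))
  if (nrow(bg)) {
    bg <- bg[order(bg$case_id, bg$time), , drop = FALSE]
    cat <- categorize_bg(bg$value)
    ev <- bg[cat > 0, , drop = FALSE]
    evcat <- cat[cat > 0]
    if (nrow(ev)) {
      key <- paste(ev$case_id, evcat)
      first_i <- !duplicated(key)           # bg sorted by time within case
      events <- data.frame(case_id = ev$case_id[first_i],
                           category = evcat[first_i],
                           event_time = ev$time[first_i],
                           bg_value = ev$value[first_i],
                           stringsAsFactors = FALSE)
      ft <- if (first_measurement == "any") {
        tapply(as.numeric(labs$time), labs$case_id, min)
      } else tapply(as.numeric(bg$time), bg$case_id, min)
      events$at_first_measurement <-
        as.numeric(events$event_time) == unname(ft[events$case_id])
      events <- events[order(events$case_id, events$category), ]
      rownames(events) <- NULL
    }
  }

  kept <- events[!events$at_first_measurement, , drop = FALSE]
  lab_idx <- split(seq_len(nrow(labs)), labs$case_id)
  lab_t <- as.numeric(labs$time)
  horizon <- numeric(nrow(kept))
  n_rows <- integer(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    ii <- lab_idx[[kept$case_id[i]]]
    tt <- lab_t[ii]
    e <- as.numeric(kept$event_time[i])
    before <- tt < e
    n_rows[i] <- sum(before)
    horizon[i] <- (e - max(tt[before])) / 3600
  }
  ev_manifest <- data.frame(case_id = kept$case_id, category = kept$category,
                            window_start = adm$admit_time[match(kept$case_id, adm$case_id)],
                            window_end = kept$event_time,
                            horizon_hours = horizon, n_rows = n_rows,
                            stringsAsFactors = FALSE)
  ctrl_cases <- setdiff(adm$case_id, events$case_id)
  ci <- match(ctrl_cases, adm$case_id)
  n_ctrl <- vapply(ctrl_cases, function(cs) length(lab_idx[[cs]] %||% integer(0)),
                   integer(1))
  ctrl_manifest <- data.frame(case_id = ctrl_cases,
                              category = rep(0L, length(ctrl_cases)),
                              window_start = adm$admit_time[ci],
                              window_end = adm$discharge_time[ci],
                              horizon_hours = rep(NA_real_, length(ctrl_cases)),
                              n_rows = unname(n_ctrl),
                              stringsAsFactors = FALSE)
  manifest <- rbind(ev_manifest, ctrl_manifest)
  manifest <- manifest[order(manifest$case_id, manifest$category), ]
  rownames(manifest) <- NULL
  structure(list(events = events, manifest = manifest,
                 bg_analyte = bg_analyte),
            class = "glyc_labels")
}

#' @export
print.glyc_labels <- function(x, ...) {
  cat("Dysglycemia labels\n")
  cat(sprintf("  detected first events: %d (%d voided at first measurement)\n",
              nrow(x$events), sum(x$events$at_first_measurement)))
  tb <- table(factor(x$manifest$category, levels = 0:4))
  cat(sprintf("  window manifest: %d instances (control %d, cat1 %d, cat2 %d, cat3 %d, cat4 %d)\n",
              nrow(x$manifest), tb[1], tb[2], tb[3], tb[4], tb[5]))
  invisible(x)
}

diabetes_icd_prefixes <- function() {
  c("E10", "E11", "E12", "E13", "E14", "E16", "E66", "E67", "E68",
    "G59", "G63", "H28", "H36", "K77.8", "K85", "M14.2", "N08.3",
    "O24", "R73", "R81")
}

#' Cohort inclusion criteria
#'
#' A patient is included if at least one rule fires: (1) a diabetes or
#' diabetes-related diagnosis (ICD-10 codes E10-E14, E16, E66-E68, G59, G63,
#' H28, H36, K77.8, K85, M14.2, N08.3, O24, R73, R81); (2) administration of
#' an antidiabetic drug (ATC category A10); (3) extreme glycemia: any BG
#' below 4.0 or at/above 11.1 mmol/L, fasting BG at/above 7.0 mmol/L, an
#' OGTT 2-h value at/above 11.1 mmol/L, or HbA1c at/above 48 mmol/mol (6.5%).
#'
#' @param cohort a `glyc_cohort`
#' @return data.frame per patient: `patient_id`, `included`, `rule` (the
#'   first rule that fired: `"diagnosis"`, `"drug"`, `"glucose"`, or `NA`)
#' @export
meets_inclusion_criteria <- function(cohort) {
  stopifnot(inherits(cohort, "glyc_cohort"))
  pid <- cohort$demographics$patient_id
  # rule 1: diagnosis
  dx <- cohort$diagnoses
  pref <- diabetes_icd_prefixes()
  dx_hit <- Reduce(`|`, lapply(pref, function(p) startsWith(dx$icd10, p)),
                   rep(FALSE, nrow(dx)))
  r1 <- pid %in% dx$patient_id[dx_hit]
  # rule 2: ATC A10
  drug_cases <- cohort$drugs$case_id[startsWith(cohort$drugs$atc, "A10")]
  adm <- cohort$admissions
  r2 <- pid %in% adm$patient_id[adm$case_id %in% drug_cases]
  # rule 3: extreme glycemia
  labs <- cohort$labs
  case_pid <- adm$patient_id[match(labs$case_id, adm$case_id)]
  v <- labs$value
  hit <- (labs$analyte == "glucose" & !is.na(v) & (v < 4.0 | v >= 11.1)) |
    (labs$analyte == "glucose_fasting" & !is.na(v) & v >= 7.0) |
    (labs$analyte == "glucose_ogtt_2h" & !is.na(v) & v >= 11.1) |
    (labs$analyte == "hba1c" & !is.na(v) & v >= 48) |
    (labs$analyte == "hba1c_pct" & !is.na(v) & v >= 6.5)
  r3 <- pid %in% unique(case_pid[hit])
  rule <- ifelse(r1, "diagnosis", ifelse(r2, "drug",
                 ifelse(r3, "glucose", NA_character_)))
  data.frame(patient_id = pid, included = r1 | r2 | r3, rule = rule,
             stringsAsFactors = FALSE)
}
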