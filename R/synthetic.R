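#' Generate a synthetic inpatient cohort with injected dysglycemia events
#'
#' Emulates the statistical structure the prediction pipeline assumes:
#' per-patient demographics, one or more admissions, irregularly sampled
#' laboratory series over a 52-analyte panel with per-analyte missingness,
#' drug administrations, diagnoses, ICU intervals, and blood-glucose (BG)
#' decompensation events of categories 1-4 injected at known ground-truth
#' times.
#'
#' Key generator properties (see the methods vignette for rationale):
#' * Background BG follows an Ornstein-Uhlenbeck process around a per-case
#'   set-point and is confined to the nondecompensated band, so the injected
#'   events are exactly the decompensations present in the data.
#' * All injected events of a case share a single episode timestamp, and
#'   hypoglycemia episodes exclude hyperglycemia, so that no look-back window
#'   contains evidence of another event of the same case. Per-category event
#'   prevalences match the configured fractions exactly in expectation.
#' * Episode times and control stays are drawn from one common distribution;
#'   event-case stays extend beyond the episode. Under `signal_strength = 0`
#'   the look-back windows of event and control instances are therefore
#'   identically distributed and no feature carries label information.
#' * Lab sampling times come from an inhomogeneous Poisson process with a
#'   daytime-peaked intensity (mimicking staffing-driven sampling bias).
#' * The six signal analytes shift linearly by `signal_strength` SD over the
#'   `signal_window_h` hours preceding an episode (glucose drifts towards the
#'   band edge, downwards for hypoglycemia, upwards for hyperglycemia).
#'
#' @param config a [cohort_config()]
#' @return object of class `glyc_cohort`: a list of data.frames
#'   `demographics`, `admissions`, `labs`, `drugs`, `diagnoses`, `icu` and
#'   `ground_truth` (the latter is never read by the pipeline itself).
#'   All timestamps are POSIXct UTC.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 30, seed = 7))
#' nrow(coh$ground_truth)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop("config must be created by cohort_config()", call. = FALSE)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  origin <- as.POSIXct("2014-01-01 00:00:00", tz = "UTC")
  np <- cfg$n_patients
  if (np == 0) return(empty_cohort(cfg))

  ## ---- patients -----------------------------------------------------------
  pid <- sprintf("P%05d", seq_len(np))
  sex <- ifelse(runif(np) < 0.56, "M", "F")
  age <- pmin(pmax(round(rnorm(np, ifelse(sex == "M", 65.9, 62.6),
                               ifelse(sex == "M", 14.4, 19.6))), 18), 100)
  height <- round(rnorm(np, ifelse(sex == "M", 175, 164), 7))
  weight <- round(rlnorm(np, log(ifelse(sex == "M", 82, 72)), 0.22), 1)
  language <- sample(c("de", "fr", "it", "en"), np, TRUE,
                     prob = c(0.62, 0.2, 0.08, 0.1))
  civil <- sample(c("single", "married", "divorced", "widowed"), np, TRUE,
                  prob = c(0.25, 0.5, 0.12, 0.13))
  demographics <- data.frame(patient_id = pid, age = age, sex = sex,
                             height_cm = height, weight_kg = weight,
                             language = language, civil_status = civil,
                             stringsAsFactors = FALSE)

  ## ---- admissions ---------------------------------------------------------
  n_adm <- 1L + rpois(np, cfg$admissions_lambda)
  case_pid <- rep(pid, n_adm)
  nc <- length(case_pid)
  cid <- sprintf("C%06d", seq_len(nc))
  admit <- origin + round(runif(nc, 0, 5.9 * 365 * 86400) / 60) * 60

  ## ---- episode / stay structure ------------------------------------------
  # one window-length draw per case from a common truncated log-normal:
  # control cases use it as their full stay, event cases as the episode time
  W_days <- pmin(pmax(rlnorm(nc, cfg$stay_meanlog, cfg$stay_sdlog), 0.35), 45)
  pv <- cfg$category_prevalences
  hypo <- runif(nc) < pv[["1"]]
  ph_cond <- pmin(pv[c("2", "3", "4")] / (1 - pv[["1"]]), 1)
  ev <- matrix(FALSE, nc, 4, dimnames = list(NULL, as.character(1:4)))
  ev[, "1"] <- hypo
  for (k in c("2", "3", "4")) ev[, k] <- !hypo & (runif(nc) < ph_cond[[k]])
  has_event <- rowSums(ev) > 0
  extra_days <- pmin(pmax(rlnorm(nc, log(1.5), 0.6), 0.2), 20)
  stay_days <- ifelse(has_event, W_days + extra_days, W_days)
  episode_s <- round(W_days * 86400)            # seconds after admission
  discharge <- admit + ceiling(stay_days * 86400 / 60) * 60
  admissions <- data.frame(case_id = cid, patient_id = case_pid,
                           admit_time = admit, discharge_time = discharge,
                           stringsAsFactors = FALSE)

  ## ---- laboratory series --------------------------------------------------
  panel <- cfg$panel
  na_ <- nrow(panel)
  p_inc <- pmin(panel$p_present * cfg$missingness / mean(panel$p_present), 1)
  present <- matrix(runif(nc * na_) < rep(p_inc, each = nc), nc, na_)
  present[, panel$analyte == "glucose"] <- TRUE
  counts <- rpois(nc * na_, rep(panel$rate_per_day, each = nc) * 1.8 *
                    rep(stay_days, na_)) * as.vector(present)
  tot <- sum(counts)
  row_case <- rep(rep(seq_len(nc), na_), counts)
  row_analyte <- rep(rep(seq_len(na_), each = nc), counts)
  t_s <- runif(tot, 0, stay_days[row_case] * 86400)
  # daytime-peaked thinning: intensity proportional to 1 + 0.8 cos(2pi(h-10)/24)
  admit_s <- as.numeric(admit) %% 86400
  hod <- ((admit_s[row_case] + t_s) %% 86400) / 3600
  keep <- runif(tot) < (1 + 0.8 * cos(2 * pi * (hod - 10) / 24)) / 1.8
  row_case <- row_case[keep]; row_analyte <- row_analyte[keep]
  t_s <- round(t_s[keep])
  value <- rnorm(length(t_s), panel$mean[row_analyte], panel$sd[row_analyte])

  # admission glucose for every case (guarantees a predictor datum before any
  # injected event)
  gl_idx <- which(panel$analyte == "glucose")
  row_case <- c(row_case, seq_len(nc))
  row_analyte <- c(row_analyte, rep(gl_idx, nc))
  t_s <- c(t_s, rep(1800, nc))
  value <- c(value, rep(NA_real_, nc))

  # clinically triggered monitoring intensification ahead of an episode:
  # suspicion of decompensation multiplies the sampling rate of glucose (x3
  # in total) and of the acute-phase signal analytes (x2) inside the
  # pre-event window; part of the injected signal, hence absent in the null
  # cohort
  if (cfg$signal_strength > 0 && any(has_event)) {
    sig_idx <- which(panel$signal)
    evc <- which(has_event)
    w_h <- pmax(pmin(cfg$signal_window_h, episode_s[evc] / 3600 - 1), 0)
    for (j in sig_idx) {
      mult <- if (panel$analyte[j] == "glucose") 2 else 1
      n_x <- rpois(length(evc), panel$rate_per_day[j] * mult * w_h / 24) *
        as.integer(present[evc, j])
      xi <- rep(seq_along(evc), n_x)
      if (!length(xi)) next
      tx <- episode_s[evc][xi] - round(runif(length(xi), 0, w_h[xi] * 3600))
      row_case <- c(row_case, evc[xi])
      row_analyte <- c(row_analyte, rep(j, length(xi)))
      t_s <- c(t_s, tx)
      value <- c(value, rnorm(length(xi), panel$mean[j], panel$sd[j]))
    }
  }

  # glucose: piecewise OU around a per-case set-point, clamped inside the
  # nondecompensated band so injected events are the only decompensations
  setpoint <- rnorm(nc, 6.5, 0.5)
  is_gl <- row_analyte == gl_idx
  value[is_gl] <- ou_series(row_case[is_gl], t_s[is_gl], setpoint,
                            tau_h = 6, sigma = 0.8)
  value[is_gl] <- pmin(pmax(value[is_gl], 4.2), 9.5)

  ## ---- injected events ----------------------------------------------------
  ev_case <- rep(seq_len(nc), 4)[as.vector(ev)]
  ev_cat <- rep(1:4, each = nc)[as.vector(ev)]
  ev_val <- bg_event_value(ev_cat)
  ev_time_s <- episode_s[ev_case]
  row_case <- c(row_case, ev_case)
  row_analyte <- c(row_analyte, rep(gl_idx, length(ev_case)))
  t_s <- c(t_s, ev_time_s)
  value <- c(value, ev_val)

  ## ---- pre-event signal shift ---------------------------------------------
  if (cfg$signal_strength > 0 && any(has_event)) {
    ep_h <- ifelse(has_event, episode_s / 3600, NA_real_)
    direction <- ifelse(hypo, -1, 1)           # glucose drift direction
    sig_idx <- which(panel$signal)
    t_h <- t_s / 3600
    dt <- ep_h[row_case] - t_h                  # hours before episode
    in_win <- !is.na(dt) & dt > 0 & dt <= cfg$signal_window_h &
      row_analyte %in% sig_idx
    ramp <- (1 - dt / cfg$signal_window_h)
    shift <- cfg$signal_strength * panel$sd[row_analyte] * ramp
    dirv <- ifelse(row_analyte == gl_idx, direction[row_case], 1)
    value[in_win] <- value[in_win] + (shift * dirv)[in_win]
    regl <- in_win & row_analyte == gl_idx
    value[regl] <- pmin(pmax(value[regl], 4.2), 9.5)
  }

  ord <- order(row_case, t_s, row_analyte)
  labs <- data.frame(case_id = cid[row_case[ord]],
                     analyte = panel$analyte[row_analyte[ord]],
                     value = value[ord],
                     time = admit[row_case[ord]] + t_s[ord],
                     stringsAsFactors = FALSE)

  ## ---- drugs, diagnoses, ICU, inclusion guarantee -------------------------
  has_dx <- runif(np) < 0.37
  on_a10 <- runif(np) < ifelse(has_dx, 0.8, 0.15)
  a10_codes <- c("A10AB01", "A10AC01", "A10BA02", "A10BB01", "A10BJ01")
  other_codes <- c("C07AB02", "N02BE01", "B01AC06", "C10AA05")
  drugs <- make_drug_table(cid, case_pid, admit, stay_days, pid, on_a10,
                           a10_codes, other_codes)
  dx_codes <- c("E10.9", "E11.9", "E13.9", "R73.0")
  other_dx <- c("I10", "J18.9", "N39.0", "K80.2")
  diagnoses <- make_dx_table(pid, has_dx, origin, dx_codes, other_dx)

  # every patient must satisfy >=1 cohort inclusion rule; those with neither a
  # diabetes diagnosis nor an A10 drug get a qualifying HbA1c measurement
  # (independent of outcome status, so the null cohort stays null)
  need <- which(!has_dx & !on_a10)
  if (length(need)) {
    first_case <- match(pid[need], case_pid)
    hb_t <- round(runif(length(need), 3600, stay_days[first_case] * 86400 * 0.9))
    labs <- rbind(labs, data.frame(
      case_id = cid[first_case], analyte = "hba1c",
      value = round(runif(length(need), 48, 70), 1),
      time = admit[first_case] + hb_t, stringsAsFactors = FALSE))
  }
  labs <- labs[order(labs$case_id, labs$time, labs$analyte), ]
  rownames(labs) <- NULL

  in_icu <- runif(nc) < 0.12
  iu <- which(in_icu)
  icu_a <- runif(length(iu), 0, 0.5) * stay_days[iu] * 86400
  icu_b <- icu_a + runif(length(iu), 0.2, 0.5) * stay_days[iu] * 86400
  icu <- data.frame(case_id = cid[iu],
                    icu_start = admit[iu] + round(icu_a),
                    icu_end = admit[iu] + round(pmin(icu_b, stay_days[iu] * 86400)),
                    stringsAsFactors = FALSE)

  gt_ord <- order(ev_case, ev_cat)
  ground_truth <- data.frame(case_id = cid[ev_case[gt_ord]],
                             category = ev_cat[gt_ord],
                             event_time = admit[ev_case[gt_ord]] + ev_time_s[gt_ord],
                             bg_value = ev_val[gt_ord],
                             stringsAsFactors = FALSE)

  structure(list(demographics = demographics, admissions = admissions,
                 labs = labs, drugs = drugs, diagnoses = diagnoses, icu = icu,
                 ground_truth = ground_truth),
            class = "glyc_cohort", config = cfg)
}

# exact OU bridge over irregular times, grouped by case id (integer)
ou_series <- function(case, t_s, setpoint, tau_h, sigma) {
  ord <- order(case, t_s)
  cs <- case[ord]; ts <- t_s[ord] / 3600
  x <- numeric(length(cs))
  new_case <- c(TRUE, cs[-1] != cs[-length(cs)])
  dt <- c(Inf, ts[-1] - ts[-length(ts)])
  dt[new_case] <- Inf
  a <- exp(-dt / tau_h)
  innov_sd <- sigma * sqrt(1 - a^2)
  innov_sd[!is.finite(a) | a == 0] <- sigma
  a[new_case] <- 0
  eps <- rnorm(length(cs), 0, innov_sd)
  # recursive AR(1) with per-case restarts; loop is over runs, short in R
  sp <- setpoint[cs]
  prev <- 0
  for (i in seq_along(x)) {
    prev <- if (new_case[i]) sp[i] + eps[i] else sp[i] + a[i] * (prev - sp[i]) + eps[i]
    x[i] <- prev
  }
  out <- numeric(length(cs))
  out[ord] <- x
  out
}

# BG value draw for an injected event of a given category (vectorized)
bg_event_value <- function(category) {
  lo <- c(3.05, 10.05, 13.95, 16.75)[category]
  hi <- c(3.85, 13.85, 16.65, 28)[category]
  mu <- c(3.5, 11.6, 15.0, 19.0)[category]
  s <- c(0.25, 1.0, 0.8, 2.0)[category]
  round(pmin(pmax(rnorm(length(category), mu, s), lo), hi), 2)
}

make_drug_table <- function(cid, case_pid, admit, stay_days, pid, on_a10,
                            a10_codes, other_codes) {
  nc <- length(cid)
  pa10 <- on_a10[match(case_pid, pid)]
  # pre-admission antidiabetic record for treated patients
  pre_i <- which(pa10)
  pre <- data.frame(case_id = cid[pre_i],
                    atc = sample(a10_codes, length(pre_i), TRUE),
                    time = admit[pre_i] - round(runif(length(pre_i), 1, 90) * 86400),
                    pre_admission = TRUE, stringsAsFactors = FALSE)
  # in-stay administrations
  n_in <- rpois(nc, ifelse(pa10, 0.5, 0) * stay_days)
  in_case <- rep(seq_len(nc), n_in)
  instay <- data.frame(case_id = cid[in_case],
                       atc = sample(a10_codes, length(in_case), TRUE),
                       time = admit[in_case] +
                         round(runif(length(in_case), 0, stay_days[in_case] * 86400)),
                       pre_admission = FALSE, stringsAsFactors = FALSE)
  n_oth <- rpois(nc, 0.3 * stay_days)
  o_case <- rep(seq_len(nc), n_oth)
  oth <- data.frame(case_id = cid[o_case],
                    atc = sample(other_codes, length(o_case), TRUE),
                    time = admit[o_case] +
                      round(runif(length(o_case), 0, stay_days[o_case] * 86400)),
                    pre_admission = FALSE, stringsAsFactors = FALSE)
  d <- rbind(pre, instay, oth)
  d <- d[order(d$case_id, d$time), ]
  rownames(d) <- NULL
  d
}

make_dx_table <- function(pid, has_dx, origin, dx_codes, other_dx) {
  np <- length(pid)
  di <- which(has_dx)
  d1 <- data.frame(patient_id = pid[di],
                   icd10 = sample(dx_codes, length(di), TRUE),
                   time = origin + round(runif(length(di), 0, 4 * 365) * 86400),
                   stringsAsFactors = FALSE)
  n_o <- rpois(np, 0.8)
  oi <- rep(seq_len(np), n_o)
  d2 <- data.frame(patient_id = pid[oi],
                   icd10 = sample(other_dx, length(oi), TRUE),
                   time = origin + round(runif(length(oi), 0, 4 * 365) * 86400),
                   stringsAsFactors = FALSE)
  d <- rbind(d1, d2)
  d <- d[order(d$patient_id, d$time), ]
  rownames(d) <- NULL
  d
}

empty_cohort <- function(cfg) {
  pos <- as.POSIXct(character(0), tz = "UTC")
  structure(list(
    demographics = data.frame(patient_id = character(0), age = numeric(0),
                              sex = character(0), height_cm = numeric(0),
                              weight_kg = numeric(0), language = character(0),
                              civil_status = character(0)),
    admissions = data.frame(case_id = character(0), patient_id = character(0),
                            admit_time = pos, discharge_time = pos),
    labs = data.frame(case_id = character(0), analyte = character(0),
                      value = numeric(0), time = pos),
    drugs = data.frame(case_id = character(0), atc = character(0), time = pos,
                       pre_admission = logical(0)),
    diagnoses = data.frame(patient_id = character(0), icd10 = character(0),
                           time = pos),
    icu = data.frame(case_id = character(0), icu_start = pos, icu_end = pos),
    ground_truth = data.frame(case_id = character(0), category = integer(0),
                              event_time = pos, bg_value = numeric(0))
  ), class = "glyc_cohort", config = cfg)
}

#' Inject a decompensation event into one case
#'
#' Adds a BG measurement inside the category's interval at the requested time
#' and applies the configured pre-event signal shift to existing measurements
#' of the signal analytes in the preceding window. Fails if the time is
#' outside the admission or if the case has no predictor datum before the
#' event (an event at the very first measurements of a case carries no
#' look-back information and is excluded by the labeling stage anyway).
#'
#' @param cohort a `glyc_cohort`
#' @param case_id case identifier
#' @param category decompensation category, 1-4
#' @param time_h event time in hours since admission
#' @param config generator configuration; defaults to the cohort's own
#' @return the modified `glyc_cohort`
#' @export
inject_event <- function(cohort, case_id, category, time_h,
                         config = attr(cohort, "config")) {
  stopifnot(inherits(cohort, "glyc_cohort"))
  if (!category %in% 1:4) stop("category must be in 1..4", call. = FALSE)
  adm <- cohort$admissions[cohort$admissions$case_id == case_id, ]
  if (nrow(adm) != 1) stop("unknown case_id: ", case_id, call. = FALSE)
  stay_h <- hours_between(adm$admit_time, adm$discharge_time)
  if (time_h <= 0 || time_h > stay_h)
    stop("event time lies outside the admission interval", call. = FALSE)
  ev_time <- adm$admit_time + round(time_h * 3600)
  case_rows <- cohort$labs$case_id == case_id
  if (!any(case_rows & cohort$labs$time < ev_time))
    stop("no predictor datum exists before the event time", call. = FALSE)
  val <- bg_event_value(category)
  if (!is.null(config) && config$signal_strength > 0) {
    panel <- config$panel
    sig <- panel$analyte[panel$signal]
    idx <- which(case_rows & cohort$labs$analyte %in% sig &
                   cohort$labs$time < ev_time &
                   hours_between(cohort$labs$time, ev_time) <= config$signal_window_h)
    if (length(idx)) {
      dt <- hours_between(cohort$labs$time[idx], ev_time)
      ramp <- 1 - dt / config$signal_window_h
      sds <- panel$sd[match(cohort$labs$analyte[idx], panel$analyte)]
      dir <- ifelse(cohort$labs$analyte[idx] == "glucose",
                    if (category == 1) -1 else 1, 1)
      v <- cohort$labs$value[idx] + config$signal_strength * sds * ramp * dir
      gl <- cohort$labs$analyte[idx] == "glucose"
      v[gl] <- pmin(pmax(v[gl], 4.2), 9.5)
      cohort$labs$value[idx] <- v
    }
  }
  cohort$labs <- rbind(cohort$labs,
                       data.frame(case_id = case_id, analyte = "glucose",
                                  value = val, time = ev_time,
                                  stringsAsFactors = FALSE))
  cohort$labs <- cohort$labs[order(cohort$labs$case_id, cohort$labs$time,
                                   cohort$labs$analyte), ]
  rownames(cohort$labs) <- NULL
  cohort$ground_truth <- rbind(cohort$ground_truth,
                               data.frame(case_id = case_id, category = category,
                                          event_time = ev_time, bg_value = val,
                                          stringsAsFactors = FALSE))
  cohort
}

#' @export
print.glyc_cohort <- function(x, ...) {
  cat("Synthetic dysglycemia cohort\n")
  cat(sprintf("  patients:   %d\n", nrow(x$demographics)))
  cat(sprintf("  admissions: %d\n", nrow(x$admissions)))
  cat(sprintf("  lab rows:   %d over %d analytes\n", nrow(x$labs),
              length(unique(x$labs$analyte))))
  if (nrow(x$ground_truth)) {
    tb <- table(factor(x$ground_truth$category, levels = 1:4))
    cat(sprintf("  injected events: %d (cat1 %d, cat2 %d, cat3 %d, cat4 %d)\n",
                nrow(x$ground_truth), tb[1], tb[2], tb[3], tb[4]))
  } else cat("  injected events: 0\n")
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' The six data tables plus the ground-truth table are written as UTF-8 CSV
#' files with a header row and ISO-8601 UTC timestamps. The ground-truth file
#' is intended for tests only and is never read by the pipeline operations.
#'
#' @param cohort a `glyc_cohort`
#' @param dir target directory (created if missing)
#' @return `write_cohort`: the directory, invisibly. `read_cohort`: a
#'   `glyc_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "glyc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(cohort)) {
    df <- cohort[[nm]]
    for (cl in names(df))
      if (inherits(df[[cl]], "POSIXct"))
        df[[cl]] <- format(df[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  time_cols <- c("time", "admit_time", "discharge_time", "icu_start",
                 "icu_end", "event_time")
  out <- list()
  for (nm in c("demographics", "admissions", "labs", "drugs", "diagnoses",
               "icu", "ground_truth")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing table file: ", f, call. = FALSE)
    df <- read.csv(f, stringsAsFactors = FALSE)
    for (cl in intersect(names(df), time_cols))
      df[[cl]] <- as.POSIXct(df[[cl]], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    out[[nm]] <- df
  }
  structure(out, class = "glyc_cohort")
}
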