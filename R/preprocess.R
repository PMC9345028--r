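#' Plausibility limits for cleaning raw tables
#'
#' Demographic values outside their limits are set to missing (all other
#' values of the patient are retained); laboratory measurements outside the
#' hard-removal bounds are dropped, as are negative laboratory values except
#' for the analytes in `allow_negative`.
#'
#' Defaults: age 18-130 years, height 100-250 cm, weight 25-400 kg;
#' hard-removal bounds for chloride (65-138 mmol/L), plasma pH (6.8-7.8),
#' potassium (1.3-9.0 mmol/L) and sodium (100-191 mmol/L); base excess may be
#' negative.
#'
#' @param demographic named list of `c(lower, upper)` per demographic column
#' @param lab_removal named list of `c(lower, upper)` per analyte; rows with
#'   values outside (strictly below/above) these bounds are removed
#' @param allow_negative analytes for which negative values are legitimate
#' @return object of class `plausibility_limits`
#' @export
plausibility_limits <- function(
    demographic = list(age = c(18, 130), height_cm = c(100, 250),
                       weight_kg = c(25, 400)),
    lab_removal = list(chloride = c(65, 138), ph = c(6.8, 7.8),
                       potassium = c(1.3, 9.0), sodium = c(100, 191)),
    allow_negative = "base_excess") {
  for (b in c(demographic, lab_removal))
    if (length(b) != 2 || b[1] >= b[2])
      stop("each limit must be c(lower, upper) with lower < upper", call. = FALSE)
  structure(list(demographic = demographic, lab_removal = lab_removal,
                 allow_negative = allow_negative),
            class = "plausibility_limits")
}

#' Set implausible demographic values to missing
#'
#' @param demographics demographics table
#' @param limits a [plausibility_limits()]
#' @return the cleaned table; out-of-range values are `NA`, everything else is
#'   untouched
#' @export
apply_demographic_limits <- function(demographics,
                                     limits = plausibility_limits()) {
  for (col in names(limits$demographic)) {
    if (!col %in% names(demographics)) next
    b <- limits$demographic[[col]]
    v <- demographics[[col]]
    v[!is.na(v) & (v < b[1] | v > b[2])] <- NA
    demographics[[col]] <- v
  }
  demographics
}

#' Remove implausible laboratory measurements
#'
#' Negative values are removed (except for analytes allowed to be negative),
#' and rows of analytes with hard-removal bounds are dropped when the value
#' lies outside those bounds. All other analytes are untouched.
#'
#' @param labs lab table with columns `analyte`, `value`
#' @param limits a [plausibility_limits()]
#' @return the filtered lab table
#' @export
apply_lab_limits <- function(labs, limits = plausibility_limits()) {
  stop_if_not_cols(labs, c("analyte", "value"), "labs")
  keep <- rep(TRUE, nrow(labs))
  neg <- !is.na(labs$value) & labs$value < 0 &
    !(labs$analyte %in% limits$allow_negative)
  keep[neg] <- FALSE
  for (an in names(limits$lab_removal)) {
    b <- limits$lab_removal[[an]]
    bad <- labs$analyte == an & !is.na(labs$value) &
      (labs$value < b[1] | labs$value > b[2])
    keep[bad] <- FALSE
  }
  out <- labs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag putative outlier measurements with an isolation forest
#'
#' Isolation forests isolate anomalies with fewer random axis-parallel splits
#' than typical points; the anomaly score of a measurement is
#' `2^(-E[h]/c(psi))` with `E[h]` its mean isolation depth over the trees.
#' The detector runs per analyte on (value, hours-since-admission) pairs, so
#' the sparse analyte panel never needs imputation. Flags never alter the
#' measurement values; downstream they are aggregated into additional
#' predictor variables.
#'
#' @param labs lab table (`case_id`, `analyte`, `value`, `time`)
#' @param admissions admissions table (for time-since-admission); optional —
#'   without it the detector uses the value dimension only
#' @param contamination fraction of measurements flagged per analyte
#'   (default 0.01)
#' @param seed integer seed; flags are deterministic given the seed
#' @param ntrees,psi forest size and subsample size per tree
#' @return logical vector, one flag per lab row
#' @export
flag_outliers <- function(labs, admissions = NULL, contamination = 0.01,
                          seed = 1L, ntrees = 100L, psi = 256L) {
  if (nrow(labs) == 0) return(logical(0))
  stop_if_not_cols(labs, c("case_id", "analyte", "value"), "labs")
  tsa <- if (!is.null(admissions)) {
    adm <- admissions$admit_time[match(labs$case_id, admissions$case_id)]
    hours_between(adm, labs$time)
  } else rep(0, nrow(labs))
  flags <- logical(nrow(labs))
  analytes <- sort(unique(labs$analyte))
  for (k in seq_along(analytes)) {
    idx <- which(labs$analyte == analytes[k] & !is.na(labs$value))
    if (length(idx) < 8) next
    X <- cbind(labs$value[idx], tsa[idx])
    m <- min(psi, nrow(X))
    depths <- iforest_depths(X, as.integer(ntrees), as.integer(m),
                             as.integer(child_seed(seed, k)), -1L)
    scores <- 2^(-depths / max(iforest_cnorm(m), .Machine$double.eps))
    thr <- quantile(scores, 1 - contamination, type = 7)
    flags[idx] <- scores > thr
  }
  flags
}

#' Clean a cohort and attach outlier flags
#'
#' Applies [apply_demographic_limits()] and [apply_lab_limits()] and appends a
#' binary `outlier` column to the lab table via [flag_outliers()].
#'
#' @param cohort a `glyc_cohort`
#' @param limits a [plausibility_limits()]
#' @param contamination,seed passed to [flag_outliers()]
#' @return the cleaned `glyc_cohort`
#' @export
preprocess_cohort <- function(cohort, limits = plausibility_limits(),
                              contamination = 0.01, seed = 1L) {
  stopifnot(inherits(cohort, "glyc_cohort"))
  cohort$demographics <- apply_demographic_limits(cohort$demographics, limits)
  cohort$labs <- apply_lab_limits(cohort$labs, limits)
  cohort$labs$outlier <- as.integer(
    flag_outliers(cohort$labs, cohort$admissions, contamination, seed))
  cohort
}
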