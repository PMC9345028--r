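analyte_stat_names <- function()
  c("mean", "sd", "iqr", "range", "trend", "extreme", "recent", "n")

#' Summary statistics of one analyte series within a look-back window
#'
#' The eight derived variables standing in for an irregular series: mean,
#' sample SD, IQR (linear-interpolation quantiles), total range (max - min),
#' recent trend (OLS slope in units/hour over the last `min(3, n)` points),
#' most extreme value (maximizing `|x - mean|`, ties resolved towards the
#' later measurement), most recent value, and analysis count. Statistics that
#' are undefined at the observed count are missing: everything at count 0;
#' SD, IQR, range and trend at count 1.
#'
#' @param values numeric analyte values
#' @param times_h measurement times in hours (any origin); must be sorted
#'   together with `values`
#' @return named numeric vector of the 8 statistics
#' @examples
#' summarize_analyte(c(4, 6, 8), c(1, 2, 3))
#' @export
summarize_analyte <- function(values, times_h) {
  stopifnot(length(values) == length(times_h))
  keep <- !is.na(values)
  values <- values[keep]; times_h <- times_h[keep]
  ord <- order(times_h)
  values <- values[ord]; times_h <- times_h[ord]
  n <- length(values)
  out <- setNames(rep(NA_real_, 8), analyte_stat_names())
  out["n"] <- n
  if (n == 0) return(out)
  m <- mean(values)
  out["mean"] <- m
  out["recent"] <- values[n]
  dev <- abs(values - m)
  out["extreme"] <- values[max(which(dev == max(dev)))]
  if (n >= 2) {
    out["sd"] <- sd(values)
    q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    out["iqr"] <- q[2] - q[1]
    out["range"] <- max(values) - min(values)
    k <- min(3, n)
    tt <- times_h[(n - k + 1):n]; vv <- values[(n - k + 1):n]
    sxx <- sum((tt - mean(tt))^2)
    out["trend"] <- if (sxx > 0) sum((tt - mean(tt)) * (vv - mean(vv))) / sxx
                    else NA_real_
  }
  out
}

# vectorized group-wise version of summarize_analyte over integer group ids
# (1..G); returns a list of per-group stat vectors (NA where undefined)
group_analyte_stats <- function(gid, v, th, G) {
  keep <- !is.na(v)
  gid <- gid[keep]; v <- v[keep]; th <- th[keep]
  res <- lapply(analyte_stat_names(), function(s) rep(NA_real_, G))
  names(res) <- analyte_stat_names()
  res$n <- rep(0, G)
  if (!length(gid)) return(res)

  cnt <- tabulate(gid, G)
  res$n <- as.numeric(cnt)
  nz <- which(cnt > 0)
  endv <- cumsum(cnt); startv <- endv - cnt + 1

  # value-sorted pass: min/max/quantiles/sums
  o1 <- order(gid, v)
  vs <- v[o1]
  cs <- cumsum(vs); cs2 <- cumsum(vs^2)
  sum_g <- cs[endv[nz]] - cs[startv[nz]] + vs[startv[nz]]
  sum2_g <- cs2[endv[nz]] - cs2[startv[nz]] + vs[startv[nz]]^2
  mu <- sum_g / cnt[nz]
  res$mean[nz] <- mu
  multi <- cnt[nz] >= 2
  sdv <- sqrt(pmax(sum2_g - cnt[nz] * mu^2, 0) / pmax(cnt[nz] - 1, 1))
  res$sd[nz[multi]] <- sdv[multi]
  res$range[nz[multi]] <- (vs[endv[nz]] - vs[startv[nz]])[multi]
  qat <- function(p) {
    h <- (cnt[nz] - 1) * p + 1
    lo <- floor(h); fr <- h - lo
    hi <- pmin(lo + 1, cnt[nz])
    vs[startv[nz] + lo - 1] * (1 - fr) + vs[startv[nz] + hi - 1] * fr
  }
  iqr <- qat(0.75) - qat(0.25)
  res$iqr[nz[multi]] <- iqr[multi]

  # time-sorted pass: recent, trend
  o2 <- order(gid, th)           # stable; later original rows win ties
  vt <- v[o2]; tt <- th[o2]
  res$recent[nz] <- vt[endv[nz]]
  has2 <- cnt[nz] >= 2
  i3 <- endv[nz]; i2 <- i3 - 1; i1 <- i3 - 2
  get3 <- function(x, idx, valid) ifelse(valid, x[pmax(idx, 1)], NA_real_)
  T <- cbind(get3(tt, i1, cnt[nz] >= 3), get3(tt, i2, cnt[nz] >= 2), tt[i3])
  V <- cbind(get3(vt, i1, cnt[nz] >= 3), get3(vt, i2, cnt[nz] >= 2), vt[i3])
  tbar <- rowMeans(T, na.rm = TRUE); vbar <- rowMeans(V, na.rm = TRUE)
  sxx <- rowSums((T - tbar)^2, na.rm = TRUE)
  sxy <- rowSums((T - tbar) * (V - vbar), na.rm = TRUE)
  tr <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  res$trend[nz[has2]] <- tr[has2]

  # extreme: |x - mean|, ties -> later time
  dev <- abs(v - res$mean[gid])
  o3 <- order(gid, dev, th)
  res$extreme[nz] <- v[o3][endv[nz]]
  res
}

default_encodings <- function() {
  list(sex = c(F = 0, M = 1),
       language = c(de = 0, fr = 1, it = 2, en = 3),
       civil_status = c(single = 0, married = 1, divorced = 2, widowed = 3))
}

encode_cat <- function(x, map, what) {
  out <- unname(map[x])
  if (any(is.na(out) & !is.na(x)))
    warning("unknown ", what, " level(s) encoded as NA: ",
            paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "))
  as.numeric(out)
}

#' Derive the feature table from look-back windows
#'
#' Converts every (case, category) instance of the label manifest into one
#' derived feature vector: the eight summary statistics for each panel
#' analyte (columns `<analyte>__<stat>`), patient demographics, antidiabetic
#' drug history (ATC A10, split pre-admission vs in-window and by A10A/A10B
#' subcode), previous-decompensation indicators per category (events of the
#' same case strictly before the window end, or of earlier admissions of the
#' same patient), diabetes diagnosis history, ICU stay, aggregated outlier
#' flags, and elapsed-time variables. No measurement at or after the window
#' end is ever read. Rows are hashed and duplicates removed.
#'
#' @param cohort a (preprocessed) `glyc_cohort`
#' @param labels a `glyc_labels` from [label_cohort()]
#' @param encodings integer category maps for sex/language/civil status;
#'   persisted as an attribute so that prediction-time encodings match
#' @return data.frame of class `glyc_features`; identifier columns `case_id`,
#'   `patient_id`, `category`, `hash`, all other columns are predictors
#'   (attribute `predictors`)
#' @export
derive_features <- function(cohort, labels, encodings = default_encodings()) {
  stopifnot(inherits(cohort, "glyc_cohort"), inherits(labels, "glyc_labels"))
  for (tb in c("demographics", "admissions", "labs", "drugs", "diagnoses", "icu"))
    if (is.null(cohort[[tb]]))
      stop("missing context table: ", tb, call. = FALSE)
  manifest <- labels$manifest
  if (nrow(manifest) == 0)
    stop("empty window manifest: nothing to featurize", call. = FALSE)
  adm <- cohort$admissions
  labs <- cohort$labs
  panel_analytes <- sort(unique(labs$analyte))
  na_ <- length(panel_analytes)

  # unique windows: (case, end); instances of a case that share the window
  # end share features
  wkey <- paste(manifest$case_id, as.numeric(manifest$window_end),
                manifest$category == 0)
  uw <- !duplicated(wkey)
  wid_of_instance <- match(wkey, wkey[uw])
  w_case <- manifest$case_id[uw]
  w_end <- manifest$window_end[uw]
  w_ctrl <- manifest$category[uw] == 0
  w_admit <- adm$admit_time[match(w_case, adm$case_id)]
  nw <- sum(uw)

  # assign lab rows to windows
  lab_idx <- split(seq_len(nrow(labs)), labs$case_id)
  lab_t <- as.numeric(labs$time)
  rows_per_w <- vector("list", nw)
  for (j in seq_len(nw)) {
    ii <- lab_idx[[w_case[j]]] %||% integer(0)
    rows_per_w[[j]] <- if (w_ctrl[j]) ii else ii[lab_t[ii] < as.numeric(w_end[j])]
  }
  wlen <- lengths(rows_per_w)
  lab_row <- unlist(rows_per_w, use.names = FALSE)
  lab_w <- rep(seq_len(nw), wlen)

  # per-(window, analyte) statistics
  a_idx <- match(labs$analyte[lab_row], panel_analytes)
  gid <- (lab_w - 1L) * na_ + a_idx
  th <- (lab_t[lab_row] - as.numeric(w_admit)[lab_w]) / 3600
  st <- group_analyte_stats(gid, labs$value[lab_row], th, nw * na_)
  stats <- analyte_stat_names()
  M <- matrix(NA_real_, nw, na_ * length(stats))
  colnames(M) <- as.vector(t(outer(panel_analytes, stats, paste, sep = "__")))
  for (s in seq_along(stats)) {
    vals <- matrix(st[[stats[s]]], nrow = nw, ncol = na_, byrow = TRUE)
    M[, (seq_len(na_) - 1) * length(stats) + s] <- vals
  }

  # demographics
  pat <- adm$patient_id[match(w_case, adm$case_id)]
  d <- cohort$demographics[match(pat, cohort$demographics$patient_id), ]
  demo <- data.frame(age = as.numeric(d$age),
                     sex = encode_cat(d$sex, encodings$sex, "sex"),
                     height_cm = as.numeric(d$height_cm),
                     weight_kg = as.numeric(d$weight_kg),
                     language = encode_cat(d$language, encodings$language, "language"),
                     civil_status = encode_cat(d$civil_status,
                                               encodings$civil_status, "civil_status"))

  # drug history (ATC A10 by subcode, pre-admission vs in-window)
  dr <- cohort$drugs
  dr_case_w <- split(seq_len(nrow(dr)), dr$case_id)
  dr_t <- as.numeric(dr$time)
  drugf <- matrix(0, nw, 6,
                  dimnames = list(NULL, c("drug_a10_pre", "drug_a10a_pre",
                                          "drug_a10b_pre", "drug_a10_in",
                                          "drug_a10a_in", "drug_a10b_in")))
  for (j in seq_len(nw)) {
    ii <- dr_case_w[[w_case[j]]] %||% integer(0)
    if (!length(ii)) next
    atc <- dr$atc[ii]
    a10 <- startsWith(atc, "A10")
    pre <- dr$pre_admission[ii] & a10
    inw <- !dr$pre_admission[ii] & a10 & dr_t[ii] < as.numeric(w_end[j])
    drugf[j, ] <- c(any(pre), any(pre & startsWith(atc, "A10A")),
                    any(pre & startsWith(atc, "A10B")),
                    any(inw), any(inw & startsWith(atc, "A10A")),
                    any(inw & startsWith(atc, "A10B")))
  }

  # previous decompensations: same case before window end, or any earlier
  # admission of the same patient
  ev <- labels$events
  prevd <- matrix(0, nw, 4, dimnames = list(NULL, paste0("prev_decomp_cat", 1:4)))
  if (nrow(ev)) {
    ev_case <- ev$case_id
    ev_t <- as.numeric(ev$event_time)
    ev_pat <- adm$patient_id[match(ev_case, adm$case_id)]
    ev_admit <- as.numeric(adm$admit_time[match(ev_case, adm$case_id)])
    ev_by_case <- split(seq_len(nrow(ev)), ev_case)
    ev_by_pat <- split(seq_len(nrow(ev)), ev_pat)
    for (j in seq_len(nw)) {
      hit <- integer(0)
      ii <- ev_by_case[[w_case[j]]] %||% integer(0)
      if (length(ii)) hit <- ii[ev_t[ii] < as.numeric(w_end[j])]
      jj <- ev_by_pat[[pat[j]]] %||% integer(0)
      if (length(jj))
        hit <- c(hit, jj[ev_admit[jj] < as.numeric(w_admit[j])])
      if (length(hit)) prevd[j, unique(ev$category[hit])] <- 1
    }
  }

  # diagnosis history (diabetes-related, known before window end)
  dx <- cohort$diagnoses
  pref <- diabetes_icd_prefixes()
  dx_diab <- Reduce(`|`, lapply(pref, function(p) startsWith(dx$icd10, p)),
                    rep(FALSE, nrow(dx)))
  dpat <- dx$patient_id[dx_diab]; dtime <- as.numeric(dx$time[dx_diab])
  dx_first <- tapply(dtime, dpat, min)
  dxv <- as.numeric(!is.na(dx_first[pat]) &
                      unname(dx_first[pat]) < as.numeric(w_end))
  dxv[is.na(dxv)] <- 0

  # ICU stay starting before window end
  icu <- cohort$icu
  icu_first <- tapply(as.numeric(icu$icu_start), icu$case_id, min)
  icuv <- as.numeric(!is.na(icu_first[w_case]) &
                       unname(icu_first[w_case]) < as.numeric(w_end))
  icuv[is.na(icuv)] <- 0

  # outlier flag aggregation within the window
  if (!is.null(labs$outlier)) {
    of <- labs$outlier[lab_row]
    on_ <- rowsum(as.numeric(of), lab_w)
    outlier_n <- numeric(nw)
    outlier_n[as.integer(rownames(on_))] <- on_[, 1]
  } else outlier_n <- rep(0, nw)

  # elapsed-time variables
  window_hours <- hours_between(w_admit, w_end)
  last_t <- rep(NA_real_, nw)
  mt <- tapply(lab_t[lab_row], lab_w, max)
  last_t[as.integer(names(mt))] <- mt
  gap_hours <- (as.numeric(w_end) - last_t) / 3600

  wfeat <- cbind(as.data.frame(M), demo, as.data.frame(drugf),
                 as.data.frame(prevd),
                 dx_diabetes = dxv, icu_stay = icuv,
                 outlier_n = outlier_n, outlier_any = as.numeric(outlier_n > 0),
                 window_hours = window_hours, last_gap_hours = gap_hours,
                 n_labs = as.numeric(wlen))

  out <- cbind(data.frame(case_id = manifest$case_id,
                          patient_id = pat[wid_of_instance],
                          category = manifest$category,
                          stringsAsFactors = FALSE),
               wfeat[wid_of_instance, , drop = FALSE])
  rownames(out) <- NULL
  predictors <- names(wfeat)
  out$hash <- hash_rows(out, c("case_id", "category", predictors))
  out <- dedup_rows(out)
  structure(out, class = c("glyc_features", "data.frame"),
            predictors = predictors, encodings = encodings,
            analytes = panel_analytes)
}

# canonical row digest over the named columns
hash_rows <- function(df, cols) {
  parts <- lapply(df[cols], function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.10g", x))
    else ifelse(is.na(x), "NA", as.character(x))
  })
  fnv1a64(do.call(paste, c(parts, sep = "|")))
}

#' Remove duplicate feature rows
#'
#' Keeps the first occurrence of each row hash; deterministic and idempotent.
#'
#' @param features a feature table carrying a `hash` column
#' @return the deduplicated table
#' @export
dedup_rows <- function(features) {
  stopifnot("hash" %in% names(features))
  out <- features[!duplicated(features$hash), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.glyc_features <- function(x, ...) {
  cat(sprintf("Derived feature table: %d instances x %d predictors\n",
              nrow(x), length(attr(x, "predictors"))))
  tb <- table(factor(x$category, levels = 0:4))
  cat(sprintf("  instances by category: 0:%d 1:%d 2:%d 3:%d 4:%d\n",
              tb[1], tb[2], tb[3], tb[4], tb[5]))
  invisible(x)
}

# numeric predictor matrix for model consumption
feature_matrix <- function(features) {
  pr <- attr(features, "predictors")
  as.matrix(as.data.frame(features)[, pr, drop = FALSE])
}

#' Subset a feature table, preserving its metadata
#'
#' `[.data.frame` drops the predictor/encoding attributes; this keeps them.
#'
#' @param features a `glyc_features`
#' @param rows row index
#' @return the subset, still a `glyc_features`
#' @export
subset_features <- function(features, rows) {
  out <- as.data.frame(features)[rows, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("glyc_features", "data.frame"),
            predictors = attr(features, "predictors"),
            encodings = attr(features, "encodings"),
            analytes = attr(features, "analytes"))
}
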