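# Shared, lazily built fixtures. Everything is generated in code at test
# time; the heavier cohorts are memoized so several test files can reuse them
# within one run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# ~250-case cohort for module-level tests
small_cohort <- function() fixture("small_cohort", function()
  preprocess_cohort(generate_cohort(cohort_config(n_patients = 150, seed = 42)),
                    seed = 42))

small_labels <- function() fixture("small_labels", function()
  label_cohort(small_cohort()))

small_features <- function() fixture("small_features", function()
  derive_features(small_cohort(), small_labels()))

# ~2000-case strong-signal cohort (the generator's default conditions)
strong_cohort <- function() fixture("strong_cohort", function()
  preprocess_cohort(generate_cohort(cohort_config(n_patients = 1200, seed = 404)),
                    seed = 404))

strong_labels <- function() fixture("strong_labels", function()
  label_cohort(strong_cohort()))

strong_features <- function() fixture("strong_features", function()
  derive_features(strong_cohort(), strong_labels()))

# spec-A binary model trained under the acceptance conditions (budget 50)
strong_model <- function() fixture("strong_model", function()
  train_binary(candidate_specs()[["A"]],
               make_instances(strong_features(), candidate_specs()[["A"]]),
               budget = 50, seed = 7))

# hand-built single/multi-case cohort for labeling and feature unit tests
mk_cohort <- function(labs,
                      cases = unique(labs$case_id),
                      stay_h = 240,
                      demographics = NULL, drugs = NULL, diagnoses = NULL,
                      icu = NULL) {
  t0 <- as.POSIXct("2016-05-01 08:00:00", tz = "UTC")
  pid <- paste0("P", sub("^C", "", cases))
  adm <- data.frame(case_id = cases, patient_id = pid,
                    admit_time = rep(t0, length(cases)),
                    discharge_time = rep(t0 + stay_h * 3600, length(cases)),
                    stringsAsFactors = FALSE)
  demo <- demographics %||% data.frame(
    patient_id = pid, age = 60, sex = "F", height_cm = 165, weight_kg = 70,
    language = "de", civil_status = "married", stringsAsFactors = FALSE)
  pos0 <- t0[0]
  structure(list(
    demographics = demo, admissions = adm, labs = labs,
    drugs = drugs %||% data.frame(case_id = character(0), atc = character(0),
                                  time = pos0, pre_admission = logical(0)),
    diagnoses = diagnoses %||% data.frame(patient_id = character(0),
                                          icd10 = character(0), time = pos0),
    icu = icu %||% data.frame(case_id = character(0), icu_start = pos0,
                              icu_end = pos0),
    ground_truth = data.frame(case_id = character(0), category = integer(0),
                              event_time = pos0, bg_value = numeric(0))
  ), class = "glyc_cohort", config = cohort_config(n_patients = 1))
}

# lab rows at given hours since admission
mk_labs <- function(case_id, analyte, value, hours) {
  t0 <- as.POSIXct("2016-05-01 08:00:00", tz = "UTC")
  data.frame(case_id = case_id, analyte = analyte, value = value,
             time = t0 + round(hours * 3600), stringsAsFactors = FALSE)
}

# minimal glyc_features table from a plain data.frame of predictors
mk_features <- function(case_id, category, pred) {
  df <- cbind(data.frame(case_id = case_id,
                         patient_id = paste0("P", case_id),
                         category = category, stringsAsFactors = FALSE),
              pred)
  df$hash <- dysglyc:::hash_rows(df, c("case_id", "category", names(pred)))
  structure(df, class = c("glyc_features", "data.frame"),
            predictors = names(pred), encodings = NULL, analytes = character(0))
}

# independent minimum-distance decoder used as an oracle for decode_votes()
oracle_decode <- function(bits, specs, priority = tiebreak_priority()) {
  d <- vapply(0:4, function(k) {
    cw <- vapply(specs, function(s) as.integer(k %in% s$positive_set),
                 integer(1))
    sum(cw != bits)
  }, numeric(1))
  tied <- which(d == min(d)) - 1L
  priority[priority %in% tied][1]
}
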