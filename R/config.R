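#' Default laboratory analyte panel
#'
#' A 52-analyte panel with invented reference means, SDs and mean sampling
#' rates (measurements per day). The reference ranges are synthetic and are
#' *not* clinically calibrated; they exist so that the generator can emulate
#' the sparsity and irregularity of routine inpatient laboratory data. Six
#' analytes (glucose, lactate, crp, wbc, cortisol, triglycerides) carry the
#' injected pre-event signal; all others are pure noise.
#'
#' Units are mmol/L for electrolytes and glucose, mmol/mol for hba1c; other
#' units are conventional SI but, being synthetic, only internally consistent.
#'
#' @return data.frame with columns `analyte`, `mean`, `sd`, `rate_per_day`
#'   (mean sampling rate while admitted; glucose is monitored most intensely
#'   in this dysglycemia-risk population, acute-phase analytes next),
#'   `p_present` (per-case probability that the analyte is measured at all:
#'   near 1 for the core panel, low for specialized tests; panel mean ~0.6)
#'   and `signal` (logical)
#' @export
analyte_panel <- function() {
  spec <- c(
    # analyte            mean    sd     rate  p_present
    "glucose             6.5     0.8    6     1.0",
    "glucose_fasting     5.8     0.9    0.3   0.3",
    "glucose_ogtt_2h     7.5     2      0.05  0.1",
    "hba1c               42      8      0.1   0.5",
    "sodium              140     3      1.5   0.9",
    "potassium           4.1     0.45   1.5   0.9",
    "chloride            103     4      1.2   0.9",
    "ph                  7.40    0.05   0.8   0.5",
    "base_excess         0       3      0.8   0.5",
    "bicarbonate         24      3      0.8   0.5",
    "lactate             1.8     0.8    3     0.9",
    "crp                 60      35     3     0.9",
    "wbc                 9       3      3     0.9",
    "cortisol            400     150    3     0.9",
    "triglycerides       1.8     0.7    3     0.9",
    "creatinine          85      30     1.2   0.85",
    "urea                7       3      1.2   0.85",
    "egfr                75      25     1.2   0.85",
    "hemoglobin          125     18     1.5   0.9",
    "hematocrit          0.38    0.05   1.5   0.9",
    "rbc                 4.3     0.6    1.5   0.9",
    "mcv                 89      6      1.5   0.9",
    "platelets           250     80     1.5   0.9",
    "albumin             36      6      0.8   0.6",
    "total_protein       68      8      0.8   0.6",
    "bilirubin_total     14      8      0.8   0.6",
    "alat                40      25     0.8   0.6",
    "asat                36      20     0.8   0.6",
    "ggt                 70      50     0.8   0.6",
    "alp                 95      40     0.8   0.6",
    "amylase             65      30     0.3   0.25",
    "lipase              50      30     0.3   0.25",
    "ck                  130     90     0.5   0.4",
    "ldh                 220     70     0.5   0.4",
    "troponin_t          22      15     0.5   0.4",
    "nt_probnp           900     600    0.3   0.4",
    "tsh                 2.2     1.2    0.2   0.3",
    "ft4                 16      3      0.2   0.3",
    "calcium             2.3     0.15   1     0.7",
    "phosphate           1.05    0.25   1     0.7",
    "magnesium           0.85    0.12   1     0.7",
    "uric_acid           320     80     0.3   0.3",
    "cholesterol_total   4.8     1      0.2   0.3",
    "hdl_cholesterol     1.3     0.35   0.2   0.3",
    "ldl_cholesterol     2.9     0.9    0.2   0.3",
    "ferritin            200     120    0.2   0.25",
    "transferrin         2.4     0.5    0.2   0.25",
    "iron                14      6      0.2   0.25",
    "inr                 1.1     0.2    0.8   0.5",
    "aptt                30      5      0.8   0.5",
    "fibrinogen          3.5     1      0.5   0.5",
    "d_dimer             1000    700    0.5   0.5")
  p <- read.table(text = paste(spec, collapse = "\n"),
                  col.names = c("analyte", "mean", "sd", "rate_per_day",
                                "p_present"),
                  stringsAsFactors = FALSE)
  p$signal <- p$analyte %in%
    c("glucose", "lactate", "crp", "wbc", "cortisol", "triglycerides")
  p
}

#' Synthetic cohort configuration
#'
#' Bundles the knobs of the cohort generator. Category prevalences default to
#' the per-admission prevalences the pipeline is built around
#' (hypoglycemia 12.8%, mild 42.1%, moderate 16.4% and severe hyperglycemia
#' 13.3%); with these, roughly a third of cases carry no event at all.
#'
#' @param n_patients number of patients (>= 0)
#' @param admissions_lambda Poisson rate of admissions beyond the first per
#'   patient (default 0.66, i.e. ~1.66 admissions/patient)
#' @param category_prevalences named fractions for categories "1".."4": the
#'   probability that an admission contains an event of that category
#' @param panel analyte panel data.frame, see [analyte_panel()]
#' @param missingness mean per-(case, analyte) inclusion probability across
#'   the panel (default 0.6); the panel's relative `p_present` profile is
#'   rescaled to this mean, glucose is always present
#' @param signal_strength effect size, in analyte SD units, by which the six
#'   signal analytes shift over the 12 h preceding an injected event
#'   (0 = null cohort with no learnable signal)
#' @param signal_window_h length of the pre-event shift window, hours
#' @param stay_meanlog,stay_sdlog log-normal parameters of the episode/stay
#'   length distribution, in days
#' @param seed integer seed; a fixed seed makes [generate_cohort()] output
#'   byte-identical
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_patients = 1200,
                          admissions_lambda = 0.66,
                          category_prevalences = c("1" = 0.128, "2" = 0.421,
                                                   "3" = 0.164, "4" = 0.133),
                          panel = analyte_panel(),
                          missingness = 0.6,
                          signal_strength = 1.5,
                          signal_window_h = 12,
                          stay_meanlog = log(4.5),
                          stay_sdlog = 0.55,
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 0 ||
      n_patients != round(n_patients))
    stop("n_patients must be a single non-negative integer", call. = FALSE)
  pv <- category_prevalences[as.character(1:4)]
  if (anyNA(pv) || any(pv < 0) || any(pv > 1))
    stop("category_prevalences must map categories 1..4 to fractions in [0,1]",
         call. = FALSE)
  if (pv[["1"]] >= 1)
    stop("hypoglycemia prevalence must be < 1", call. = FALSE)
  if (!is.data.frame(panel) || nrow(panel) == 0)
    stop("analyte panel must be a non-empty data.frame", call. = FALSE)
  stop_if_not_cols(panel, c("analyte", "mean", "sd", "rate_per_day",
                            "p_present", "signal"), "panel")
  structure(list(
    n_patients = as.integer(n_patients),
    admissions_lambda = admissions_lambda,
    category_prevalences = pv,
    panel = panel,
    missingness = missingness,
    signal_strength = signal_strength,
    signal_window_h = signal_window_h,
    stay_meanlog = stay_meanlog,
    stay_sdlog = stay_sdlog,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Genetic algorithm settings for ensemble composition search
#'
#' @param pop_size population size
#' @param generations number of generations
#' @param crossover_rate per-bit probability of taking the first parent's bit
#'   during uniform crossover
#' @param mutation_rate per-bit mutation probability; `NULL` means `1/L`
#' @param tournament_size tournament selection size
#' @param elitism number of elite individuals copied unchanged
#' @return list of class `ga_control`
#' @export
ga_control <- function(pop_size = 50, generations = 30, crossover_rate = 0.5,
                       mutation_rate = NULL, tournament_size = 3, elitism = 2) {
  structure(list(pop_size = pop_size, generations = generations,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 tournament_size = tournament_size, elitism = elitism),
            class = "ga_control")
}
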