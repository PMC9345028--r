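test_that("analyte summaries reproduce hand-computed statistics", {
  s <- summarize_analyte(c(4, 6, 8), c(1, 2, 3))
  expect_equal(s[["mean"]], 6)
  expect_equal(s[["sd"]], 2)
  expect_equal(s[["range"]], 4)
  expect_equal(s[["n"]], 3)
  expect_equal(s[["recent"]], 8)
  expect_equal(s[["trend"]], 2)               # OLS slope over the 3 points
  expect_equal(s[["iqr"]], quantile(c(4, 6, 8), 0.75) - quantile(c(4, 6, 8), 0.25),
               ignore_attr = TRUE)

  # trend over last-3 window only; extreme is the largest |x - mean|
  s2 <- summarize_analyte(c(5, 5, 5, 9), 1:4)
  expect_equal(s2[["trend"]], 2)
  expect_equal(s2[["extreme"]], 9)

  # degenerate counts
  s0 <- summarize_analyte(numeric(0), numeric(0))
  expect_equal(s0[["n"]], 0)
  expect_true(all(is.na(s0[setdiff(names(s0), "n")])))
  s1 <- summarize_analyte(7.5, 3)
  expect_equal(s1[["n"]], 1)
  expect_equal(s1[["mean"]], 7.5)
  expect_equal(s1[["recent"]], 7.5)
  expect_equal(s1[["extreme"]], 7.5)
  expect_true(all(is.na(s1[c("sd", "iqr", "range", "trend")])))
  # ties in |x - mean| resolve to the later measurement
  st <- summarize_analyte(c(4, 8), c(1, 2))
  expect_equal(st[["extreme"]], 8)
  expect_equal(summarize_analyte(c(8, 4), c(1, 2))[["extreme"]], 4)
})

test_that("order-free statistics are permutation invariant", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    v <- rnorm(n); t <- sort(runif(n, 0, 48))
    p <- sample(n)
    a <- summarize_analyte(v, t)
    b <- summarize_analyte(v[p], t[p])
    expect_equal(a, b)                # sorting by time is part of the contract
  }
})

test_that("vectorized group statistics agree with the scalar reference", {
  set.seed(21)
  G <- 40
  gid <- sample(G, 300, replace = TRUE)
  v <- rnorm(300); th <- runif(300, 0, 100)
  got <- dysglyc:::group_analyte_stats(gid, v, th, G)
  for (g in seq_len(G)) {
    idx <- which(gid == g)
    want <- summarize_analyte(v[idx], th[idx])
    for (s in names(want))
      expect_equal(got[[s]][g], want[[s]], label = sprintf("group %d stat %s", g, s))
  }
})

test_that("feature assembly encodes history, context and duplicates correctly", {
  t0 <- as.POSIXct("2016-05-01 08:00:00", tz = "UTC")
  labs <- rbind(
    mk_labs("C1", "glucose", c(5, 11.5, 6, 15.2, 6.5), c(1, 10, 20, 30, 40)),
    mk_labs("C1", "sodium", c(140, 141), c(2, 25)),
    mk_labs("C2", "glucose", c(5.5, 6.0), c(1, 30)))
  coh <- mk_cohort(labs, cases = c("C1", "C2"), stay_h = 60,
                   drugs = data.frame(case_id = c("C1", "C1"),
                                      atc = c("A10BA02", "A10AB01"),
                                      time = c(t0 - 86400, t0 + 35 * 3600),
                                      pre_admission = c(TRUE, FALSE)),
                   icu = data.frame(case_id = "C1", icu_start = t0 + 3600,
                                    icu_end = t0 + 10 * 3600))
  lab <- label_cohort(coh)
  ft <- derive_features(coh, lab)
  # C1 contributes cat-2 (h10) and cat-3 (h30) instances, C2 a control row
  expect_setequal(paste(ft$case_id, ft$category),
                  c("C1 2", "C1 3", "C2 0"))
  r2 <- ft[ft$category == 2, ]
  r3 <- ft[ft$category == 3, ]
  # earlier mild-hyperglycemia event is visible to the later instance only
  expect_identical(r2$prev_decomp_cat2, 0)
  expect_identical(r3$prev_decomp_cat2, 1)
  expect_identical(ft$prev_decomp_cat1[ft$case_id == "C2"], 0)
  # pre-admission insulin counts for both, the in-stay dose (h35) for neither
  expect_identical(r2$drug_a10_pre, 1)
  expect_identical(r2$drug_a10b_pre, 1)
  expect_identical(r2$drug_a10_in, 0)
  expect_identical(r3$drug_a10_in, 0)
  expect_identical(r2$icu_stay, 1)
  # window statistics honour the strict pre-event cut
  expect_equal(r2$glucose__n, 1)
  expect_equal(r2$glucose__recent, 5)
  expect_equal(r3$glucose__n, 3)
  expect_equal(r3$glucose__recent, 6)
  expect_equal(r3$sodium__n, 2)
  # missing context tables are reported by name
  broken <- coh; broken$drugs <- NULL
  expect_error(derive_features(broken, lab), "drugs")
})

test_that("row hashing and deduplication keep first occurrences, idempotently", {
  pred <- data.frame(a = c(1, 1, 2, 2), b = c(0.5, 0.5, 0.5, 0.25))
  ft <- mk_features(c("C1", "C1", "C2", "C3"), c(0, 0, 0, 0), pred)
  dd <- dedup_rows(ft)
  expect_identical(nrow(dd), 3L)                # exact duplicate collapsed
  expect_identical(dedup_rows(dd), dd)          # idempotent
  # rows differing in a single statistic stay distinct
  expect_identical(length(unique(dd$hash)), 3L)
  # n duplicates of k distinct rows -> k rows
  ft2 <- mk_features(rep("C1", 9), rep(0, 9),
                     data.frame(a = rep(c(1, 2, 3), each = 3)))
  expect_identical(nrow(dedup_rows(ft2)), 3L)
})

test_that("no feature reads data at or after the event time", {
  coh <- small_cohort()
  lab <- small_labels()
  ft <- small_features()
  pert <- coh
  ev_first <- tapply(as.numeric(lab$events$event_time), lab$events$case_id, min)
  et <- ev_first[pert$labs$case_id]
  post <- !is.na(et) & as.numeric(pert$labs$time) >= et
  pert$labs$value[post] <- pert$labs$value[post] * 10 + 1
  ft2 <- derive_features(pert, lab)
  ev_rows <- ft$category > 0
  pr <- attr(ft, "predictors")
  expect_identical(as.data.frame(ft)[ev_rows, pr],
                   as.data.frame(ft2)[ft2$category > 0, pr])
})
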