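test_that("percent change matches the published stratum arithmetic", {
  expect_equal(percent_change(0.0200, 0.0187), 6.5)
  expect_equal(round(percent_change(0.0239, 0.0217), 1), 9.2)
  expect_equal(percent_change(3, 3), 0)
  expect_lt(percent_change(0.0134, 0.0144), 0)  # an increase is negative
  expect_error(percent_change(0, 1), "positive")
})

test_that("format_percent truncates toward zero at one decimal", {
  expect_equal(format_percent(7.46), 7.4)
  expect_equal(format_percent(-7.46), -7.4)
  expect_equal(format_percent(20.328), 20.3)
  expect_equal(format_percent(6.5), 6.5)
})

test_that("paired t matches an independent difference-formula oracle", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(4:30, 1)
    ref <- runif(n, 0.01, 0.08)
    algo <- ref * runif(n, 0.7, 1.3)
    got <- paired_t(ref, algo)
    want <- brute_paired_t(ref, algo)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$df, want$df)
    expect_equal(got$p.value, want$p.value)
  }
})

test_that("paired t handles degenerate and invalid inputs", {
  expect_warning(res <- paired_t(c(1, 2, 3), c(0, 1, 2)),
                 class = "agedose_degenerate_t")
  expect_true(is.na(res$statistic))
  expect_equal(res$mean_diff, 1)
  expect_error(paired_t(1, numeric(0)), "equal length")
  expect_error(paired_t(1, 2), "n >= 2")
  # worked session: statistic is finite (no significance claim at n = 10)
  ws_res <- evaluate_sessions(worked())
  expect_true(is.finite(paired_t(ws_res$acr_ref, ws_res$acr_algo)$statistic))
})

test_that("summarize_cohort stratifies correctly and is permutation-invariant", {
  sim <- generate_cohort(cohort_config(n_sessions = 6), seed = 13)
  res <- evaluate_sessions(sim)
  sm <- summarize_cohort(res)
  expect_equal(sm$stratum, c("total", "F", "M", "18-29", "30-60", "61-90"))
  # bracket ns sum to the total; sex ns too
  expect_equal(sum(sm$n[4:6]), sm$n[1])
  expect_equal(sum(sm$n[2:3]), sm$n[1])
  expect_true(all(sm$sd_acr_ref >= 0, na.rm = TRUE))
  # sample sd (n - 1): check the total row against stats::sd
  expect_equal(sm$sd_acr_ref[1], sd(res$acr_ref))
  expect_equal(sm$mean_acr_ref[1], mean(res$acr_ref))
  # permutation invariance
  perm <- res[sample(nrow(res)), ]
  expect_equal(summarize_cohort(perm), sm)
})

test_that("empty strata report n = 0 with no statistics", {
  roster <- make_roster(ages = c(65, 70, 72, 75, 78, 80, 85))
  sm <- summarize_cohort(evaluate_sessions(roster))
  young_row <- sm[sm$stratum == "18-29", ]
  expect_equal(young_row$n, 0)
  expect_true(is.na(young_row$mean_acr_ref))
  expect_true(is.na(young_row$p.value))
  f_row <- sm[sm$stratum == "F", ]
  expect_equal(f_row$n, 0)
})

test_that("dose-ratio identity drives stratum percent change (property)", {
  # single-sex cohort with a flat young bracket: every 18-29 patient sits in
  # a young group, so the bracket reduction is the dose reduction
  roster <- make_roster(ages = c(20, 22, 25, 65, 70, 75, 80),
                        activity = 300, scan_time = 1200)
  res <- evaluate_sessions(apply_algo(roster), table = flat_decreasing_table())
  # per-patient: acr_algo / acr_ref equals the activity ratio exactly
  expect_equal(res$acr_algo / res$acr_ref,
               res$activity_algo_mbq / res$activity_mbq)
  sm <- summarize_cohort(res)
  expect_equal(sm$pct_change[sm$stratum == "18-29"],
               100 * (1 - 240 / 300))  # exact 20% (300 * 0.8 = 240, no floor loss)
})

test_that("single-patient and all-middle cohorts show zero change", {
  suppressWarnings({
    one <- evaluate_sessions(make_roster(ages = 50))
  })
  expect_equal(one$pct_change, 0)
  sm <- summarize_cohort(one)
  expect_equal(sm$pct_change[sm$stratum == "total"], 0)
  # k = 0 scheme: everyone middle
  res0 <- evaluate_sessions(make_roster(), scheme = algo_scheme(group_size = 0))
  expect_true(all(res0$pct_change == 0))
})

test_that("session table summarises each session from unrounded means", {
  res <- evaluate_sessions(worked())
  st <- session_table(res)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_female, 4)
  expect_equal(st$n_male, 6)
  expect_equal(st$age_min, 19)
  expect_equal(st$age_max, 81)
  expect_equal(st$pct_decrease,
               percent_change(mean(res$acr_ref), mean(res$acr_algo)))
  # two identical sessions -> two identical rows
  r2 <- make_roster(session_id = "A")
  r2b <- make_roster(session_id = "B")
  both <- evaluate_sessions(dplyr::bind_rows(r2, r2b))
  st2 <- session_table(both)
  expect_equal(nrow(st2), 2)
  expect_equal(dplyr::select(st2[1, ], -session_id),
               dplyr::select(st2[2, ], -session_id))
  # f = 0 scheme -> zero percent decrease
  st0 <- session_table(evaluate_sessions(r2, scheme = algo_scheme(fraction = 0)))
  expect_equal(st0$pct_decrease, 0)
})

test_that("session risk totals fall when young coefficients dominate old", {
  # calibrated table: every young-group coefficient exceeds every old-group
  # coefficient in the worked session, so total risk must fall
  res <- evaluate_sessions(worked())
  tab <- default_risk_table()
  young_min <- min(coefficient_at(tab, res$age[res$group == "young"],
                                  res$sex[res$group == "young"]))
  old_max <- max(coefficient_at(tab, res$age[res$group == "old"],
                                res$sex[res$group == "old"]))
  expect_gt(young_min, old_max)
  expect_lt(sum(res$acr_algo), sum(res$acr_ref))
  # and on simulated sessions satisfying the same dominance condition
  sim <- evaluate_sessions(generate_cohort(cohort_config(n_sessions = 5),
                                           seed = 19))
  dominated <- sim |>
    dplyr::group_by(session_id) |>
    dplyr::filter(min(acr_ref[group == "young"] / ed_ref_msv[group == "young"]) >
                    max(acr_ref[group == "old"] / ed_ref_msv[group == "old"])) |>
    dplyr::ungroup()
  per_sess <- dominated |>
    dplyr::group_by(session_id) |>
    dplyr::summarise(drop = sum(acr_ref) - sum(acr_algo), .groups = "drop")
  expect_gt(nrow(per_sess), 0)
  expect_true(all(per_sess$drop > 0))
})

test_that("summary JSON writer emits one object per stratum", {
  sm <- summarize_cohort(evaluate_sessions(worked()))
  path <- withr::local_tempfile(fileext = ".json")
  write_summary_json(sm, path)
  parsed <- jsonlite::read_json(path)
  expect_setequal(names(parsed), c("total", "F", "M", "18-29", "30-60", "61-90"))
  expect_equal(parsed$total$n, 10)
})
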