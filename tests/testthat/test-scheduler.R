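test_that("group selection matches the worked session", {
  roster <- read_roster(agedose_example("worked_session.csv"))
  grp <- select_groups(roster, k = 3)
  expect_equal(sort(grp$age[grp$group == "young"]), c(19, 29, 51))
  expect_equal(sort(grp$age[grp$group == "old"]), c(77, 79, 81))
  expect_equal(sort(grp$age[grp$group == "middle"]), c(63, 67, 70, 76))
  # original roster order preserved
  expect_equal(grp$patient_id, roster$patient_id)
})

test_that("group selection degrades gracefully and respects ties", {
  # n = 7, k = 3: minimal full split
  g7 <- select_groups(make_roster(), k = 3)
  expect_equal(sum(g7$group == "young"), 3)
  expect_equal(sum(g7$group == "middle"), 1)
  expect_equal(sum(g7$group == "old"), 3)
  # n = 1: k shrinks to 0, sole patient is middle
  expect_warning(g1 <- select_groups(make_roster(ages = 50), k = 3),
                 "shrinking k")
  expect_equal(g1$group, "middle")
  # n = 6, k = 3 -> k = 2
  expect_warning(g6 <- select_groups(make_roster(ages = c(20, 30, 40, 50, 60, 70)),
                                     k = 3), "shrinking k")
  expect_equal(sum(g6$group == "young"), 2)
  expect_equal(sum(g6$group == "old"), 2)
  # strict mode errors instead
  expect_error(select_groups(make_roster(ages = 50), k = 3, strict = TRUE),
               "fewer than")
  expect_error(select_groups(make_roster(), k = -1), "non-negative")
  # age ties at the boundary: stable roster order decides
  tied <- make_roster(ages = c(40, 40, 40, 40, 40, 40, 40))
  gt <- select_groups(tied, k = 3)
  expect_equal(gt$group, c("young", "young", "young", "middle",
                           "old", "old", "old"))
})

test_that("the reallocation reproduces the published worked arithmetic", {
  # the in-text example: young doses 250/280/310 -> 200/224/248
  roster <- make_roster(ages = c(20, 25, 28, 50, 55, 60, 70, 75, 80),
                        activity = 300)
  roster$activity_mbq[1:3] <- c(250, 280, 310)
  planned <- apply_algo(roster)
  expect_equal(planned$activity_algo_mbq[1:3], c(200, 224, 248))
  # and the corresponding old-rule doses 250/280/310 -> 300/336/372
  roster$activity_mbq[7:9] <- c(250, 280, 310)
  planned <- apply_algo(roster)
  expect_equal(planned$activity_algo_mbq[7:9], c(300, 336, 372))
})

test_that("floor truncation matches every modified worked-session cell", {
  ws <- worked()
  planned <- apply_algo(read_roster(agedose_example("worked_session.csv")))
  expect_equal(planned$activity_algo_mbq, ws$activity_algo_mbq)
  # scan times: all printed cells except the first row's (internally
  # inconsistent in the source table: 1211 * 1.2 = 1453.2)
  expect_equal(planned$scan_time_algo_s[-1], ws$scan_time_algo_s[-1])
  expect_equal(planned$scan_time_algo_s[1], 1453)
})

test_that("identity scheme and invariants", {
  roster <- make_roster()
  # f = 0 leaves every plan unchanged
  p0 <- apply_algo(roster, algo_scheme(fraction = 0))
  expect_equal(p0$activity_algo_mbq, roster$activity_mbq)
  expect_equal(p0$scan_time_algo_s, roster$scan_time_s)
  # count, identity and order preservation on simulated sessions
  sim <- generate_cohort(cohort_config(n_sessions = 4), seed = 31)
  planned <- apply_algo(sim)
  expect_equal(planned$patient_id, sim$patient_id)
  expect_equal(nrow(planned), nrow(sim))
  expect_true(all(planned$activity_algo_mbq >= 1))
  expect_true(all(planned$scan_time_algo_s >= 1))
  expect_true(all(planned$activity_algo_mbq ==
                    as.integer(planned$activity_algo_mbq)))
  # middle patients untouched
  mid <- planned$group == "middle"
  expect_equal(planned$activity_algo_mbq[mid], planned$activity_mbq[mid])
})

test_that("pre-truncation activity shift matches the closed form (property)", {
  f <- 0.2
  for (seed in c(41, 42, 43)) {
    sim <- generate_cohort(cohort_config(n_sessions = 3), seed = seed)
    planned <- apply_algo(sim)
    per_session <- planned |>
      dplyr::group_by(session_id) |>
      dplyr::summarise(
        delta = sum(activity_algo_mbq) - sum(activity_mbq),
        expected = f * (sum(activity_mbq[group == "old"]) -
                          sum(activity_mbq[group == "young"])),
        k = sum(group == "old"), .groups = "drop")
    # post-truncation deviation from the closed form stays below 2k MBq
    expect_true(all(abs(per_session$delta - per_session$expected) <
                      2 * per_session$k))
  }
})

test_that("modified counting statistic scales by 1 - f^2 before truncation", {
  f <- 0.2
  expect_equal((1 - f) * (1 + f), 0.96)
  roster <- make_roster()
  planned <- apply_algo(roster, algo_scheme(fraction = f))
  mod <- planned$group != "middle"
  pre_trunc <- planned$activity_mbq[mod] * planned$scan_time_s[mod] * 0.96
  post <- planned$activity_algo_mbq[mod] * planned$scan_time_algo_s[mod]
  # truncation only ever reduces, and by less than one unit in each factor
  expect_true(all(post <= pre_trunc + 1e-6))
  expect_true(all(post / pre_trunc > 0.99))
})

test_that("scheme validation and zero-driving schemes error", {
  expect_error(algo_scheme(fraction = 1), "fraction")
  expect_error(algo_scheme(fraction = -0.1), "fraction")
  expect_error(algo_scheme(group_size = -1), "group_size")
  tiny <- make_roster(activity = 1, scan_time = 1)
  expect_error(apply_algo(tiny, algo_scheme(fraction = 0.9)),
               "zero")
})

test_that("scheme config reader applies defaults and overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fraction: 0.1", "group_size: 2"), path)
  sc <- read_scheme_config(path)
  expect_equal(sc$fraction, 0.1)
  expect_equal(sc$group_size, 2L)
  expect_equal(sc$truncation, "floor")
})
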