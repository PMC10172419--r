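# Shared fixtures and independent oracles for the test suite.

# A minimal roster built in code: ages chosen so the young/middle/old split
# is unambiguous under k = 3.
make_roster <- function(ages = c(25, 40, 50, 60, 65, 70, 80),
                        session_id = "T1",
                        activity = 300, scan_time = 1200,
                        sex = "M") {
  n <- length(ages)
  tibble::tibble(
    session_id = session_id,
    patient_id = sprintf("%s-P%02d", session_id, seq_len(n)),
    sex = rep_len(sex, n),
    age = ages,
    weight_kg = 70,
    activity_mbq = rep_len(activity, n),
    scan_time_s = rep_len(scan_time, n)
  )
}

# A smooth, strictly age-decreasing risk table covering [18, 90] for both
# sexes, female above male.
flat_decreasing_table <- function() {
  ages <- seq(18, 90, by = 8)
  risk_table(tibble::tibble(
    sex = rep(c("M", "F"), each = length(ages)),
    age = rep(ages, 2),
    coefficient_per_msv = c(0.012 - 0.0001 * ages, 0.015 - 0.0001 * ages)
  ))
}

# Independent paired-t oracle: the difference formula coded from scratch.
brute_paired_t <- function(ref, algo) {
  d <- ref - algo
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, df = n - 1,
       p.value = 2 * pt(-abs(t), df = n - 1))
}

# Independent lifetable oracle: explicit double loop over attained ages,
# no vectorisation shared with the implementation.
brute_lar <- function(params, dose, e, sex) {
  beta <- if (sex == "M") params$beta_m else params$beta_f
  surv <- as.data.frame(params$survival)
  S_e <- approx(surv$age, surv$S, xout = e, rule = 2)$y
  e_star <- (min(e, 30) - 30) / 10
  total <- 0
  for (i in seq_len(nrow(surv))) {
    a <- surv$age[i]
    if (a > e && a >= e + params$latency_y && a <= params$max_age) {
      m <- (beta * dose / params$ddref) * exp(params$gamma * e_star) *
        (a / 60)^params$eta
      total <- total + m * surv$S[i] / S_e
    }
  }
  total
}

worked <- function() worked_session()
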