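test_that("subgroup comparison: identical values give p in the no-signal regime", {
  co <- generate_cohort(cohort_spec(seed = 2))
  co$auccsh_total <- 0.5
  res <- subgroup_compare(co, "event", "auccsh_total")
  expect_equal(res$p, 1)
  expect_equal(res$mean1, res$mean2)
  expect_equal(res$test, "degenerate")
})

test_that("subgroup comparison has power at the published effect size", {
  # event 0.410 +/- 0.062 vs non-event 0.515 +/- 0.101 at n = 19 + 19
  set.seed(61)
  rej <- replicate(200, {
    co <- data.frame(
      event = rep(c(1, 0), each = 19),
      auccsh_total = c(rnorm(19, 0.410, 0.062), rnorm(19, 0.515, 0.101)))
    subgroup_compare(co, "event", "auccsh_total")$p < 0.05
  })
  expect_gt(mean(rej), 0.8)
})

test_that("subgroup comparison rejects at ~alpha under permuted labels", {
  co <- generate_cohort(cohort_spec(seed = 33))
  set.seed(34)
  rej <- replicate(400, {
    co$g <- sample(co$event)
    subgroup_compare(co, "g", "auccsh_total")$p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("univariate Cox: null covariate gives HR near 1 with covering CI", {
  co <- generate_cohort(cohort_spec(n_patients = 3000, seed = 14))
  res <- univariate_cox(co, "mycn")  # no planted MYCN effect
  expect_equal(res$hr, 1, tolerance = 0.15)
  expect_lte(res$ci_low, 1)
  expect_gte(res$ci_high, 1)
})

test_that("univariate Cox matches the closed-form rate ratio without censoring", {
  # exponential times, binary covariate, no censoring: the MLE of the
  # rate ratio is (d1/T1)/(d0/T0)
  spec <- cohort_spec(n_patients = 2000, seed = 44,
                      log_hr = c(bmi = log(3)),
                      baseline_hazard = 0.03,
                      censor_horizon_months = 1e6)
  co <- generate_cohort(spec)
  expect_true(all(co$event == 1))
  d1 <- sum(co$event[co$bmi == 1]); t1 <- sum(co$followup_months[co$bmi == 1])
  d0 <- sum(co$event[co$bmi == 0]); t0 <- sum(co$followup_months[co$bmi == 0])
  rate_ratio <- (d1 / t1) / (d0 / t0)
  res <- univariate_cox(co, "bmi")
  expect_equal(res$hr, rate_ratio, tolerance = 0.05)
  expect_equal(res$hr, 3, tolerance = 0.15)
})

test_that("backward elimination boundary thresholds retain all or none", {
  co <- generate_cohort(cohort_spec(seed = 3))
  cand <- c("bmi", "mycn", "del_11q")
  keep_all <- multivariate_cox_backward(co, cand, p_remove = 1)
  expect_setequal(keep_all$retained, cand)
  expect_equal(nrow(keep_all$steps), 0)
  keep_none <- multivariate_cox_backward(co, cand, p_remove = 0)
  expect_length(keep_none$retained, 0)
  expect_equal(nrow(keep_none$final), 0)
  expect_equal(nrow(keep_none$steps), length(cand))
})

test_that("backward elimination keeps a planted effect over pure noise", {
  set.seed(71)
  kept_signal <- 0; kept_noise <- 0
  for (i in 1:10) {
    co <- generate_cohort(cohort_spec(n_patients = 600, seed = 1000 + i,
                                      log_hr = c(bmi = log(4.677))))
    co$noise <- rbinom(nrow(co), 1, 0.5)
    mv <- multivariate_cox_backward(co, c("bmi", "noise"), p_remove = 0.10)
    kept_signal <- kept_signal + ("bmi" %in% mv$retained)
    kept_noise <- kept_noise + ("noise" %in% mv$retained)
  }
  expect_gte(kept_signal, 9)
  expect_lte(kept_noise, 3)
})

test_that("Cox rejects degenerate inputs and flags monotone likelihood", {
  co <- generate_cohort(cohort_spec(seed = 6))
  co$const <- 1
  expect_error(univariate_cox(co, "const"), "constant")
  no_ev <- co; no_ev$event <- 0
  expect_error(univariate_cox(no_ev, "bmi"), "at least one event")
  # perfectly separating covariate: diagnostic reported, not a crash
  sep <- co
  sep$sep_var <- as.integer(sep$event == 1)
  res <- univariate_cox(sep, "sep_var")
  expect_true(nzchar(res$diagnostic) || res$ci_high > 100)
})

test_that("Youden cutoff: separation returns the gap midpoint, null gives J ~ 0", {
  co <- data.frame(event = rep(c(1, 0), each = 10),
                   auccsh_total = c(runif(10, 0.2, 0.42), runif(10, 0.48, 0.9)))
  co$auccsh_total[co$event == 1][1] <- 0.42   # fix the gap edges exactly
  co$auccsh_total[co$event == 0][1] <- 0.48
  res <- roc_optimal_cutoff(co)
  expect_equal(res$cutoff, 0.45)
  expect_equal(res$youden_j, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)

  set.seed(52)
  null_j <- replicate(100, {
    co <- data.frame(event = rep(c(1, 0), each = 50),
                     auccsh_total = runif(100))
    roc_optimal_cutoff(co)$youden_j
  })
  expect_lt(median(null_j), 0.3)  # small-sample optimism only

  expect_error(roc_optimal_cutoff(data.frame(event = rep(1, 5),
                                             auccsh_total = runif(5))),
               "degenerate")
})

test_that("Youden cutoff agrees with an independent ROC implementation", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 15))
  res <- roc_optimal_cutoff(co)
  r <- pROC::roc(co$event, co$auccsh_total, direction = ">", quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden")
  # pROC may return several tied bests; ours must match one to J precision
  expect_true(any(abs(best$threshold - res$cutoff) < 1e-9) ||
                abs(max(best$sensitivity + best$specificity - 1) -
                      res$youden_j) < 1e-9)
})

test_that("Kaplan-Meier without censoring equals the empirical survival", {
  co <- data.frame(followup_months = c(2, 4, 4, 7, 10, 12),
                   event = rep(1, 6))
  km <- km_logrank(co, rep("all", 6))
  s <- summary(km$fit)
  n <- 6
  emp <- sapply(s$time, function(tt) mean(co$followup_months > tt))
  expect_equal(s$surv, emp, tolerance = 1e-12)
})

test_that("log-rank p agrees with a brute-force permutation test at small n", {
  co <- generate_cohort(cohort_spec(n_patients = 16, seed = 27))
  g <- co$bmi
  obs <- km_logrank(co, g)
  set.seed(28)
  perm <- replicate(10000, km_logrank(co, sample(g))$chisq)
  p_perm <- mean(perm >= obs$chisq - 1e-12)
  expect_lt(abs(p_perm - obs$p), 0.04)
})

test_that("all-censored cohorts give an undefined log-rank, reported not raised", {
  co <- generate_cohort(cohort_spec(seed = 9))
  co$event <- 0
  km <- km_logrank(co, co$bmi)
  expect_true(is.na(km$p))
  expect_match(km$note, "censored")
})

test_that("risk stratification partitions the cohort by the two-factor rule", {
  co <- generate_cohort(cohort_spec(seed = 18))
  g <- stratify_risk_groups(co, cutoff = 0.49)
  expect_equal(length(g), nrow(co))
  expect_false(anyNA(g))
  low <- co$auccsh_total <= 0.49
  bmi <- co$bmi == 1
  expect_true(all(g[!low & !bmi] == "I"))
  expect_true(all(g[xor(low, bmi)] == "II"))
  expect_true(all(g[low & bmi] == "III"))
  expect_equal(sum(table(g)), nrow(co))
})

test_that("stratified groups order survival in the planted direction", {
  co <- generate_cohort(cohort_spec(n_patients = 600, seed = 55))
  g <- stratify_risk_groups(co)
  km <- km_logrank(co, g)
  expect_lt(km$p, 0.01)
  med <- sapply(levels(g), function(lv)
    mean(co$event[g == lv]))
  expect_lt(med[["I"]], med[["II"]])
  expect_lt(med[["II"]], med[["III"]])
})

test_that("baseline table reproduces exact categorical percentages", {
  co <- data.frame(
    age = c(rnorm(19, 3.3, 2.1), rnorm(19, 4.0, 2.2)),
    inss_stage = rep(c(1, 2, 3, 4), c(2, 1, 6, 29)),
    sex = rep(c("male", "female"), c(14, 24)),
    event = rep(c(0, 1), c(19, 19)))
  bt <- baseline_table(co, continuous = "age",
                       categorical = c("sex", "inss_stage"))
  stage4 <- bt[bt$variable == "inss_stage" & bt$level == "4", ]
  expect_equal(stage4$total, "29 (76.3%)")
  male <- bt[bt$variable == "sex" & bt$level == "male", ]
  expect_equal(male$total, "14 (36.8%)")
  expect_true(all(is.finite(bt$p)))
})

test_that("baseline table flags degenerate columns and balanced factors", {
  n <- 2000
  co <- data.frame(
    age = rep(5, n),                       # constant: degenerate
    sex = rep(c("male", "female"), n / 2), # exactly balanced across events
    event = rep(c(0, 1), each = n / 2))
  bt <- baseline_table(co, continuous = "age", categorical = "sex")
  age_row <- bt[bt$variable == "age", ]
  expect_true(is.na(age_row$p))
  expect_match(age_row$note, "degenerate")
  sex_p <- unique(bt$p[bt$variable == "sex"])
  expect_gt(sex_p, 0.9)
})
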