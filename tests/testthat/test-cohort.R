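test_that("identical seed and config give identical cohorts", {
  cfg <- cohort_config(n_children = 120)
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$children, b$children)
  expect_identical(a$daily, b$daily)
  c2 <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$children, c2$children))
})

test_that("degenerate law returns the ilr-inverse of the log-mean every day", {
  cfg <- cohort_config(
    n_children = 5,
    behavior = list(
      y5 = list(logmean = log(c(72, 347, 487, 535)),
                child_logsd = rep(0, 4), day_logsd = rep(0, 4),
                weekend_logshift = rep(0, 4), child_cor_inact_sleep = 0),
      y8 = cohort_config()$behavior$y8),
    p_valid_day = 1)
  set.seed(1)
  days <- generate_daily_minutes(cfg, n_days = 4, day_type = "weekday")
  target <- close_composition(c(72, 347, 487, 535))
  for (i in 1:4)
    expect_equal(unname(unlist(days[i, mb_behaviors()])), unname(target),
                 tolerance = 1e-12)
})

test_that("validity rule requires two weekdays and one weekend day", {
  mk <- function(types, valid) data.frame(day_type = types, valid = valid)
  wk <- c(rep("weekday", 5), rep("weekend", 2))
  expect_true(apply_validity_rules(mk(wk, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))))
  expect_false(apply_validity_rules(mk(wk, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))))
  expect_false(apply_validity_rules(mk(wk, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))))
})

test_that("weekly averaging uses 5:2 weekday:weekend weighting", {
  days <- data.frame(
    day_type = c("weekday", "weekday", "weekend"),
    valid = TRUE,
    mvpa = c(55, 65, 120), lpa = c(345, 335, 340),
    inactivity = c(500, 500, 480), sleep = c(540, 540, 500))
  w <- weighted_week_average(days)
  expect_equal(unname(w["mvpa"]), (5 * 60 + 2 * 120) / 7, tolerance = 1e-12)
  expect_equal(sum(w), 1440)
  # convexity: between the weekday and weekend means component-wise
  wd <- colMeans(days[1:2, mb_behaviors()])
  we <- unlist(days[3, mb_behaviors()])
  expect_true(all(w >= pmin(wd, we) - 1e-9 & w <= pmax(wd, we) + 1e-9))

  one_day <- days[c(1, 3), ]
  one_day[, mb_behaviors()] <- rep(c(60, 340, 500, 540), each = 2)
  expect_equal(unname(weighted_week_average(one_day)), c(60, 340, 500, 540))

  no_we <- days[1:2, ]
  expect_error(weighted_week_average(no_we), "weekend")
})

test_that("vectorized generator agrees with the per-child weighting op", {
  coh <- simulate_cohort(cohort_config(n_children = 60), seed = 7)
  kids <- coh$children
  for (id in head(kids$child_id[kids$valid_y5], 5)) {
    days <- coh$daily[coh$daily$child_id == id & coh$daily$timepoint == "y5", ]
    w <- weighted_week_average(days[!is.na(days$mvpa), ])
    expect_equal(unname(w),
                 unname(unlist(kids[kids$child_id == id, parts_y5])),
                 tolerance = 1e-9)
  }
  # every generated valid day closes to 1440
  v <- coh$daily[coh$daily$valid, mb_behaviors()]
  expect_true(all(abs(rowSums(v) - 1440) < 1e-6))
})

test_that("domain day average and total SVT follow their formulas", {
  expect_equal(domain_day_average(70, 70), 70)
  expect_equal(domain_day_average(0, 140), 40)
  expect_equal(domain_day_average(60, 120), 540 / 7)
  expect_error(domain_day_average(-1, 10), "non-negative")

  expect_equal(total_svt(57, 10, 40, 7), 114)
  expect_equal(total_svt(0, 0, 0, 0), 0)
  expect_equal(total_svt(88, 20, 64, 9), 181)
  expect_error(total_svt(-1, 0, 0, 0), "non-negative")
})

test_that("null effects leave outcomes unrelated to the composition", {
  coh <- simulate_cohort(fast_config(800, effects = null_effects()), seed = 17)
  fit <- coda_lm(academic_latent ~ 1, coh$children, parts = parts_y5)
  ci <- confint(fit, "ilr1")
  expect_true(ci[1] < 0 && ci[2] > 0 || abs(coef(fit)["ilr1"]) < 0.2)
  expect_gt(joint_composition_test(fit)$p.value, 0.001)
})

test_that("larger outcome noise widens the ilr1 confidence interval", {
  eff <- null_effects()
  w1 <- w2 <- NULL
  coh1 <- simulate_cohort(fast_config(500, effects = eff,
                                      noise_sd = c(ef = 0.7, academic = 0.5)),
                          seed = 23)
  coh2 <- simulate_cohort(fast_config(500, effects = eff,
                                      noise_sd = c(ef = 0.7, academic = 2.0)),
                          seed = 23)
  f1 <- coda_lm(academic_latent ~ 1, coh1$children, parts = parts_y5)
  f2 <- coda_lm(academic_latent ~ 1, coh2$children, parts = parts_y5)
  w1 <- diff(confint(f1, "ilr1")[1, ])
  w2 <- diff(confint(f2, "ilr1")[1, ])
  expect_gt(w2, w1)
})

test_that("timepoint missingness drives per-model sample sizes", {
  coh <- simulate_cohort(cohort_config(n_children = 1000,
                                       p_measured = c(y5 = 1, y8 = 0.8),
                                       p_valid_day = 1),
                         seed = 31)
  expect_true(all(coh$children$valid_y5))
  frac <- mean(coh$children$valid_y8)
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 1000))
})
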