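test_that("reallocation moves exactly the requested minutes", {
  expect_equal(reallocate(MEAN_Y5, "mvpa", "sleep", 30),
               c(mvpa = 38, lpa = 343, inactivity = 487, sleep = 572))
  expect_equal(reallocate(MEAN_Y5, "mvpa", "sleep", 0), MEAN_Y5)
  expect_equal(reallocate(MEAN_Y8, "sleep", "mvpa", 30),
               c(mvpa = 97, lpa = 336, inactivity = 509, sleep = 497))
  expect_equal(sum(reallocate(MEAN_Y5, "lpa", "inactivity", 45)), 1440)
  expect_error(reallocate(MEAN_Y5, "mvpa", "sleep", 68), "infeasible")
  expect_error(reallocate(MEAN_Y5, "mvpa", "mvpa", 5), "differ")
})

test_that("clr coefficients are reconstructed from rotation-wise estimates", {
  g <- reconstruct_clr_coefficients(B_Y5)
  expect_equal(unname(g$gamma),
               c(-0.3178, 0.0693, -0.2520, 0.5006), tolerance = 1e-3)
  expect_equal(sum(g$gamma), 0, tolerance = 1e-14)
  expect_lt(abs(g$sum_dev), 0.002)

  g8 <- reconstruct_clr_coefficients(B_Y8)
  expect_equal(g8$sum_dev, sqrt(3) / 2 * 0.001, tolerance = 1e-10)

  sym <- reconstruct_clr_coefficients(c(1, -1 / 3, -1 / 3, -1 / 3))
  expect_equal(unname(sym$gamma),
               sqrt(3) / 2 * c(1, -1 / 3, -1 / 3, -1 / 3), tolerance = 1e-12)
  expect_equal(sym$sum_dev, 0, tolerance = 1e-12)
})

test_that("reconstruction inverts the rotation table of a fitted model", {
  coh <- simulate_cohort(fast_config(300, effects = null_effects()), seed = 91)
  rt <- rotation_table(academic_latent ~ sex, coh$children, parts = parts_y5)
  g <- reconstruct_clr_coefficients(rt$estimate, parts = parts_y5)
  # the model's clr coefficients from its MVPA-lead ilr coefficients
  fit <- attr(rt, "fits")[[1]]
  b_ilr <- coef(fit)[fit$ilr_names]
  gamma_direct <- drop(t(fit$basis$V) %*% b_ilr)
  expect_equal(unname(g$gamma), unname(gamma_direct[parts_y5]), tolerance = 1e-10)
})

test_that("predicted differences are zero at the base and basis invariant", {
  coh <- simulate_cohort(fast_config(300, effects = null_effects()), seed = 92)
  base <- setNames(MEAN_Y5, parts_y5)
  new <- setNames(reallocate(MEAN_Y5, "mvpa", "sleep", 30), parts_y5)
  deltas <- vapply(mb_behaviors(), function(ld) {
    f <- coda_lm(academic_latent ~ sex, coh$children, parts = parts_y5,
                 lead = paste0(ld, "_y5"))
    est <- predict_difference(f, base, new)
    if (ld == "mvpa") {
      same <- predict_difference(f, base, base)
      expect_equal(same$delta, 0, tolerance = 1e-12)
      expect_equal(same$se, 0, tolerance = 1e-12)
    }
    est$delta
  }, numeric(1))
  expect_true(all(abs(deltas - deltas[1]) < 1e-10))
})

test_that("published substitution values are reproduced from the printed table", {
  g5 <- reconstruct_clr_coefficients(B_Y5)
  g8 <- reconstruct_clr_coefficients(B_Y8)
  expect_equal(predict_difference(g5, MEAN_Y5,
                                  reallocate(MEAN_Y5, "mvpa", "sleep", 30))$delta,
               0.214, tolerance = 0.01)
  expect_equal(predict_difference(g5, MEAN_Y5,
                                  reallocate(MEAN_Y5, "sleep", "mvpa", 30))$delta,
               -0.145, tolerance = 0.01)
  expect_equal(predict_difference(g8, MEAN_Y8,
                                  reallocate(MEAN_Y8, "mvpa", "sleep", 30))$delta,
               0.170, tolerance = 0.01)
  expect_equal(predict_difference(g8, MEAN_Y8,
                                  reallocate(MEAN_Y8, "sleep", "mvpa", 30))$delta,
               -0.117, tolerance = 0.01)
})

test_that("forward and reverse reallocations are asymmetric except in the limit", {
  g5 <- reconstruct_clr_coefficients(B_Y5)
  fwd30 <- predict_difference(g5, MEAN_Y5,
                              reallocate(MEAN_Y5, "mvpa", "sleep", 30))$delta
  rev30 <- predict_difference(g5, MEAN_Y5,
                              reallocate(MEAN_Y5, "sleep", "mvpa", 30))$delta
  expect_gt(abs(fwd30 + rev30), 0.05)  # not mirror images at 30 min
  fwd_eps <- predict_difference(g5, MEAN_Y5,
                                reallocate(MEAN_Y5, "mvpa", "sleep", 0.01))$delta
  rev_eps <- predict_difference(g5, MEAN_Y5,
                                reallocate(MEAN_Y5, "sleep", "mvpa", 0.01))$delta
  expect_equal(fwd_eps, -rev_eps, tolerance = 1e-3)
})

test_that("the substitution surface covers the grid and flags infeasible cells", {
  g5 <- reconstruct_clr_coefficients(B_Y5)
  surf <- substitution_surface(g5, base = MEAN_Y5)
  expect_identical(nrow(surf), 12L * 12L)
  expect_true(all(table(surf$from, surf$to)[
    cbind(rep(1:4, each = 3),
          unlist(lapply(1:4, function(i) setdiff(1:4, i))))] == 12))
  # durations of 60 min exhaust nothing at this base (min part is 68)
  expect_true(all(surf$feasible))

  low_mvpa <- c(mvpa = 40, lpa = 371, inactivity = 487, sleep = 542)
  surf2 <- substitution_surface(g5, base = low_mvpa)
  bad <- surf2[surf2$from == "mvpa" & surf2$minutes >= 40, ]
  expect_true(all(!bad$feasible))
  expect_true(all(is.na(bad$delta)))
  expect_identical(nrow(surf2), 144L)  # infeasible cells marked, not dropped

  # |delta| is monotone in duration for a fixed pair (fixed-sign contrast)
  for (pair in list(c("mvpa", "sleep"), c("inactivity", "lpa"))) {
    dd <- surf[surf$from == pair[1] & surf$to == pair[2], ]
    expect_true(all(diff(abs(dd$delta)) > 0))
  }
})

test_that("delta and bootstrap intervals agree on a fitted model", {
  coh <- simulate_cohort(fast_config(250, effects = null_effects()), seed = 93)
  fit <- coda_lm(academic_latent ~ sex, coh$children, parts = parts_y5)
  base <- compositional_mean(fit$composition)
  new <- reallocate(base, parts_y5[1], parts_y5[4], 30)
  d1 <- predict_difference(fit, base, new)
  expect_true(d1$ci_low <= d1$delta && d1$delta <= d1$ci_high)
  set.seed(94)
  d2 <- predict_difference(fit, base, new, method = "bootstrap", B = 80)
  expect_equal(d2$delta, d1$delta, tolerance = 1e-12)
  expect_equal(d2$se, d1$se, tolerance = 0.6)  # same order of magnitude
})

test_that("surface defaults to the sample compositional mean reference", {
  coh <- simulate_cohort(fast_config(250, effects = null_effects()), seed = 95)
  fit <- coda_lm(academic_latent ~ 1, coh$children, parts = parts_y5)
  surf <- substitution_surface(fit, durations = c(10, 30))
  expect_equal(attr(surf, "base"),
               compositional_mean(fit$composition), tolerance = 1e-12)
  surf_a <- substitution_surface(fit, durations = c(10, 30),
                                 reference = "arithmetic")
  expect_equal(attr(surf_a, "base"),
               close_composition(colMeans(fit$composition)), tolerance = 1e-12)
})
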