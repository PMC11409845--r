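test_that("closure rescales proportionally and conserves the total", {
  expect_equal(close_composition(c(34, 171.5, 243.5, 271)),
               c(68, 343, 487, 542), ignore_attr = TRUE)
  expect_equal(close_composition(c(360, 360, 360, 360)),
               c(360, 360, 360, 360), ignore_attr = TRUE)
  # published arithmetic means sum to 1441; closure shaves the extra minute
  expect_equal(close_composition(c(72, 347, 487, 535)),
               c(72, 347, 487, 535) * 1440 / 1441, ignore_attr = TRUE)
  expect_error(close_composition(c(0, 0, 0, 0)), "degenerate")

  set.seed(11)
  m <- matrix(runif(400, 0.01, 900), ncol = 4)
  closed <- close_composition(m)
  expect_true(all(abs(rowSums(closed) - 1440) < 1e-9 * 1440))
})

test_that("multiplicative zero replacement preserves totals and ratios", {
  out <- zero_replace(c(0, 400, 500, 540), floor = 1)
  expect_equal(unname(out), c(1, 400, 500, 540) * c(1, rep(1439 / 1440, 3)))
  expect_equal(sum(out), 1440)
  # ratios of unaffected parts preserved
  expect_equal(out[2] / out[3], 400 / 500, ignore_attr = TRUE)

  x <- c(10, 400, 500, 530)
  expect_identical(unname(zero_replace(x)), x)

  out2 <- zero_replace(c(0, 0, 720, 720), floor = 1)
  expect_equal(unname(out2[1:2]), c(1, 1))
  expect_equal(sum(out2), 1440)

  expect_error(zero_replace(c(0, 0, 0, 3), floor = 1.1), "exceeds")
  expect_error(zero_replace(c(0, 1), floor = 0), "positive")
})

test_that("ilr coordinates match the printed pivot formula", {
  comp <- c(mvpa = 68, lpa = 343, inactivity = 487, sleep = 542)
  y <- ilr_transform(comp)
  # hand evaluation of sqrt(3/4) * (ln MVPA - mean(ln others))
  expect_equal(unname(y[1]),
               sqrt(3 / 4) * (log(68) - mean(log(c(343, 487, 542)))),
               tolerance = 1e-12)
  expect_equal(unname(y[1]), -1.6347, tolerance = 1e-4)
  expect_equal(unname(y[2]),
               sqrt(2 / 3) * (log(343) - mean(log(c(487, 542)))),
               tolerance = 1e-12)
  expect_equal(unname(y[3]), sqrt(1 / 2) * log(487 / 542), tolerance = 1e-12)

  expect_equal(unname(ilr_transform(c(360, 360, 360, 360))), c(0, 0, 0))
  expect_error(ilr_transform(c(0, 400, 500, 540)), "zero_replace")
})

test_that("ilr coordinates are scale invariant", {
  set.seed(21)
  x <- random_comp(50)
  for (c_ in c(10, 1 / 1440, 3.7))
    expect_equal(ilr_transform(x * c_), ilr_transform(x), tolerance = 1e-12)
})

test_that("ilr round-trips are exact to numerical precision", {
  b <- ilr_basis()
  expect_equal(unname(ilr_inverse(c(0, 0, 0))), rep(360, 4))
  x <- c(mvpa = 68, lpa = 343, inactivity = 487, sleep = 542)
  expect_equal(ilr_inverse(ilr_transform(x, b), b), x, tolerance = 1e-12)

  set.seed(31)
  comps <- random_comp(1000)
  y <- ilr_transform(comps, b)
  expect_equal(ilr_transform(ilr_inverse(y, b), b), y, tolerance = 1e-10)
  expect_equal(ilr_inverse(y, b), comps, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("basis rows are orthonormal sum-zero sequential binary contrasts", {
  for (lead in mb_behaviors()) {
    V <- ilr_basis(lead = lead)$V
    expect_equal(V %*% t(V), diag(3), ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(rowSums(V), c(0, 0, 0), ignore_attr = TRUE, tolerance = 1e-12)
    # row k: positive pivot weight, equal negative weights afterwards
    for (k in 1:3) {
      expect_gt(V[k, k], 0)
      expect_true(all(abs(V[k, (k + 1):4] - V[k, 4]) < 1e-12))
      if (k > 1) expect_equal(unname(V[k, 1:(k - 1)]), rep(0, k - 1))
    }
  }
})

test_that("rotations place the lead behavior in the ilr1 numerator", {
  b_sleep <- ilr_basis(lead = "sleep")
  expect_identical(b_sleep$parts[1], "sleep")
  x <- c(mvpa = 68, lpa = 343, inactivity = 487, sleep = 542)
  y1 <- ilr_transform(x, b_sleep)[1]
  expect_equal(unname(y1),
               sqrt(3 / 4) * (log(542) - mean(log(c(68, 343, 487)))),
               tolerance = 1e-12)
  expect_error(ilr_basis(lead = "napping"), "unknown")

  # lead-k first coordinate equals sqrt(D/(D-1)) times the k-th clr component
  set.seed(41)
  for (i in 1:20) {
    x <- drop(random_comp(1))
    names(x) <- mb_behaviors()
    cl <- clr_oracle(x)
    for (k in 1:4) {
      bk <- ilr_basis(lead = mb_behaviors()[k])
      expect_equal(unname(ilr_transform(x, bk)[1]), sqrt(4 / 3) * cl[[k]],
                   tolerance = 1e-10)
    }
  }
})

test_that("all rotations are isometric to the clr geometry", {
  set.seed(51)
  for (i in 1:20) {
    a <- setNames(drop(random_comp(1)), mb_behaviors())
    b <- setNames(drop(random_comp(1)), mb_behaviors())
    d_clr <- sqrt(sum((clr_oracle(a) - clr_oracle(b))^2))
    expect_equal(aitchison_dist(a, b), d_clr, tolerance = 1e-10)
    d_rot <- vapply(mb_behaviors(), function(ld) {
      bs <- ilr_basis(lead = ld)
      sqrt(sum((ilr_transform(a, bs) - ilr_transform(b, bs))^2))
    }, numeric(1))
    expect_true(all(abs(d_rot - d_clr) < 1e-10))
  }
})

test_that("aitchison distance is a scale-invariant metric", {
  x <- c(mvpa = 68, lpa = 343, inactivity = 487, sleep = 542)
  y <- c(mvpa = 90, lpa = 320, inactivity = 500, sleep = 530)
  expect_equal(aitchison_dist(x, x), 0)
  expect_equal(aitchison_dist(x, 2 * x), 0)
  expect_equal(aitchison_dist(x, y), aitchison_dist(y, x))
  expect_gt(aitchison_dist(x, y), 0)
})

test_that("compositional mean is the closed geometric mean", {
  x <- c(mvpa = 68, lpa = 343, inactivity = 487, sleep = 542)
  expect_equal(compositional_mean(rbind(x)), x, tolerance = 1e-12)

  two <- rbind(c(64, 343, 487, 546), c(72.25, 343, 487, 538.1))
  oracle <- exp(colMeans(log(two)))
  oracle <- oracle * 1440 / sum(oracle)
  expect_equal(unname(compositional_mean(two)), unname(oracle), tolerance = 1e-12)

  # simulation consistency: logistic-normal sample centered at x
  set.seed(61)
  b <- ilr_basis()
  y0 <- ilr_transform(x, b)
  draws <- matrix(rnorm(4000 * 3, sd = 0.2), ncol = 3) +
    matrix(y0, 4000, 3, byrow = TRUE)
  samp <- ilr_inverse(draws, b)
  cm <- compositional_mean(samp)
  expect_equal(unname(cm), unname(x), tolerance = 0.02)

  expect_error(compositional_mean(matrix(numeric(0), ncol = 4)), "empty")
})
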