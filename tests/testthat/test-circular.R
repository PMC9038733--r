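test_that("wrap180 matches a brute-force modular oracle and its boundary convention", {
  # oracle: among all representatives delta - 180k, pick the one in (-90, 90]
  oracle <- function(delta) {
    ks <- seq(floor(delta / 180) - 2, ceiling(delta / 180) + 2)
    reps <- delta - 180 * ks
    reps[reps > -90 & reps <= 90][1]
  }
  ints <- -1000:1000
  expect_equal(wrap180(ints), vapply(ints, oracle, numeric(1)))
  expect_identical(wrap180(0), 0)
  expect_identical(wrap180(178), -2)        # response 1 vs target 179
  expect_identical(wrap180(90), 90)
  expect_identical(wrap180(-90), 90)        # half-open boundary
  expect_equal(wrap180(13.7 + 180 * c(-3, 0, 7)), rep(wrap180(13.7), 3))
  expect_error(wrap180(NaN), "finite")
  expect_error(wrap180(Inf), "finite")
})

test_that("signed_error subtracts target from response on the orientation circle", {
  expect_identical(signed_error(45, 45), 0)
  expect_identical(signed_error(10, 170), 20)   # wraps across 180
  expect_identical(signed_error(100, 30), 70)
  # full enumeration against the modular oracle
  grid <- expand.grid(r = seq(1, 180, by = 7), t = seq(1, 180, by = 7))
  direct <- wrap180(grid$r - grid$t)
  expect_true(all(direct > -90 & direct <= 90))
  expect_equal(signed_error(grid$r, grid$t), direct)
})

test_that("sd_to_kappa inverts the closed-form kappa_to_sd and is monotone", {
  for (s in c(2, 5, 10, 20, 40)) {
    expect_equal(kappa_to_sd(sd_to_kappa(s)), s, tolerance = 1e-6)
  }
  sig <- seq(1, 90, length.out = 40)
  k <- sd_to_kappa(sig)
  expect_true(all(diff(k) < 0))                 # strictly decreasing
  expect_lt(sd_to_kappa(90), sd_to_kappa(89))
  expect_lt(sd_to_kappa(90), 0.05)              # near-uniform limit
  expect_error(sd_to_kappa(0), "\\(0, 90]")
  expect_error(sd_to_kappa(91), "\\(0, 90]")
})

test_that("vm_pdf_180 is a symmetric density that integrates to 1", {
  for (s in c(2, 8, 30, 89)) {
    q <- stats::integrate(function(x) vm_pdf_180(x, s), -90, 90,
                          rel.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-8)
  }
  x <- seq(-89, 90, by = 0.5)
  expect_equal(vm_pdf_180(x, 12), vm_pdf_180(-x, 12))
  # near the uniform limit the density flattens toward 1/180
  expect_equal(vm_pdf_180(c(-45, 0, 45, 90), 90),
               rep(1 / 180, 4), tolerance = 0.02)
  expect_gt(vm_pdf_180(0, 5), vm_pdf_180(10, 5))
})

test_that("rvm180 draws match the density they are meant to follow", {
  withr::with_seed(42, {
    x <- rvm180(2e4, mu = 50, sigma = 10)
    expect_true(all(x > 0 & x <= 180))
    err <- signed_error(x, 50)
    # binned empirical density vs bin-averaged pdf
    bw <- 10
    h <- hist(err, breaks = seq(-90, 90, by = bw), plot = FALSE)
    expected <- vapply(h$mids, function(m) {
      stats::integrate(function(x) vm_pdf_180(x, 10),
                       m - bw / 2, m + bw / 2)$value / bw
    }, numeric(1))
    se <- sqrt(expected / (length(err) * bw))
    expect_true(all(abs(h$density - expected) < 4 * se + 1e-4))
  })
})

test_that("mean_error and precision summarize wrapped errors", {
  expect_identical(mean_error(c(0, 0, 0)), 0)
  expect_identical(mean_error(c(-5, 5)), 0)
  expect_identical(mean_error(c(10, 20, 30)), 20)
  # circular variant agrees with linear for concentrated errors
  expect_equal(mean_error(c(10, 20, 30), type = "circular"), 20,
               tolerance = 1e-9)
  expect_error(mean_error(numeric(0)), "non-empty")

  e <- c(-12, -4, 0, 4, 12)
  expect_equal(precision(e), 1 / sd(e))
  expect_equal(precision(e, type = "variance"), 1 / var(e))
  expect_equal(precision(0.5 * e), precision(e) / 0.5)   # scaling property
  expect_error(precision(5), "at least 2")
  expect_error(precision(c(3, 3, 3)), "zero variance")
})

test_that("precision recovers the generating SD by Monte Carlo", {
  withr::with_seed(7, {
    e <- signed_error(rvm180(1e5, 0, 8), 0)
    expect_equal(precision(e), 1 / 8, tolerance = 0.02)
  })
})
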