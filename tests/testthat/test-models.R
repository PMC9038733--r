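test_that("pdf_standard combines the von Mises and uniform components", {
  tr <- one_trial()
  # pure guessing: flat density 1/180 everywhere
  p1 <- model_params(gamma = 1, sigma = 10)
  expect_equal(pdf_standard(seq(1, 180, by = 3), 40, p1),
               rep(1 / 180, 60))
  # no guessing, response at target: the von Mises mode
  p0 <- model_params(gamma = 0, sigma = 10)
  expect_equal(pdf_standard(40, 40, p0), vm_pdf_180(0, 10))
  # mixture arithmetic against the two component calls
  p <- model_params(gamma = 0.3, sigma = 10)
  expect_equal(pdf_standard(55, 40, p),
               0.7 * vm_pdf_180(15, 10) + 0.3 / 180)
})

test_that("the model family is strictly nested and collapses correctly", {
  tr <- one_trial()
  x <- seq(0.5, 180, by = 1)   # 180-point grid
  ps <- model_params(gamma = 0.2, sigma = 9)
  pl0 <- model_params(gamma = 0.2, sigma = 9, beta_loc = 0)
  pg0 <- model_params(gamma = 0.2, sigma = 9, beta_loc = 0, beta_glo = 0)
  std <- pdf_standard(x, tr$target_deg, ps)
  expect_equal(pdf_local(x, tr, pl0), std, tolerance = 1e-12)
  expect_equal(pdf_global_local(x, tr, pg0), std, tolerance = 1e-12)
  # beta_glo = 0: global-local equals local pointwise
  pl <- model_params(gamma = 0.1, sigma = 7, beta_loc = 0.2)
  pg <- model_params(gamma = 0.1, sigma = 7, beta_loc = 0.2, beta_glo = 0)
  expect_equal(pdf_global_local(x, tr, pg), pdf_local(x, tr, pl),
               tolerance = 1e-12)
  expect_equal(pdf_global_perpendicular(x, tr, pg), pdf_local(x, tr, pl),
               tolerance = 1e-12)
})

test_that("paired flankers reduce to two components with half weight", {
  tr <- one_trial(f1 = 30, f2 = 110)
  p <- model_params(gamma = 0.1, sigma = 8, beta_loc = 0.4)
  x <- seq(1, 180, by = 2.5)
  manual <- (1 - 0.1 - 0.4) * vm_pdf_180(signed_error(x, tr$target_deg), 8) +
    0.1 / 180 +
    0.4 * (vm_pdf_180(signed_error(x, 30), 8) +
             vm_pdf_180(signed_error(x, 110), 8)) / 2
  expect_equal(pdf_local(x, tr, p), manual, tolerance = 1e-12)
})

test_that("all flankers at the target collapse the local model onto the standard", {
  tr <- one_trial(target = 77, f1 = 77, f2 = 77)
  p <- model_params(gamma = 0.1, sigma = 8, beta_loc = 0.25)
  x <- seq(1, 180, by = 5)
  collapsed <- model_params(gamma = 0.1, sigma = 8)
  manual <- (1 - 0.1) * vm_pdf_180(signed_error(x, 77), 8) + 0.1 / 180
  expect_equal(pdf_local(x, tr, p), manual, tolerance = 1e-12)
})

test_that("no-target-weight mixtures are independent of the target", {
  tr1 <- one_trial(target = 10); tr2 <- one_trial(target = 150)
  p <- model_params(gamma = 0.5, sigma = 8, beta_loc = 0.3, beta_glo = 0.2)
  x <- seq(1, 180, by = 4)
  expect_equal(pdf_global_local(x, tr1, p), pdf_global_local(x, tr2, p))
})

test_that("model densities integrate to 1 over the orientation circle", {
  withr::with_seed(11, {
    for (i in 1:10) {
      tr <- one_trial(sample(180, 1), sample(180, 1), sample(180, 1),
                      sample(180, 1))
      w <- diff(c(0, sort(runif(3)), 1))
      p <- model_params(gamma = w[1], sigma = runif(1, 1, 60),
                        beta_loc = w[2], beta_glo = w[3])
      q <- stats::integrate(function(x) pdf_global_local(x, tr, p), 0, 180,
                            rel.tol = 1e-9, subdivisions = 400)
      expect_equal(q$value, 1, tolerance = 1e-6)
    }
  })
})

test_that("the perpendicular control peaks 90 degrees from the global orientation", {
  tr <- one_trial(g = 70)
  p <- model_params(gamma = 0, sigma = 5, beta_loc = 0, beta_glo = 1)
  x <- seq(0.5, 180, by = 0.5)
  d <- pdf_global_perpendicular(x, tr, p)
  expect_equal(wrap180(x[which.max(d)] - 160), 0, tolerance = 0.5)
})

test_that("log_likelihood sums per-trial log densities and guards conditions", {
  cell <- make_cell(n = 100, seed = 3)
  p <- model_params(gamma = 0.1, sigma = 8, beta_loc = 0.15, beta_glo = 0.08)
  ll <- log_likelihood("global_local", p, cell)
  # independent per-trial oracle via the scalar pdf interface
  oracle <- sum(vapply(seq_len(nrow(cell)), function(i) {
    log(pdf_global_local(cell$response_deg[i], cell[i, ], p))
  }, numeric(1)))
  expect_equal(ll, oracle, tolerance = 1e-10)
  # additivity: duplicated trials double the log-likelihood
  expect_equal(log_likelihood("global_local", p, rbind(cell, cell)), 2 * ll)
  # a single pure-guess trial
  u <- make_cell(n = 30, condition = "U", seed = 4)
  expect_equal(log_likelihood("standard", model_params(1, 10), u[1, ]),
               log(1 / 180))
  # crowded models refuse uncrowded trials
  expect_error(log_likelihood("local",
                              model_params(0.1, 8, beta_loc = 0.1), u),
               "uncrowded")
})

test_that("sample_response matches its own likelihood and component weights", {
  withr::with_seed(21, {
    d <- gen_design(2e4, "FA", seed = 8)
    p <- model_params(gamma = 0.15, sigma = 8, beta_loc = 0.25,
                      beta_glo = 0.2)
    s <- sample_response(d, "global_local", p, seed = 9)
    # component frequencies within 3 binomial SEs
    freq <- table(s$component) / nrow(d)
    probs <- c(target = 0.4, guess = 0.15, local = 0.25, global = 0.2)
    for (nm in names(probs)) {
      se <- sqrt(probs[nm] * (1 - probs[nm]) / nrow(d))
      expect_lt(abs(freq[[nm]] - probs[[nm]]), 3.5 * se)
    }
    # pure guessing is uniform over the 180 wheel values
    sg <- sample_response(d[1:1e4, ], "standard", model_params(1, 8))
    expect_gt(chisq.test(table(factor(sg$response, levels = 1:180)))$p.value,
              0.01)
    # a near-deterministic target component concentrates at the target
    st <- sample_response(d[1:2000, ], "standard",
                          model_params(0, 2), seed = 10)
    expect_gt(mean(abs(signed_error(st$response, d$target_deg[1:2000])) < 8),
              0.99)
  })
})

test_that("empirical density of simulated responses matches pdf_global_local", {
  withr::with_seed(31, {
    tr <- one_trial(target = 90, f1 = 30, f2 = 140, g = 60)
    trs <- tibble::as_tibble(tr)[rep(1, 1e5), ]
    trs$condition <- "FA"
    p <- model_params(gamma = 0.1, sigma = 6, beta_loc = 0.3, beta_glo = 0.2)
    s <- sample_response(trs, "global_local", p)
    bw <- 5
    h <- hist(s$response, breaks = seq(0, 180, by = bw), plot = FALSE)
    expected <- vapply(h$mids, function(m) {
      stats::integrate(function(x) pdf_global_local(x, tr, p),
                       m - bw / 2, m + bw / 2)$value / bw
    }, numeric(1))
    se <- sqrt(pmax(expected, 1e-6) / (1e5 * bw))
    expect_true(all(abs(h$density - expected) < 4 * se + 1e-4))
  })
})
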