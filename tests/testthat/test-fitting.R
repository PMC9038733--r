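test_that("aicc matches its closed form and limits", {
  expect_equal(aicc(-500, 2, 200), 1004 + 12 / 197)
  # large n: AICc approaches AIC
  expect_equal(aicc(-500, 3, 1e9), 1006, tolerance = 1e-6)
  # increasing in k at fixed loglik and n
  a <- vapply(2:5, function(k) aicc(-100, k, 200), numeric(1))
  expect_true(all(diff(a) > 0))
  expect_error(aicc(-10, 5, 6), "n > k \\+ 1")
})

test_that("target_report_rate follows the model formula", {
  expect_equal(target_report_rate(model_params(0.2, 8)), 0.8)
  expect_equal(target_report_rate(
    model_params(0.1, 8, beta_loc = 0.15, beta_glo = 0.05)), 0.7)
  expect_equal(target_report_rate(model_params(1, 8)), 0)
})

test_that("parameters are recovered from Standard-generated data", {
  cell <- make_cell(n = 5000, condition = "U",
                    params = list(gamma = 0, sigma = 8), seed = 11)
  f <- fit_mle("standard", cell, restarts = 10, seed = 12)
  expect_true(f$converged)
  expect_lte(f$params$gamma, 0.02)
  expect_gt(f$params$sigma, 7.5)
  expect_lt(f$params$sigma, 8.5)
})

test_that("parameters are recovered from Global-Local-generated data", {
  cell <- make_cell(n = 2000, condition = "FA",
                    params = list(gamma = 0.10, sigma = 8,
                                  beta_loc = 0.15, beta_glo = 0.08),
                    seed = 21)
  f <- fit_models(cell, restarts = 10, seed = 22)
  g <- f$global_local$params
  expect_lt(abs(g$gamma - 0.10), 0.03)
  expect_lt(abs(g$beta_loc - 0.15), 0.03)
  expect_lt(abs(g$beta_glo - 0.08), 0.03)
  expect_lt(abs(g$sigma - 8), 1)
  # nesting: richer models never fit worse
  expect_lte(f$standard$loglik, f$local$loglik + 1e-6)
  expect_lte(f$local$loglik, f$global_local$loglik + 1e-6)
})

test_that("fitted log-likelihoods are monotone along the nesting on many datasets", {
  for (i in 1:10) {
    cell <- make_cell(n = 150, seed = 100 + i,
                      params = list(gamma = runif(1, 0, 0.3),
                                    sigma = runif(1, 3, 20),
                                    beta_loc = runif(1, 0, 0.3),
                                    beta_glo = runif(1, 0, 0.2)))
    f <- fit_models(cell, restarts = 6, seed = 200 + i)
    lls <- c(f$standard$loglik, f$local$loglik, f$global_local$loglik)
    expect_true(all(diff(lls) >= -1e-6))
  }
})

test_that("refitting with the same seed is bit-reproducible", {
  cell <- make_cell(n = 200, seed = 31)
  f1 <- fit_mle("global_local", cell, restarts = 8, seed = 33)
  f2 <- fit_mle("global_local", cell, restarts = 8, seed = 33)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$best_start_index, f2$best_start_index)
})

test_that("fit_mle enforces its preconditions", {
  cell <- make_cell(n = 19, seed = 41)
  expect_error(fit_mle("global_local", cell), "at least 20")
  u <- make_cell(n = 50, condition = "U", seed = 42)
  expect_error(fit_mle("local", u), "uncrowded")
})

test_that("compare_models reports AICc deltas and the winner", {
  cell <- make_cell(n = 2000, seed = 51,
                    params = list(gamma = 0.1, sigma = 8,
                                  beta_loc = 0.15, beta_glo = 0.15))
  f <- fit_models(cell, restarts = 8, seed = 52)
  cmp <- compare_models(f)
  expect_lt(cmp$delta_gl_local, 0)   # strong global signal favors GL
  expect_lt(cmp$delta_gl_std, 0)
  expect_identical(cmp$winner, "global_local")
  expect_equal(cmp$delta_gl_std,
               f$global_local$aicc - f$standard$aicc)
  # mismatched trial sets are refused
  f2 <- f
  f2$standard <- fit_mle("standard", cell[1:200, ], restarts = 4, seed = 53)
  expect_error(compare_models(f2), "different trial sets")
})

test_that("estimator error shrinks with sample size", {
  truth <- list(gamma = 0.10, sigma = 8, beta_loc = 0.15, beta_glo = 0.08)
  err_at_n <- vapply(c(200, 1000, 5000), function(n) {
    errs <- vapply(1:3, function(r) {
      cell <- make_cell(n = n, seed = 1000 * r + n, params = truth)
      g <- fit_models(cell, models = c("standard", "local", "global_local"),
                      restarts = 6, seed = 77 + r)$global_local$params
      mean(abs(c(g$gamma - truth$gamma, g$beta_loc - truth$beta_loc,
                 g$beta_glo - truth$beta_glo)))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(err_at_n[3], err_at_n[1])
})
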