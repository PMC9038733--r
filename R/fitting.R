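# ---- parameter transforms -------------------------------------------------
#
# The simplex constraint (gamma + beta_loc + beta_glo <= 1, all rates >= 0)
# is handled by optimizing mixture logits: the target-report rate is the
# softmax baseline, so every unconstrained vector maps to a valid interior
# point.  sigma is squeezed into [0.5, 90] by a scaled logistic.

SIGMA_LO <- 0.5
SIGMA_HI <- 90

# sigma bounds expressed on the log-concentration scale; the optimizer works
# in log(kappa) so the likelihood never needs the numeric sigma -> kappa
# inversion in its hot loop (kappa -> sigma is closed form).
kappa_bounds <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- log(c(lo = sd_to_kappa(SIGMA_HI), hi = sd_to_kappa(SIGMA_LO)))
    }
    cache
  }
})

z_to_params <- function(z, model) {
  nr <- model_k(model) - 1L            # number of free mixture rates
  ez <- exp(z[seq_len(nr)])
  d <- 1 + sum(ez)
  w <- ez / d
  kb <- kappa_bounds()
  kappa <- exp(kb[["lo"]] + (kb[["hi"]] - kb[["lo"]]) *
                 stats::plogis(z[nr + 1L]))
  list(gamma = w[1],
       sigma = kappa_to_sd(kappa),
       kappa = kappa,
       beta_loc = if (nr >= 2) w[2] else NULL,
       beta_glo = if (nr >= 3) w[3] else NULL)
}

params_to_z <- function(params, model) {
  nr <- model_k(model) - 1L
  w <- c(params$gamma,
         if (nr >= 2) params$beta_loc %||% 0,
         if (nr >= 3) params$beta_glo %||% 0)
  w <- pmin(pmax(w, 1e-5), 1 - 1e-5)
  pt <- max(1 - sum(w), 1e-5)
  kb <- kappa_bounds()
  s <- min(max(params$sigma, SIGMA_LO + 1e-4), SIGMA_HI - 1e-4)
  lk <- log(sd_to_kappa(s))
  lk <- min(max(lk, kb[["lo"]] + 1e-9), kb[["hi"]] - 1e-9)
  c(log(w / pt),
    stats::qlogis((lk - kb[["lo"]]) / (kb[["hi"]] - kb[["lo"]])))
}

neg_loglik_factory <- function(err, model) {
  function(z) {
    p <- z_to_params(z, model)
    dens <- mixture_density(err, model, p, kappa = p$kappa)
    if (any(dens <= 0) || any(!is.finite(dens))) return(1e10)
    -sum(log(dens))
  }
}

# Latin-hypercube starting points in natural parameter space
lhs_starts <- function(restarts, model) {
  nr <- model_k(model) - 1L
  u <- lhs::randomLHS(restarts, nr + 1L)
  lapply(seq_len(restarts), function(i) {
    rates <- 0.01 + 0.38 * u[i, seq_len(nr)]
    if (sum(rates) > 0.9) rates <- rates * 0.9 / sum(rates)
    list(gamma = rates[1],
         sigma = 2 + 38 * u[i, nr + 1L],
         beta_loc = if (nr >= 2) rates[2] else NULL,
         beta_glo = if (nr >= 3) rates[3] else NULL)
  })
}

#' Maximum-likelihood fit of a mixture model to one trial set
#'
#' Fits the chosen model by multi-start maximum likelihood: `restarts`
#' Latin-hypercube starting points over the interior of the constraint
#' region (rates in the simplex, `sigma` in `[0.5, 90]`), each polished by
#' Nelder-Mead on an unconstrained logit parameterization.  The best start
#' wins; log-likelihood ties below 1e-6 are broken by the lower start index,
#' so refits under the same seed are bit-reproducible.
#'
#' @param model Model name (`"standard"`, `"local"`, `"global_local"`,
#'   `"global_perp"`).
#' @param trials Trial table for a single observer and condition.
#' @param restarts Number of random starts (default 20).
#' @param seed Optional integer seed for the start draw.
#' @param extra_starts Optional list of [model_params()]-style lists used as
#'   additional deterministic starts before the random ones (e.g. the best
#'   fit of a nested model with the new rate at zero).
#' @param maxit,reltol Nelder-Mead control.
#' @return A `"crowdmix_fit"` list: `model`, `params`, `loglik`, `n_trials`,
#'   `k_params`, `aicc`, `n_restarts`, `converged`, `best_start_index`.
#' @export
fit_mle <- function(model, trials, restarts = 20, seed = NULL,
                    extra_starts = NULL, maxit = 2000, reltol = 1e-10) {
  model <- match.arg(model, model_names)
  check_model_condition(model, trials)
  if (nrow(trials) < 20) {
    stop("need at least 20 trials to fit; got ", nrow(trials), call. = FALSE)
  }
  err <- trial_errors(trials, model)
  nll <- neg_loglik_factory(err, model)
  starts <- if (is.null(seed)) lhs_starts(restarts, model) else
    withr::with_seed(seed, lhs_starts(restarts, model))
  starts <- c(extra_starts, starts)

  best <- NULL
  any_ok <- FALSE
  for (i in seq_along(starts)) {
    z0 <- params_to_z(starts[[i]], model)
    opt <- tryCatch(
      stats::optim(z0, nll, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    any_ok <- TRUE
    if (is.null(best) || opt$value < best$value - 1e-6) {
      best <- opt
      best$start_index <- i
    }
  }
  if (!any_ok) {
    return(structure(list(model = model, params = NULL, loglik = NA_real_,
                          n_trials = nrow(trials), k_params = model_k(model),
                          aicc = NA_real_, n_restarts = length(starts),
                          converged = FALSE, best_start_index = NA_integer_),
                     class = "crowdmix_fit"))
  }
  p <- z_to_params(best$par, model)
  p$kappa <- NULL
  ll <- -best$value
  structure(list(
    model = model,
    params = do.call(model_params, p),
    loglik = ll,
    n_trials = nrow(trials),
    k_params = model_k(model),
    aicc = aicc(ll, model_k(model), nrow(trials)),
    n_restarts = length(starts),
    converged = best$convergence == 0,
    best_start_index = best$start_index
  ), class = "crowdmix_fit")
}

#' @export
print.crowdmix_fit <- function(x, ...) {
  cat(sprintf("MLE fit: %s model, n = %d trials\n", x$model, x$n_trials))
  if (is.null(x$params)) {
    cat("  all starts failed\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf("  gamma = %.4f  sigma = %.2f deg", p$gamma, p$sigma))
  if (!is.null(p$beta_loc)) cat(sprintf("  beta_loc = %.4f", p$beta_loc))
  if (!is.null(p$beta_glo)) cat(sprintf("  beta_glo = %.4f", p$beta_glo))
  cat(sprintf("\n  logLik = %.2f  AICc = %.2f  (best start %d/%d, %s)\n",
              x$loglik, x$aicc, x$best_start_index, x$n_restarts,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Akaike information criterion with small-sample correction
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of trials.
#' @return Scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1.", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the nested model family to one trial set
#'
#' Fits Standard, Local and Global-Local (optionally also the perpendicular
#' control) in nesting order, passing each fit forward as a warm start for
#' the next model (with the new rate at zero), which guarantees the fitted
#' log-likelihoods are monotone along the nesting.
#'
#' @inheritParams fit_mle
#' @param models Character vector of models to fit.
#' @return Named list of `"crowdmix_fit"` objects.
#' @export
fit_models <- function(trials, models = c("standard", "local", "global_local"),
                       restarts = 20, seed = NULL) {
  models <- match.arg(models, model_names, several.ok = TRUE)
  fits <- list()
  seeds <- if (is.null(seed)) rep(list(NULL), length(model_names)) else
    as.list(seed + seq_along(model_names))
  names(seeds) <- model_names
  warm <- function(from, add) {
    f <- fits[[from]]
    if (is.null(f) || is.null(f$params)) return(NULL)
    p <- unclass(f$params)
    for (a in add) p[[a]] <- 0
    list(p)
  }
  for (m in intersect(c("standard", "local", "global_local", "global_perp"),
                      models)) {
    extra <- switch(m,
      standard = NULL,
      local = warm("standard", "beta_loc"),
      global_local = warm("local", "beta_glo") %||%
        warm("standard", c("beta_loc", "beta_glo")),
      global_perp = warm("local", "beta_glo") %||%
        warm("standard", c("beta_loc", "beta_glo"))
    )
    fits[[m]] <- fit_mle(m, trials, restarts = restarts, seed = seeds[[m]],
                         extra_starts = extra)
  }
  fits[models]
}

#' Compare fitted models by AICc
#'
#' Computes the AICc differences the model comparison reports:
#' `AICc(global_local) - AICc(standard)` and
#' `AICc(global_local) - AICc(local)` (negative values favor the
#' Global-Local model), plus the winning (minimum-AICc) model.
#'
#' @param fits Named list of `"crowdmix_fit"` objects for the same trial
#'   set, containing at least `standard`, `local` and `global_local`.
#' @return A one-row tibble: `delta_gl_std`, `delta_gl_local`, `winner`,
#'   `tie`.
#' @export
compare_models <- function(fits) {
  need <- c("standard", "local", "global_local")
  if (!all(need %in% names(fits))) {
    stop("`fits` must contain standard, local and global_local fits.",
         call. = FALSE)
  }
  n <- vapply(fits[need], function(f) f$n_trials, numeric(1))
  if (length(unique(n)) != 1L) {
    stop("fits were computed on different trial sets (n differs).",
         call. = FALSE)
  }
  a <- vapply(fits[need], function(f) f$aicc, numeric(1))
  winner <- need[which.min(a)]
  tie <- sum(abs(a - min(a)) < 1e-9) > 1L
  tibble::tibble(
    delta_gl_std = a[["global_local"]] - a[["standard"]],
    delta_gl_local = a[["global_local"]] - a[["local"]],
    winner = winner,
    tie = tie
  )
}

#' Target-report rate of a fitted parameter set
#'
#' `P_T = 1 - gamma - beta_loc - beta_glo`, with absent rates taken as zero
#' (so `P_T = 1 - gamma` for the Standard Mixture).
#'
#' @param params A [model_params()] list.
#' @return Probability in `[0, 1]`.
#' @export
target_report_rate <- function(params) {
  validate_params(params)
  1 - params$gamma - (params$beta_loc %||% 0) - (params$beta_glo %||% 0)
}
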