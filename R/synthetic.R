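#' Default generating parameters per display condition
#'
#' The generator's defaults emulate the qualitative structure of a crowding
#' continuous-report experiment: an uncrowded (U) condition well described by
#' the Standard Mixture with low guessing and tight reports, and two crowded
#' conditions (flankers aligned, FA; flankers misaligned, FM) with broader
#' reports, some guessing, misreports of local flanker orientations (more
#' frequent when flankers are misaligned) and an equal, smaller rate of
#' misreports of the global-configuration orientation.
#'
#' @return Named list of per-condition [model_params()]-style lists.
#' @export
default_condition_params <- function() {
  list(
    U  = list(gamma = 0.02, sigma = 4),
    FA = list(gamma = 0.06, sigma = 8, beta_loc = 0.10, beta_glo = 0.08),
    FM = list(gamma = 0.06, sigma = 8, beta_loc = 0.16, beta_glo = 0.08)
  )
}

#' Simulation design configuration
#'
#' @param n_observers Number of simulated observers (default 27).
#' @param trials_per_condition Trials per observer per condition (default
#'   200).
#' @param conditions Subset of `c("U", "FA", "FM")`.
#' @param seed Integer master seed.
#' @param generating_model Model used to draw responses on crowded trials
#'   (`"global_local"` by default; U trials always use the Standard
#'   Mixture).
#' @param params_per_condition Named list of generating parameters per
#'   condition.
#' @param rate_sd,sigma_sd Between-observer heterogeneity: each rate
#'   parameter is jittered by a truncated normal with this SD (default
#'   0.03), `sigma` by a truncated normal with SD `sigma_sd` (default 2
#'   degrees, truncated to +/- 2 degrees).
#' @return A list of class `"crowdmix_config"`.
#' @export
design_config <- function(n_observers = 27, trials_per_condition = 200,
                          conditions = c("U", "FA", "FM"), seed = 1,
                          generating_model = "global_local",
                          params_per_condition = default_condition_params(),
                          rate_sd = 0.03, sigma_sd = 2) {
  conditions <- match.arg(conditions, c("U", "FA", "FM"), several.ok = TRUE)
  stopifnot(n_observers >= 1, trials_per_condition >= 1)
  generating_model <- match.arg(generating_model, model_names)
  for (cond in conditions) {
    p <- params_per_condition[[cond]]
    if (is.null(p)) stop("missing parameters for condition ", cond,
                         call. = FALSE)
    validate_params(p)
  }
  structure(list(n_observers = n_observers,
                 trials_per_condition = trials_per_condition,
                 conditions = conditions, seed = as.integer(seed),
                 generating_model = generating_model,
                 params_per_condition = params_per_condition,
                 rate_sd = rate_sd, sigma_sd = sigma_sd),
            class = "crowdmix_config")
}

#' Generate the stimulus design for a block of trials
#'
#' Targets are drawn uniformly from the 180 integer orientation values
#' (1-180 degrees).  Crowded trials additionally carry two unique flanker
#' orientations, drawn independently and assigned to diagonal pairs
#' (flanker1 = flanker3, flanker2 = flanker4), and a global-configuration
#' orientation drawn independently of both.  Uncrowded trials carry neither.
#'
#' @param n_trials Number of trials.
#' @param condition One of `"U"`, `"FA"`, `"FM"`.
#' @param observer Observer identifier.
#' @param seed Optional integer seed.
#' @return A tibble in the trial-table schema with `response_deg = NA`.
#' @export
gen_design <- function(n_trials, condition = c("U", "FA", "FM"),
                       observer = "obs01", seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(n_trials >= 1)
  draw <- function() {
    target <- sample(1:180, n_trials, replace = TRUE)
    if (condition == "U") {
      f1 <- f2 <- g <- rep(NA_integer_, n_trials)
    } else {
      f1 <- sample(1:180, n_trials, replace = TRUE)
      f2 <- sample(1:180, n_trials, replace = TRUE)
      g <- sample(1:180, n_trials, replace = TRUE)
    }
    tibble::tibble(
      observer = observer, condition = condition,
      target_deg = target,
      flanker1_deg = f1, flanker2_deg = f2,
      flanker3_deg = f1, flanker4_deg = f2,
      global_deg = g, response_deg = NA_real_
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Fill in simulated responses for a design
#'
#' Draws one response per trial from the generative model via
#' [sample_response()].  The hidden component label of each trial (target,
#' guess, local, global) is retained in a `component` column as ground truth
#' for recovery tests.
#'
#' @param design Trial table from [gen_design()].
#' @param model Generating model.
#' @param params Generating [model_params()] list.
#' @param seed Optional integer seed.
#' @return The design with `response_deg` filled and a `component` column.
#' @export
gen_responses <- function(design, model, params, seed = NULL) {
  s <- sample_response(design, model, params, seed = seed)
  design$response_deg <- s$response
  design$component <- s$component
  design
}

# truncated-normal jitter of one observer's parameters
jitter_params <- function(params, rate_sd, sigma_sd) {
  rtrunc <- function(mu, sd, lo, hi) {
    if (sd <= 0) return(mu)
    repeat {
      x <- stats::rnorm(1, mu, sd)
      if (x >= lo && x <= hi) return(x)
    }
  }
  p <- params
  rates <- intersect(c("gamma", "beta_loc", "beta_glo"), names(p))
  repeat {
    for (r in rates) p[[r]] <- rtrunc(params[[r]], rate_sd, 0, 1)
    if (sum(unlist(p[rates])) < 0.98) break
  }
  p$sigma <- rtrunc(params$sigma, sigma_sd,
                    max(params$sigma - 2, SIGMA_LO), min(params$sigma + 2, 90))
  p
}

#' Generate a full experiment-shaped dataset
#'
#' Simulates every observer and condition of a [design_config()]: each
#' observer receives an independent stimulus design, observer-specific
#' parameters (the condition parameters jittered by the configured
#' between-observer heterogeneity), and responses drawn from the generating
#' model (Standard Mixture on U trials).  Fully deterministic given the
#' config seed.
#'
#' @param config A [design_config()].
#' @return A list with `trials` (one tibble, all observers, with hidden
#'   `component` labels) and `truth` (tibble of every observer's true
#'   generating parameters per condition).
#' @export
gen_dataset <- function(config) {
  stopifnot(inherits(config, "crowdmix_config"))
  withr::with_seed(config$seed, {
    all_trials <- list()
    truth <- list()
    for (i in seq_len(config$n_observers)) {
      obs <- sprintf("obs%02d", i)
      for (cond in config$conditions) {
        model <- if (cond == "U") "standard" else config$generating_model
        p <- jitter_params(config$params_per_condition[[cond]],
                           config$rate_sd, config$sigma_sd)
        d <- gen_design(config$trials_per_condition, cond, observer = obs)
        d <- gen_responses(d, model, p)
        all_trials[[length(all_trials) + 1L]] <- d
        truth[[length(truth) + 1L]] <- tibble::tibble(
          observer = obs, condition = cond, model = model,
          gamma = p$gamma, sigma = p$sigma,
          beta_loc = p$beta_loc %||% NA_real_,
          beta_glo = p$beta_glo %||% NA_real_
        )
      }
    }
    list(trials = dplyr::bind_rows(all_trials),
         truth = dplyr::bind_rows(truth))
  })
}
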