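#' Mixture-model parameter vectors
#'
#' Constructs and validates the parameter set of one of the response-error
#' mixture models:
#' \describe{
#'   \item{standard}{target von Mises + uniform guessing: `gamma`, `sigma`.}
#'   \item{local}{adds a flanker-misreport component: `+ beta_loc`.}
#'   \item{global_local}{adds a global-configuration misreport component:
#'     `+ beta_glo`.}
#'   \item{global_perp}{same parameters as `global_local`, but the global
#'     component sits at the orientation perpendicular (+90 degrees) to the
#'     true global configuration (control model).}
#' }
#' All mixture rates lie in `[0, 1]` with `gamma + beta_loc + beta_glo <= 1`;
#' the remainder is the target-report rate.  `sigma` (degrees, shared by all
#' von Mises components) lies in `(0, 90]`.
#'
#' @param gamma Guessing rate.
#' @param sigma Von Mises SD in orientation degrees.
#' @param beta_loc Local (flanker) misreport rate, or `NULL`.
#' @param beta_glo Global-configuration misreport rate, or `NULL`.
#' @return A named list of class `"crowdmix_params"`.
#' @export
model_params <- function(gamma, sigma, beta_loc = NULL, beta_glo = NULL) {
  p <- list(gamma = gamma, sigma = sigma,
            beta_loc = beta_loc, beta_glo = beta_glo)
  validate_params(p)
  structure(p, class = "crowdmix_params")
}

validate_params <- function(p) {
  rates <- c(p$gamma, p$beta_loc, p$beta_glo)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("mixture rates must lie in [0, 1].", call. = FALSE)
  }
  if (sum(rates) > 1 + 1e-12) {
    stop("gamma + beta_loc + beta_glo must not exceed 1.", call. = FALSE)
  }
  if (!is.finite(p$sigma) || p$sigma <= 0 || p$sigma > 90) {
    stop("`sigma` must lie in (0, 90].", call. = FALSE)
  }
  invisible(p)
}

model_names <- c("standard", "local", "global_local", "global_perp")

#' Number of free parameters of a model
#' @param model One of `"standard"`, `"local"`, `"global_local"`,
#'   `"global_perp"`.
#' @return Integer count of free parameters.
#' @export
model_k <- function(model) {
  model <- match.arg(model, model_names)
  switch(model, standard = 2L, local = 3L, global_local = 4L,
         global_perp = 4L)
}

params_for_model <- function(params, model) {
  model <- match.arg(model, model_names)
  need <- c("gamma", "sigma",
            if (model != "standard") "beta_loc",
            if (model %in% c("global_local", "global_perp")) "beta_glo")
  miss <- need[vapply(params[need], is.null, logical(1))]
  if (length(miss)) {
    stop(sprintf("model '%s' needs parameter(s): %s", model,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  validate_params(params)
  params
}

# Wrapped-error design for one set of trials: target error, four flanker
# errors, global error (all response-relative), computed once so the
# likelihood can be evaluated many times cheaply during optimization.
trial_errors <- function(trials, model) {
  resp <- trials$response_deg
  et <- signed_error(resp, trials$target_deg)
  out <- list(et = et, n = length(et))
  if (model != "standard") {
    fl <- as.matrix(trials[, paste0("flanker", 1:4, "_deg")])
    if (any(is.na(fl))) stop("model requires flanker orientations on every trial.",
                             call. = FALSE)
    out$ef <- wrap180(resp - fl)
  }
  if (model %in% c("global_local", "global_perp")) {
    g <- trials$global_deg
    if (any(is.na(g))) stop("model requires the global orientation on every trial.",
                            call. = FALSE)
    if (model == "global_perp") g <- g + 90
    out$eg <- signed_error(resp, g)
  }
  out
}

# density per degree for precomputed wrapped errors; kappa precomputed
mixture_density <- function(err, model, params, kappa = NULL) {
  kappa <- kappa %||% sd_to_kappa(params$sigma)
  li0 <- log_bessel_i0(kappa)
  vm <- function(x) exp(kappa * cos(x * pi / 90) - li0) / 180
  g <- params$gamma
  bl <- if (model == "standard") 0 else params$beta_loc
  bg <- if (model %in% c("global_local", "global_perp")) params$beta_glo else 0
  dens <- (1 - g - bl - bg) * vm(err$et) + g / 180
  if (bl > 0 || model != "standard") {
    dens <- dens + bl * rowMeans(vm(err$ef))
  }
  if (model %in% c("global_local", "global_perp")) {
    dens <- dens + bg * vm(err$eg)
  }
  dens
}

#' Response-density of the Standard Mixture model
#'
#' Probability density (per degree) of a reported orientation under the
#' two-component model: a von Mises centred on the target plus a uniform
#' guessing floor, `(1 - gamma) * vm(response - target, sigma) + gamma / 180`.
#'
#' @param response,target Orientations in degrees.
#' @param params A [model_params()] list with `gamma` and `sigma`.
#' @return Densities per degree.
#' @export
pdf_standard <- function(response, target, params) {
  params_for_model(params, "standard")
  err <- list(et = signed_error(response, target))
  mixture_density(err, "standard", params)
}

pdf_with_trial <- function(model, response, trial, params) {
  params_for_model(params, model)
  trial <- as.list(trial)
  resp <- response
  fl <- unlist(trial[paste0("flanker", 1:4, "_deg")], use.names = FALSE)
  if (length(fl) != 4 || any(is.na(fl))) {
    stop("trial must carry four flanker orientations.", call. = FALSE)
  }
  if (abs(wrap180(fl[1] - fl[3])) > 1e-9 || abs(wrap180(fl[2] - fl[4])) > 1e-9) {
    stop("flankers must be paired: flanker1 == flanker3, flanker2 == flanker4.",
         call. = FALSE)
  }
  err <- list(
    et = signed_error(resp, trial$target_deg),
    ef = wrap180(outer(resp, fl, `-`))
  )
  if (model %in% c("global_local", "global_perp")) {
    g <- trial$global_deg
    if (is.null(g) || is.na(g)) stop("trial must carry a global orientation.",
                                     call. = FALSE)
    if (model == "global_perp") g <- g + 90
    err$eg <- signed_error(resp, g)
  }
  mixture_density(err, model, params)
}

#' Response-densities of the misreport mixture models
#'
#' `pdf_local()` adds to the Standard Mixture a flanker-misreport component:
#' with probability `beta_loc` the report is centred on one of the `m = 4`
#' flanker orientations (each with weight `1/m`).  `pdf_global_local()`
#' further adds a component centred on the global-configuration orientation
#' with weight `beta_glo`.  `pdf_global_perpendicular()` is the control
#' variant with the global component displaced by +90 degrees.
#'
#' @param response Reported orientation(s) in degrees.
#' @param trial A one-row data frame or named list with `target_deg`,
#'   `flanker1_deg` ... `flanker4_deg` and (for the global models)
#'   `global_deg`.
#' @param params A [model_params()] list with the parameters the model needs.
#' @return Densities per degree, one per element of `response`.
#' @export
pdf_local <- function(response, trial, params) {
  pdf_with_trial("local", response, trial, params)
}

#' @rdname pdf_local
#' @export
pdf_global_local <- function(response, trial, params) {
  pdf_with_trial("global_local", response, trial, params)
}

#' @rdname pdf_local
#' @export
pdf_global_perpendicular <- function(response, trial, params) {
  pdf_with_trial("global_perp", response, trial, params)
}

#' Log-likelihood of a model over a trial table
#'
#' Sum of per-trial log densities.  Returns `-Inf` (with a warning) if any
#' trial has zero density under the parameters.
#'
#' @param model Model name.
#' @param params A [model_params()] list.
#' @param trials Trial table (see [read_trials()] for the schema).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model, params, trials) {
  model <- match.arg(model, model_names)
  params_for_model(params, model)
  check_model_condition(model, trials)
  err <- trial_errors(trials, model)
  dens <- mixture_density(err, model, params)
  if (any(dens <= 0)) {
    warning("zero density on at least one trial; log-likelihood is -Inf.")
    return(-Inf)
  }
  sum(log(dens))
}

check_model_condition <- function(model, trials) {
  if (model != "standard" && any(trials$condition == "U")) {
    stop("flanker/global models cannot be evaluated on uncrowded (U) trials.",
         call. = FALSE)
  }
  invisible(trials)
}

#' Simulate responses from a mixture model
#'
#' Generative counterpart of the likelihoods: each trial first draws a
#' component (target / guess / local flanker / global configuration) with
#' probabilities `(P_T, gamma, beta_loc, beta_glo)`; the target, flanker and
#' global components then add von Mises noise (SD `sigma`) around the
#' respective orientation (the flanker component first picks one of the four
#' flankers uniformly), while the guess component draws uniformly from the
#' 180 integer orientation values of the response wheel.
#'
#' @param trials Trial table (responses ignored); one response is drawn per
#'   row.
#' @param model Model name.
#' @param params A [model_params()] list.
#' @param seed Optional integer; if given, sampling is reproducible.
#' @return A list with `response` (degrees in `(0, 180]`) and `component`
#'   (factor: `"target"`, `"guess"`, `"local"`, `"global"`).
#' @export
sample_response <- function(trials, model, params, seed = NULL) {
  model <- match.arg(model, model_names)
  params_for_model(params, model)
  check_model_condition(model, trials)
  draw <- function() {
    n <- nrow(trials)
    g <- params$gamma
    bl <- if (model == "standard") 0 else params$beta_loc
    bg <- if (model %in% c("global_local", "global_perp")) params$beta_glo else 0
    comp <- sample(c("target", "guess", "local", "global"), n, replace = TRUE,
                   prob = c(1 - g - bl - bg, g, bl, bg))
    resp <- numeric(n)
    it <- comp == "target"
    if (any(it)) resp[it] <- rvm180(sum(it), 0, params$sigma) +
        trials$target_deg[it]
    ig <- comp == "guess"
    if (any(ig)) resp[ig] <- sample(1:180, sum(ig), replace = TRUE)
    il <- comp == "local"
    if (any(il)) {
      fl <- as.matrix(trials[il, paste0("flanker", 1:4, "_deg"), drop = FALSE])
      pick <- fl[cbind(seq_len(sum(il)), sample.int(4, sum(il), replace = TRUE))]
      resp[il] <- rvm180(sum(il), 0, params$sigma) + pick
    }
    ib <- comp == "global"
    if (any(ib)) {
      g0 <- trials$global_deg[ib]
      if (model == "global_perp") g0 <- g0 + 90
      resp[ib] <- rvm180(sum(ib), 0, params$sigma) + g0
    }
    list(response = wrap_0_180(resp),
         component = factor(comp, levels = c("target", "guess", "local",
                                             "global")))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
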