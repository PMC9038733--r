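#' Per-observer descriptive statistics and model fits
#'
#' For every observer x condition cell: the mean signed error and the
#' precision of the wrapped errors, plus maximum-likelihood fits of the
#' applicable models (U: Standard Mixture only; FA/FM: Standard, Local and
#' Global-Local, optionally also the +90-degree perpendicular control).
#' The designated "best" model whose parameters are reported per cell
#' follows the analysis convention: Standard for U, Global-Local for FA/FM
#' (per-cell AICc winners are reported alongside).
#'
#' Cells with fewer than `min_trials` trials are dropped with a warning.
#'
#' @param trials Trial table (see [read_trials()]).
#' @param restarts Multi-start count passed to [fit_mle()].
#' @param seed Integer seed driving the optimizer starts.
#' @param include_perp Also fit the perpendicular-global control on crowded
#'   cells.
#' @param min_trials Minimum trials per cell (default 20).
#' @return A list: `summary` (tibble, one row per observer x condition with
#'   `mean_error`, `precision`, designated-model parameters `gamma`,
#'   `sigma`, `beta_loc`, `beta_glo`, `p_t`, per-model AICcs, `winner`, and
#'   for crowded cells `delta_gl_std` / `delta_gl_local` /
#'   `beta_glo_perp`), and `fits` (nested list of all fit objects).
#' @export
summarize_observers <- function(trials, restarts = 20, seed = 1,
                                include_perp = FALSE, min_trials = 20) {
  validate_trials(trials)
  cells <- split(trials, list(trials$observer, trials$condition), drop = TRUE)
  small <- vapply(cells, nrow, integer(1)) < min_trials
  if (any(small)) {
    warning("dropping cells with fewer than ", min_trials, " trials: ",
            paste(names(cells)[small], collapse = ", "))
    cells <- cells[!small]
  }
  fits <- list()
  rows <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    obs <- cell$observer[1]
    cond <- cell$condition[1]
    err <- signed_error(cell$response_deg, cell$target_deg)
    cell_seed <- seed + 137L * i
    if (cond == "U") {
      f <- fit_models(cell, models = "standard", restarts = restarts,
                      seed = cell_seed)
      fits[[paste(obs, cond, sep = ".")]] <<- f
      p <- f$standard$params
      tibble::tibble(
        observer = obs, condition = cond, n_trials = nrow(cell),
        mean_error = mean_error(err), precision = precision(err),
        model = "standard",
        gamma = p$gamma, sigma = p$sigma,
        beta_loc = NA_real_, beta_glo = NA_real_,
        p_t = target_report_rate(p),
        aicc_standard = f$standard$aicc,
        aicc_local = NA_real_, aicc_global_local = NA_real_,
        winner = "standard",
        delta_gl_std = NA_real_, delta_gl_local = NA_real_,
        beta_glo_perp = NA_real_
      )
    } else {
      mods <- c("standard", "local", "global_local",
                if (include_perp) "global_perp")
      f <- fit_models(cell, models = mods, restarts = restarts,
                      seed = cell_seed)
      fits[[paste(obs, cond, sep = ".")]] <<- f
      cmp <- compare_models(f)
      p <- f$global_local$params
      tibble::tibble(
        observer = obs, condition = cond, n_trials = nrow(cell),
        mean_error = mean_error(err), precision = precision(err),
        model = "global_local",
        gamma = p$gamma, sigma = p$sigma,
        beta_loc = p$beta_loc, beta_glo = p$beta_glo,
        p_t = target_report_rate(p),
        aicc_standard = f$standard$aicc,
        aicc_local = f$local$aicc,
        aicc_global_local = f$global_local$aicc,
        winner = cmp$winner,
        delta_gl_std = cmp$delta_gl_std,
        delta_gl_local = cmp$delta_gl_local,
        beta_glo_perp = if (include_perp) f$global_perp$params$beta_glo
                        else NA_real_
      )
    }
  })
  summary <- dplyr::arrange(dplyr::bind_rows(rows), condition, observer)
  list(summary = summary, fits = fits)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject one-way ANOVA of a per-observer value across conditions.
#' Sphericity is assessed with Mauchly's test; when it is rejected (at
#' `mauchly_alpha`) the Greenhouse-Geisser epsilon is applied to the degrees
#' of freedom and the p-value.  Both corrected and uncorrected results are
#' reported, plus partial eta squared and Bonferroni-adjusted pairwise
#' paired t-tests.  The univariate machinery is delegated to
#' [car::Anova()] on a multivariate linear model.
#'
#' @param data Data frame with one row per observer x condition.
#' @param value,observer,condition Column names (strings).
#' @param mauchly_alpha Significance threshold that triggers the GG
#'   correction (default 0.05).
#' @return A list of class `"crowdmix_anova"`: `test` (one-row tibble with
#'   `F`, uncorrected and GG dfs and p-values, `gg_epsilon`, `mauchly_p`,
#'   `sphericity_violated`, `partial_eta_sq`, and the designated `p_value` /
#'   `df1` / `df2`) and `pairwise` (Bonferroni-adjusted paired
#'   comparisons).
#' @export
rm_anova_gg <- function(data, value, observer = "observer",
                        condition = "condition", mauchly_alpha = 0.05) {
  df <- data.frame(obs = data[[observer]], cond = factor(data[[condition]]),
                   y = data[[value]])
  if (anyNA(df$y)) stop("missing values in `", value, "`.", call. = FALSE)
  lev <- levels(df$cond)
  obs_ids <- sort(unique(df$obs))
  y <- sapply(lev, function(l) {
    sub <- df[df$cond == l, ]
    sub$y[match(obs_ids, sub$obs)]
  })
  if (anyNA(y)) {
    miss <- obs_ids[!stats::complete.cases(y)]
    stop("incomplete cases: observer(s) missing a condition: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- as.matrix(y)
  mlm <- stats::lm(y ~ 1)
  idata <- data.frame(cond = factor(lev, levels = lev))
  aov_res <- car::Anova(mlm, idata = idata, idesign = ~cond, type = "III")
  # summary() warns when the (unused) Huynh-Feldt epsilon exceeds 1
  s <- suppressWarnings(summary(aov_res, multivariate = FALSE))
  uni <- s$univariate.tests
  ss_eff <- uni["cond", "Sum Sq"]
  ss_err <- uni["cond", "Error SS"]
  f_val <- uni["cond", "F value"]
  df1 <- uni["cond", "num Df"]
  df2 <- uni["cond", "den Df"]
  p_unc <- uni["cond", "Pr(>F)"]
  if (length(lev) > 2 && !is.null(s$sphericity.tests) &&
      nrow(s$sphericity.tests) > 0) {
    mauchly_p <- s$sphericity.tests["cond", "p-value"]
    eps <- s$pval.adjustments["cond", "GG eps"]
    p_gg <- s$pval.adjustments["cond", "Pr(>F[GG])"]
  } else {
    mauchly_p <- NA_real_; eps <- 1; p_gg <- p_unc
  }
  violated <- is.finite(mauchly_p) && mauchly_p < mauchly_alpha
  pw <- stats::pairwise.t.test(df$y, df$cond, paired = TRUE,
                               p.adjust.method = "bonferroni")
  pairwise <- tibble::as_tibble(as.data.frame(as.table(pw$p.value)),
                                .name_repair = "minimal")
  names(pairwise) <- c("level1", "level2", "p_bonferroni")
  pairwise <- pairwise[!is.na(pairwise$p_bonferroni), ]
  out <- list(
    test = tibble::tibble(
      name = paste("one-way RM ANOVA on", value),
      F = f_val,
      df1_uncorrected = df1, df2_uncorrected = df2, p_uncorrected = p_unc,
      gg_epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2, p_gg = p_gg,
      mauchly_p = mauchly_p, sphericity_violated = violated,
      df1 = if (violated) eps * df1 else df1,
      df2 = if (violated) eps * df2 else df2,
      p_value = if (violated) p_gg else p_unc,
      partial_eta_sq = ss_eff / (ss_eff + ss_err)
    ),
    pairwise = pairwise
  )
  class(out) <- "crowdmix_anova"
  out
}

#' @export
print.crowdmix_anova <- function(x, ...) {
  t <- x$test
  cat(sprintf("%s: F(%.2f, %.2f) = %.2f, p = %.4g, partial eta^2 = %.2f\n",
              t$name, t$df1, t$df2, t$F, t$p_value, t$partial_eta_sq))
  if (isTRUE(t$sphericity_violated)) {
    cat(sprintf("  (Greenhouse-Geisser corrected, epsilon = %.3f, Mauchly p = %.3g)\n",
                t$gg_epsilon, t$mauchly_p))
  }
  invisible(x)
}

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t-test plus the paired-samples effect size
#' `d = mean(x - y) / sd(x - y)`.
#'
#' @param x,y Equal-length paired numeric vectors, `n >= 3`.
#' @return One-row tibble: `t`, `df`, `p_value`, `cohens_d`, `mean_diff`.
#' @export
paired_t_cohen <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must be paired with n >= 3.", call. = FALSE)
  }
  d <- x - y
  if (stats::sd(d) == 0) stop("zero-variance differences.", call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    cohens_d = mean(d) / stats::sd(d), mean_diff = mean(d)
  )
}

#' One-sample t-test against zero (with Cohen's d)
#'
#' @param x Numeric vector, `n >= 3`, non-degenerate.
#' @return One-row tibble: `mean`, `t`, `df`, `p_value`, `cohens_d`,
#'   `degenerate`.
#' @export
one_sample_t <- function(x) {
  if (length(x) < 3) stop("need n >= 3.", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(tibble::tibble(mean = mean(x), t = NA_real_, df = length(x) - 1,
                          p_value = NA_real_, cohens_d = NA_real_,
                          degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = 0)
  tibble::tibble(mean = mean(x), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 cohens_d = mean(x) / stats::sd(x), degenerate = FALSE)
}

#' Group tests on the misreport rates
#'
#' For each crowded condition: one-sample t-tests of the fitted global and
#' local misreport rates against zero; paired t-tests comparing each rate
#' between the two crowded conditions; and, when the perpendicular control
#' was fitted, the mean perpendicular-global rate per condition (expected
#' near zero).
#'
#' @param summary The `summary` tibble from [summarize_observers()].
#' @return A list of tibbles: `vs_zero`, `between_conditions`,
#'   `perpendicular`.
#' @export
misreport_tests <- function(summary) {
  crowd <- summary[summary$condition %in% c("FA", "FM"), ]
  if (!nrow(crowd) || anyNA(crowd$beta_glo)) {
    stop("summaries lack Global-Local fits for the crowded conditions.",
         call. = FALSE)
  }
  conds <- sort(unique(crowd$condition))
  vs_zero <- dplyr::bind_rows(lapply(conds, function(cc) {
    sub <- crowd[crowd$condition == cc, ]
    dplyr::bind_rows(
      dplyr::mutate(one_sample_t(sub$beta_glo), condition = cc,
                    rate = "beta_glo", .before = 1),
      dplyr::mutate(one_sample_t(sub$beta_loc), condition = cc,
                    rate = "beta_loc", .before = 1)
    )
  }))
  # degenerate inputs (e.g. all rates exactly zero) are reported, not fatal
  paired_or_degenerate <- function(x, y) {
    if (stats::sd(x - y) == 0) {
      tibble::tibble(t = NA_real_, df = length(x) - 1, p_value = NA_real_,
                     cohens_d = NA_real_, mean_diff = mean(x - y),
                     degenerate = TRUE)
    } else {
      dplyr::mutate(paired_t_cohen(x, y), degenerate = FALSE)
    }
  }
  between <- NULL
  if (length(conds) == 2) {
    a <- crowd[crowd$condition == conds[1], ]
    b <- crowd[crowd$condition == conds[2], ]
    a <- a[order(a$observer), ]; b <- b[order(b$observer), ]
    between <- dplyr::bind_rows(
      dplyr::mutate(paired_or_degenerate(a$beta_glo, b$beta_glo),
                    rate = "beta_glo",
                    contrast = paste(conds[1], "-", conds[2]), .before = 1),
      dplyr::mutate(paired_or_degenerate(a$beta_loc, b$beta_loc),
                    rate = "beta_loc",
                    contrast = paste(conds[1], "-", conds[2]), .before = 1)
    )
  }
  perp <- NULL
  if (!all(is.na(crowd$beta_glo_perp))) {
    perp <- dplyr::summarise(
      dplyr::group_by(crowd, condition),
      mean_beta_glo_perp = mean(beta_glo_perp), .groups = "drop"
    )
  }
  list(vs_zero = vs_zero, between_conditions = between, perpendicular = perp)
}

#' Run the full analysis pipeline
#'
#' End-to-end analysis of a trial table (real or simulated): per-observer
#' descriptives and fits, AICc model comparison with paired t-tests on the
#' per-observer AICcs, repeated-measures ANOVAs (Greenhouse-Geisser
#' corrected) on precision, guessing rate, variability and target-report
#' rate, misreport-rate tests, and the perpendicular-global control.
#' Deterministic given the data and `seed`.  Estimates are maximum
#' likelihood (MLE); sigma follows the angle-doubling convention (the
#' doubled-space circular SD equals `2 * sigma` degrees of orientation).
#'
#' @param trials Trial table or path to a trial CSV.
#' @param restarts,seed Passed to [summarize_observers()].
#' @param include_perp Fit the perpendicular-global control (default TRUE).
#' @param out Optional directory; if given, the report bundle is written
#'   there via [write_report()].
#' @return A list of class `"crowdmix_report"`.
#' @export
run_pipeline <- function(trials, restarts = 20, seed = 1,
                         include_perp = TRUE, out = NULL) {
  if (is.character(trials)) trials <- read_trials(trials)
  so <- summarize_observers(trials, restarts = restarts, seed = seed,
                            include_perp = include_perp)
  sm <- so$summary
  conds <- unique(sm$condition)
  anovas <- list()
  for (v in c("precision", "gamma", "sigma", "p_t")) {
    if (length(conds) >= 2 &&
        all(table(sm$observer) == length(conds))) {
      anovas[[v]] <- rm_anova_gg(sm, v)
    }
  }
  aicc_tests <- NULL
  crowd <- sm[sm$condition %in% c("FA", "FM"), ]
  enough <- length(unique(crowd$observer)) >= 3
  if (nrow(crowd) && enough) {
    aicc_tests <- dplyr::bind_rows(lapply(split(crowd, crowd$condition),
      function(sub) {
        dplyr::bind_rows(
          dplyr::mutate(paired_t_cohen(sub$aicc_global_local,
                                       sub$aicc_standard),
                        condition = sub$condition[1],
                        contrast = "GL - Standard", .before = 1),
          dplyr::mutate(paired_t_cohen(sub$aicc_global_local,
                                       sub$aicc_local),
                        condition = sub$condition[1],
                        contrast = "GL - Local", .before = 1)
        )
      }))
  }
  mis <- if (nrow(crowd) && enough) misreport_tests(sm) else NULL
  report <- structure(list(
    seed = seed, n_observers = length(unique(sm$observer)),
    conditions = conds,
    estimator = "MLE (multi-start Nelder-Mead)",
    sigma_convention = "angle doubling: doubled-space circular SD = 2*sigma",
    summary = sm, anovas = anovas, aicc_tests = aicc_tests,
    misreport = mis, fits = so$fits
  ), class = "crowdmix_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' @export
print.crowdmix_report <- function(x, ...) {
  cat("Crowding mixture-model analysis report\n")
  cat(sprintf("  %d observers, conditions: %s; estimator: %s\n",
              x$n_observers, paste(x$conditions, collapse = ", "),
              x$estimator))
  grp <- dplyr::summarise(
    dplyr::group_by(x$summary, condition),
    mean_error = mean(mean_error), precision = mean(precision),
    gamma = mean(gamma), sigma = mean(sigma), p_t = mean(p_t),
    beta_loc = mean(beta_loc, na.rm = TRUE),
    beta_glo = mean(beta_glo, na.rm = TRUE),
    .groups = "drop"
  )
  cat("\nGroup means per condition:\n")
  print(as.data.frame(grp), digits = 3, row.names = FALSE)
  if (!is.null(x$aicc_tests)) {
    cat("\nPaired t-tests on per-observer AICc (negative mean favors Global-Local):\n")
    print(as.data.frame(x$aicc_tests), digits = 3, row.names = FALSE)
  }
  for (a in x$anovas) print(a)
  if (!is.null(x$misreport$perpendicular)) {
    cat("\nPerpendicular (+90 deg) global control, mean rate per condition:\n")
    print(as.data.frame(x$misreport$perpendicular), digits = 3,
          row.names = FALSE)
  }
  invisible(x)
}
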