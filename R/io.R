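SCHEMA_VERSION <- "crowdmix-trials-1"

trial_cols <- c("observer", "condition", "target_deg",
                paste0("flanker", 1:4, "_deg"), "global_deg", "response_deg")

#' Validate a trial table against the schema
#'
#' Columns: `observer` (string), `condition` (`U`/`FA`/`FM`), `target_deg`
#' (1-180), `flanker1_deg` ... `flanker4_deg` and `global_deg` (1-180,
#' empty on U rows), `response_deg` (in `(0, 180]`, decimals allowed).
#' Uncrowded rows must have empty flanker/global cells; crowded rows must
#' have all of them, with diagonal pairing `flanker1 == flanker3`,
#' `flanker2 == flanker4`.  Violations are reported with row numbers.
#'
#' @param trials Data frame.
#' @return The validated table, invisibly.
#' @export
validate_trials <- function(trials) {
  miss <- setdiff(trial_cols, names(trials))
  if (length(miss)) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_row <- function(which, what) {
    if (any(which)) {
      stop(sprintf("%s (row %s)", what,
                   paste(utils::head(base::which(which), 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_row(!trials$condition %in% c("U", "FA", "FM"),
          "condition must be one of U, FA, FM")
  ori_ok <- function(x) !is.na(x) & x > 0 & x <= 180
  bad_row(!ori_ok(trials$target_deg), "target_deg out of (0, 180]")
  resp <- trials$response_deg
  bad_row(!is.na(resp) & !(resp > 0 & resp <= 180),
          "response_deg out of (0, 180]")
  u <- trials$condition == "U"
  fl <- as.matrix(trials[, paste0("flanker", 1:4, "_deg")])
  bad_row(u & (rowSums(!is.na(fl)) > 0 | !is.na(trials$global_deg)),
          "U rows must have empty flanker/global cells")
  if (any(!u)) {
    bad_row(!u & (rowSums(is.na(fl)) > 0 | is.na(trials$global_deg)),
            "crowded rows must have all flanker and global orientations")
    filled <- !u & rowSums(is.na(fl)) == 0
    unpaired <- logical(nrow(trials))
    unpaired[filled] <-
      abs(wrap180(fl[filled, 1] - fl[filled, 3])) > 1e-9 |
      abs(wrap180(fl[filled, 2] - fl[filled, 4])) > 1e-9
    bad_row(unpaired,
            "flanker pairing violated (flanker1 != flanker3 or flanker2 != flanker4)")
    bad_row(filled & (!ori_ok(fl[, 1]) | !ori_ok(fl[, 2]) |
                        !ori_ok(trials$global_deg)),
            "flanker/global orientation out of (0, 180]")
  }
  invisible(trials)
}

#' Read and write trial tables
#'
#' Plain CSV in the trial-table schema (see [validate_trials()]).  Extra
#' columns are kept with a message; validation errors name the offending
#' rows.  `write_trials()` / `read_trials()` round-trip exactly.
#'
#' @param path CSV file path.
#' @param trials Trial table.
#' @return `read_trials()`: a validated tibble.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(trials), c(trial_cols, "component"))
  if (length(extra)) {
    message("note: ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  trials$observer <- as.character(trials$observer)
  validate_trials(trials)
  tibble::as_tibble(trials)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

fit_to_record <- function(fit) {
  list(model = fit$model,
       params = if (is.null(fit$params)) NULL else
         Filter(Negate(is.null), unclass(fit$params)),
       loglik = fit$loglik, n_trials = fit$n_trials,
       k_params = fit$k_params, aicc = fit$aicc,
       n_restarts = fit$n_restarts, converged = fit$converged,
       best_start_index = fit$best_start_index,
       estimator = "MLE")
}

#' Write a report bundle to disk
#'
#' Writes the per-observer summary and group tables as CSV, every fit as a
#' JSON record, and a human-readable Markdown report.  Every file embeds
#' the schema version and the analysis seed, so a re-run with the same
#' inputs is byte-identical.
#'
#' @param report A `"crowdmix_report"` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "observer_summary.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(report$aicc_tests)) {
    utils::write.csv(report$aicc_tests, file.path(dir, "aicc_tests.csv"),
                     row.names = FALSE, na = "")
  }
  json <- list(
    schema = SCHEMA_VERSION, seed = report$seed,
    estimator = report$estimator,
    sigma_convention = report$sigma_convention,
    n_observers = report$n_observers, conditions = report$conditions,
    anovas = lapply(report$anovas, function(a)
      list(test = as.list(a$test), pairwise = a$pairwise)),
    aicc_tests = report$aicc_tests,
    misreport = report$misreport,
    fits = lapply(report$fits, function(cell) lapply(cell, fit_to_record))
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  md <- c(
    "# Crowding mixture-model analysis", "",
    sprintf("- schema: %s, seed: %d", SCHEMA_VERSION, report$seed),
    sprintf("- estimator: %s", report$estimator),
    sprintf("- sigma convention: %s", report$sigma_convention),
    sprintf("- observers: %d; conditions: %s", report$n_observers,
            paste(report$conditions, collapse = ", ")),
    "",
    utils::capture.output(print(report))
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Command-line interface
#'
#' Thin shell entry point over the package functions, used by the
#' `inst/scripts/crowdmix` launcher.  Subcommands:
#' \describe{
#'   \item{simulate}{`--seed`, `--out DIR` (+ optional `--config YAML`):
#'     generate a synthetic dataset; writes `trials.csv` and
#'     `ground_truth.json`.}
#'   \item{fit}{`--trials CSV`, `--out DIR`, `--models LIST`,
#'     `--restarts N`, `--seed`: per observer x condition fits as JSON.}
#'   \item{analyze}{`--trials CSV`, `--out DIR`, `--restarts N`, `--seed`:
#'     full report bundle.}
#' }
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly.
#' @export
crowdmix_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: crowdmix <simulate|fit|analyze> [options]",
    "  simulate --seed INT --out DIR [--config YAML]",
    "  fit      --trials CSV --out DIR [--models LIST] [--restarts INT] [--seed INT]",
    "  analyze  --trials CSV --out DIR [--restarts INT] [--seed INT]",
    sep = "\n")
  fail <- function(msg) {
    message(msg, "\n", usage)
    return(invisible(1L))
  }
  if (length(args) < 1) return(fail("no subcommand given"))
  cmd <- args[1]
  opts <- list(seed = 1L, restarts = 20L, models = "standard,local,global_local")
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- rest[i]
    if (!startsWith(key, "--") || i == length(rest)) {
      return(fail(paste("bad or valueless flag:", key)))
    }
    k <- sub("^--", "", key)
    if (!k %in% c("seed", "out", "trials", "models", "restarts", "config")) {
      return(fail(paste("unknown flag:", key)))
    }
    opts[[k]] <- rest[i + 1]
    i <- i + 2
  }
  opts$seed <- as.integer(opts$seed)
  opts$restarts <- as.integer(opts$restarts)
  res <- tryCatch({
    switch(cmd,
      simulate = {
        if (is.null(opts$out)) stop("simulate needs --out")
        cfg_args <- if (!is.null(opts$config)) yaml::read_yaml(opts$config)
                    else list()
        cfg_args$seed <- opts$seed
        cfg <- do.call(design_config, cfg_args)
        ds <- gen_dataset(cfg)
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        write_trials(ds$trials, file.path(opts$out, "trials.csv"))
        jsonlite::write_json(
          list(schema = SCHEMA_VERSION, seed = opts$seed,
               truth = ds$truth),
          file.path(opts$out, "ground_truth.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
        0L
      },
      fit = {
        if (is.null(opts$trials) || is.null(opts$out)) {
          stop("fit needs --trials and --out")
        }
        trials <- read_trials(opts$trials)
        models <- strsplit(opts$models, ",")[[1]]
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        cells <- split(trials, list(trials$observer, trials$condition),
                       drop = TRUE)
        recs <- lapply(cells, function(cell) {
          ms <- if (cell$condition[1] == "U") intersect(models, "standard")
                else models
          if (!length(ms)) return(NULL)
          lapply(fit_models(cell, models = ms, restarts = opts$restarts,
                            seed = opts$seed), fit_to_record)
        })
        jsonlite::write_json(
          list(schema = SCHEMA_VERSION, seed = opts$seed,
               fits = Filter(Negate(is.null), recs)),
          file.path(opts$out, "fits.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
        0L
      },
      analyze = {
        if (is.null(opts$trials) || is.null(opts$out)) {
          stop("analyze needs --trials and --out")
        }
        run_pipeline(opts$trials, restarts = opts$restarts,
                     seed = opts$seed, out = opts$out)
        0L
      },
      stop("unknown subcommand: ", cmd)
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e), "\n", usage)
    1L
  })
  invisible(res)
}
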