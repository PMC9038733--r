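# one simulated observer x condition cell, built in code
make_cell <- function(n = 200, condition = "FA", params = NULL,
                      model = "global_local", seed = 1, observer = "obs01") {
  params <- params %||% list(gamma = 0.10, sigma = 8,
                             beta_loc = 0.15, beta_glo = 0.08)
  if (condition == "U") {
    model <- "standard"
    params <- params[c("gamma", "sigma")]
  }
  d <- gen_design(n, condition, observer = observer, seed = seed)
  gen_responses(d, model, params, seed = seed + 1L)
}

# a single crowded trial as a named list
one_trial <- function(target = 40, f1 = 100, f2 = 160, g = 70) {
  list(target_deg = target, flanker1_deg = f1, flanker2_deg = f2,
       flanker3_deg = f1, flanker4_deg = f2, global_deg = g)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
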