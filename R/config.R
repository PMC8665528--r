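#' Read a flat model configuration file
#'
#' Reads a flat key-value YAML document listing hyperparameters, MCMC
#' settings, the model variant and seeds, and translates it into the
#' `hyper`, `control` and `model` arguments of [coxbvs()]. Recognized
#' keys: `model` (coxbvs_sl, sub_struct, subgroup, pooled), `n_iter`,
#' `burn_in`, `seed`, `preset`, and any field of [coxbvs_hyper()]
#' (a0, tau, c, a, b1, b2, nu0, nu1, lambda, pi_G, pi_gamma).
#'
#' @param path path to the YAML file.
#' @param p number of genes (needed for the default `pi_G`).
#' @return list with elements `model`, `hyper`, `control`.
#' @export
read_coxbvs_config <- function(path, p) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  model <- cfg$model %||% "coxbvs_sl"
  preset <- cfg$preset %||% "default"
  hyper_keys <- intersect(names(cfg),
                          c("a0", "tau", "c", "a", "b1", "b2",
                            "nu0", "nu1", "lambda", "pi_G", "pi_gamma"))
  hyper <- do.call(coxbvs_hyper,
                   c(list(p = p, preset = preset), cfg[hyper_keys]))
  control <- coxbvs_control(
    n_iter = cfg$n_iter %||% 20000,
    burn_in = cfg$burn_in %||% 10000,
    seed = cfg$seed %||% 1L)
  list(model = model, hyper = hyper, control = control)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
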