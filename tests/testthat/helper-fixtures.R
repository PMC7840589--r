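# Small-scale study configurations used across the test files.

# three cohorts x 60, eight biomarkers in three families: fast but keeps
# the full pipeline structure (families, censoring, block missingness off)
tiny_config <- function(seed = 1L, ...) {
  args <- list(
    cohort_sizes = c(a = 60, b = 60, c = 60),
    family_sizes = c(f1 = 3, f2 = 3, f3 = 2),
    covariate_missing_rate = 0.01,
    cohort_log_means = list(externalizing = log(c(4, 5, 6)),
                            internalizing = log(c(3, 3, 3))),
    seed = seed)
  args[names(list(...))] <- list(...)
  # keep one baseline log-mean per cohort when cohort_sizes is overridden
  if (!"cohort_log_means" %in% names(list(...))) {
    k <- length(args$cohort_sizes)
    args$cohort_log_means <- lapply(args$cohort_log_means, rep_len, k)
  }
  do.call(synth_config, args)
}

# a complete (no censoring, no missingness) analysis table; with nothing to
# impute, impute_chained returns m identical copies
complete_table <- function(seed = 1L, n_per_cohort = 60, ...) {
  cfg <- tiny_config(seed = seed,
                     cohort_sizes = setNames(rep(n_per_cohort, 3),
                                             c("a", "b", "c")),
                     lod_quantiles = 0, covariate_missing_rate = 0, ...)
  st <- generate_study(cfg)
  prep <- prepare_exposures(st$panel, st$covariates, seed = seed)
  build_analysis_table(prep, st$outcomes)
}

# build an analysis table with missingness and impute it
small_stack <- function(seed = 1L, m = 3L, n_iter = 2L, ...) {
  cfg <- tiny_config(seed = seed, ...)
  st <- generate_study(cfg)
  prep <- prepare_exposures(st$panel, st$covariates, seed = seed)
  tab <- build_analysis_table(prep, st$outcomes)
  impute_chained(tab, m = m, n_iter = n_iter, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direct NB2 log-likelihood, used by the generic-optimizer oracle
nb_ll_direct <- function(par, y, X) {
  beta <- par[-length(par)]
  theta <- exp(par[length(par)])
  mu <- exp(drop(X %*% beta))
  -sum(lgamma(y + theta) - lgamma(theta) - lfactorial(y) +
         theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu)))
}
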