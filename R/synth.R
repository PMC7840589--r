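#' Configuration for the multi-cohort exposome simulator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate a pooled five-cohort pregnancy study: 708 subjects split
#' 46/193/218/83/168 across cohorts, 47 exposure biomarkers in 8 chemical
#' families (organochlorines, PBDEs, PFASs, metals/elements, phthalate
#' metabolites, phenols, organophosphate pesticide metabolites, cotinine)
#' with within-family correlation, cohort-specific log-scale median shifts,
#' left-censoring at a per-biomarker limit of detection (39 of 47 biomarkers
#' detected in at least ~95\% of samples, 8 detected less often),
#' cohort-level block missingness (whole biomarker families unmeasured in
#' some cohorts), and two negative-binomial count outcomes on a 0-20 scale
#' driven by a log-linear model on IQR-standardized exposures.
#'
#' @param cohort_sizes named integer vector of subjects per cohort.
#' @param family_sizes named integer partition of biomarkers into families.
#' @param within_family_rho,between_family_rho block correlations of the
#'   latent log exposures, each in [0, 1).
#' @param cohort_shift_sd SD of cohort-specific log-scale biomarker median
#'   shifts (0 switches cohort heterogeneity in exposures off).
#' @param biomarker_sd per-biomarker log-scale SD.
#' @param lod_quantiles per-biomarker censoring quantile in [0, 1); either a
#'   single value, or a full vector, or NULL for the default regime
#'   (0.05 for 39 biomarkers, 0.30 for 8).
#' @param block_missing list of \code{list(cohort =, biomarkers =)} pairs
#'   that are entirely unmeasured; NULL for the default pattern (metals
#'   unmeasured in the two largest cohorts, PBDEs in one).
#' @param true_log_irr 47 x 2 matrix of true per-IQR log incidence-rate
#'   ratios (columns \code{externalizing}, \code{internalizing}); defaults
#'   to the global null.
#' @param covariate_effects per-outcome named lists of log-scale covariate
#'   effects (names \code{sex_male}, \code{smoking_yes}, or any continuous
#'   covariate column).
#' @param cohort_log_means per-outcome log baseline means by cohort; the
#'   defaults give one cohort a markedly lower externalizing level, echoing
#'   the heterogeneity seen in pooled cohort studies.
#' @param dispersion_theta NB2 dispersion (> 0) of the outcomes.
#' @param outcome_max integer cap of the score scale (overflowing draws are
#'   resampled).
#' @param covariate_missing_rate missingness rate applied to imputable
#'   covariates.
#' @param seed master seed; all generator randomness derives from it.
#'
#' @return object of class \code{synth_config}.
#' @export
synth_config <- function(cohort_sizes = c(coh1 = 46, coh2 = 193, coh3 = 218,
                                          coh4 = 83, coh5 = 168),
                         family_sizes = c(organochlorines = 8, pbdes = 2,
                                          pfas = 5, metals = 9,
                                          phthalates = 10, phenols = 7,
                                          op_pesticides = 5, cotinine = 1),
                         within_family_rho = 0.5,
                         between_family_rho = 0.1,
                         cohort_shift_sd = 0.3,
                         biomarker_sd = 1,
                         lod_quantiles = NULL,
                         block_missing = NULL,
                         true_log_irr = NULL,
                         covariate_effects = list(
                           externalizing = c(sex_male = log(1.25),
                                             smoking_yes = log(1.2)),
                           internalizing = c(smoking_yes = log(1.1))),
                         cohort_log_means = list(
                           externalizing = log(c(1.2, 5.5, 5.5, 6.5, 5.5)),
                           internalizing = log(c(2.5, 3.5, 3.5, 3.8, 3.3))),
                         dispersion_theta = 2,
                         outcome_max = 20L,
                         covariate_missing_rate = 0.02,
                         seed = 1L) {
  if (is.null(names(cohort_sizes)))
    names(cohort_sizes) <- paste0("coh", seq_along(cohort_sizes))
  if (is.null(names(family_sizes)))
    names(family_sizes) <- paste0("fam", seq_along(family_sizes))
  n_biomarkers <- sum(family_sizes)
  biomarker_names <- unlist(lapply(names(family_sizes), function(f) {
    k <- family_sizes[[f]]
    if (k == 1L) f else paste0(f, "_", seq_len(k))
  }), use.names = FALSE)

  if (is.null(lod_quantiles)) {
    lod_quantiles <- setNames(rep(0.05, n_biomarkers), biomarker_names)
    # a handful of poorly detected biomarkers, spread over families
    low_detect <- intersect(
      c("organochlorines_8", "pbdes_2", "pfas_5", "metals_8", "metals_9",
        "phthalates_10", "phenols_7", "op_pesticides_5"),
      biomarker_names)
    lod_quantiles[low_detect] <- 0.30
  } else if (length(lod_quantiles) == 1L) {
    lod_quantiles <- setNames(rep(lod_quantiles, n_biomarkers),
                              biomarker_names)
  } else {
    if (length(lod_quantiles) != n_biomarkers)
      stop("lod_quantiles must have one entry per biomarker")
    if (is.null(names(lod_quantiles))) names(lod_quantiles) <- biomarker_names
  }

  fam_of <- rep(names(family_sizes), family_sizes)
  if (is.null(block_missing)) {
    metals <- biomarker_names[fam_of == "metals"]
    pbdes <- biomarker_names[fam_of == "pbdes"]
    block_missing <- list()
    cs <- names(cohort_sizes)
    if (length(metals) && length(cs) >= 3)
      block_missing <- c(block_missing,
                         list(list(cohort = cs[3], biomarkers = metals),
                              list(cohort = cs[2], biomarkers = metals)))
    if (length(pbdes) && length(cs) >= 4)
      block_missing <- c(block_missing,
                         list(list(cohort = cs[4], biomarkers = pbdes)))
  }

  if (is.null(true_log_irr)) {
    true_log_irr <- matrix(0, n_biomarkers, 2,
                           dimnames = list(biomarker_names,
                                           c("externalizing",
                                             "internalizing")))
  } else {
    true_log_irr <- as.matrix(true_log_irr)
    if (nrow(true_log_irr) != n_biomarkers || ncol(true_log_irr) != 2)
      stop("true_log_irr must be n_biomarkers x 2")
    rownames(true_log_irr) <- biomarker_names
    colnames(true_log_irr) <- c("externalizing", "internalizing")
  }

  stopifnot(all(cohort_sizes > 0),
            within_family_rho >= 0, within_family_rho < 1,
            between_family_rho >= 0, between_family_rho < 1,
            cohort_shift_sd >= 0, biomarker_sd > 0,
            all(lod_quantiles >= 0), all(lod_quantiles < 1),
            dispersion_theta > 0, outcome_max >= 1,
            covariate_missing_rate >= 0, covariate_missing_rate < 1)
  for (nm in names(cohort_log_means)) {
    if (length(cohort_log_means[[nm]]) != length(cohort_sizes))
      stop("cohort_log_means must give one value per cohort")
  }

  structure(list(
    cohort_sizes = cohort_sizes,
    n = sum(cohort_sizes),
    family_sizes = family_sizes,
    n_biomarkers = n_biomarkers,
    biomarker_names = biomarker_names,
    family_of = setNames(fam_of, biomarker_names),
    within_family_rho = within_family_rho,
    between_family_rho = between_family_rho,
    cohort_shift_sd = cohort_shift_sd,
    biomarker_sd = biomarker_sd,
    lod_quantiles = lod_quantiles,
    block_missing = block_missing,
    true_log_irr = true_log_irr,
    covariate_effects = covariate_effects,
    cohort_log_means = cohort_log_means,
    dispersion_theta = dispersion_theta,
    outcome_max = as.integer(outcome_max),
    covariate_missing_rate = covariate_missing_rate,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# family -> medium / standardization / transform conventions
family_medium <- function(fam) {
  urine <- c("phthalates", "phenols", "op_pesticides", "cotinine")
  ifelse(fam %in% urine, "urine", "blood")
}
family_standardization <- function(fam) {
  out <- rep("none", length(fam))
  out[fam %in% c("organochlorines", "pbdes")] <- "lipids"     # lipophilic
  out[fam %in% c("phthalates", "phenols", "op_pesticides",
                 "cotinine")] <- "creatinine"                 # urinary
  out
}
family_transform <- function(fam) ifelse(fam == "cotinine", "ln", "log2")

#' Generate the covariate table
#'
#' Draws cohort labels with the configured sizes and the standard adjustment
#' factors of a pregnancy-cohort analysis: season of conception (4 levels),
#' child sex, cohort-specific child age at assessment, parity (3), maternal
#' education (3), work status, active smoking, maternal age, pre-pregnancy
#' BMI (continuous + 4 classes), gestational weight gain (kg), and urinary
#' creatinine / total serum lipids for concentration standardization.
#' Missingness at rate \code{missing_rate} is injected into the imputable
#' covariates; the complete pre-missingness table is kept in the
#' \code{"complete"} attribute so outcomes can be generated from it.
#'
#' @param config a \code{synth_config}.
#' @param seed integer seed.
#' @param missing_rate overrides \code{config$covariate_missing_rate}.
#' @return data.frame with one row per subject.
#' @export
generate_covariates <- function(config, seed = config$seed,
                                missing_rate = config$covariate_missing_rate) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n
  cohort <- factor(rep(names(config$cohort_sizes), config$cohort_sizes),
                   levels = names(config$cohort_sizes))

  age_ranges <- list(c(4.9, 5.7), c(5.3, 5.9), c(6.3, 7.0),
                     c(3.9, 5.1), c(4.0, 4.3))
  age_ranges <- rep(age_ranges, length.out = length(config$cohort_sizes))
  child_age <- numeric(n)
  for (k in seq_along(config$cohort_sizes)) {
    idx <- which(as.integer(cohort) == k)
    child_age[idx] <- runif(length(idx), age_ranges[[k]][1],
                            age_ranges[[k]][2])
  }

  rcat <- function(levels, probs) {
    factor(sample(levels, n, replace = TRUE, prob = probs), levels = levels)
  }
  season <- rcat(c("jan_mar", "apr_jun", "jul_sep", "oct_dec"),
                 c(0.29, 0.23, 0.25, 0.23))
  sex <- rcat(c("female", "male"), c(0.44, 0.56))
  parity <- rcat(c("nulliparous", "one_child", "two_plus"),
                 c(0.45, 0.38, 0.17))
  education <- rcat(c("primary", "secondary", "university"),
                    c(0.13, 0.42, 0.45))
  work <- rcat(c("unemployed", "employed"), c(0.19, 0.81))
  smoking <- rcat(c("no", "yes"), c(0.79, 0.21))
  maternal_age <- rnorm(n, 30.7, 4.5)
  bmi <- rlnorm(n, log(23.5), 0.17)
  bmi_class <- cut(bmi, c(0, 18.5, 25, 30, Inf),
                   labels = c("underweight", "normal", "overweight",
                              "obese"), right = FALSE)
  gwg_kg <- rnorm(n, 13.5, 5.5)
  creatinine_gl <- rlnorm(n, log(1.0), 0.4)
  lipids_gl <- rlnorm(n, log(6.0), 0.2)

  out <- data.frame(id = seq_len(n), cohort = cohort, season = season,
                    sex = sex, child_age = child_age, parity = parity,
                    education = education, work = work, smoking = smoking,
                    maternal_age = maternal_age, bmi = bmi,
                    bmi_class = bmi_class, gwg_kg = gwg_kg,
                    creatinine_gl = creatinine_gl, lipids_gl = lipids_gl)
  complete <- out

  if (missing_rate > 0) {
    imputable <- c("season", "parity", "education", "work", "smoking",
                   "maternal_age", "bmi", "bmi_class", "gwg_kg")
    for (v in imputable) {
      hit <- runif(n) < missing_rate
      out[[v]][hit] <- NA
    }
    # BMI class follows continuous BMI
    out$bmi_class[is.na(out$bmi)] <- NA
  }
  attr(out, "complete") <- complete
  out
}

#' Generate the exposure biomarker panel
#'
#' Latent log concentrations are drawn from a multivariate normal with block
#' correlation (\code{within_family_rho} inside chemical families,
#' \code{between_family_rho} across), shifted by cohort-specific log-scale
#' medians, then exponentiated. A per-biomarker limit of detection is placed
#' at the configured quantile of the pooled distribution; values below it
#' are flagged censored and masked. Block-missing (cohort, biomarker) cells
#' are flagged missing. The complete latent matrix is retained as ground
#' truth.
#'
#' @param config a \code{synth_config}.
#' @param seed integer seed.
#' @return object of class \code{exposome_panel}: concentration matrix with
#'   censored/missing cells set to \code{NA}, logical \code{censored} and
#'   \code{missing} masks (always disjoint), per-biomarker metadata
#'   (\code{lod}, \code{medium}, \code{family}, \code{transform},
#'   \code{standardize}), the cohort factor, and a \code{truth} element
#'   holding the uncensored complete matrix and generator parameters.
#' @export
generate_exposures <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n
  p <- config$n_biomarkers
  fam <- config$family_of

  R <- matrix(config$between_family_rho, p, p)
  same_fam <- outer(fam, fam, "==")
  R[same_fam] <- config$within_family_rho
  diag(R) <- 1
  L <- tryCatch(chol(R), error = function(e)
    stop("implied correlation matrix is not positive definite ",
         "(within_family_rho = ", config$within_family_rho,
         ", between_family_rho = ", config$between_family_rho, ")"))

  base_meanlog <- rnorm(p, 0, 1)                       # biomarker medians
  shifts <- matrix(rnorm(length(config$cohort_sizes) * p, 0,
                         config$cohort_shift_sd),
                   nrow = length(config$cohort_sizes),
                   dimnames = list(names(config$cohort_sizes),
                                   config$biomarker_names))
  Z <- matrix(rnorm(n * p), n, p) %*% L
  cohort <- factor(rep(names(config$cohort_sizes), config$cohort_sizes),
                   levels = names(config$cohort_sizes))
  latent_log <- sweep(Z * config$biomarker_sd, 2, base_meanlog, "+") +
    shifts[as.integer(cohort), , drop = FALSE]
  latent <- exp(latent_log)
  dimnames(latent) <- list(NULL, config$biomarker_names)

  lod <- vapply(seq_len(p), function(j)
    quantile(latent[, j], config$lod_quantiles[j], names = FALSE, type = 7),
    numeric(1))
  censored <- sweep(latent, 2, lod, "<")

  missing <- matrix(FALSE, n, p, dimnames = dimnames(latent))
  for (bm in config$block_missing) {
    rows <- which(cohort == bm$cohort)
    cols <- intersect(bm$biomarkers, colnames(latent))
    missing[rows, cols] <- TRUE
  }
  censored[missing] <- FALSE                            # masks are disjoint

  conc <- latent
  conc[censored | missing] <- NA

  meta <- data.frame(
    name = config$biomarker_names,
    family = unname(fam),
    medium = family_medium(unname(fam)),
    lod = lod,
    transform = family_transform(unname(fam)),
    standardize = family_standardization(unname(fam)),
    stringsAsFactors = FALSE
  )

  structure(list(
    conc = conc,
    censored = censored,
    missing = missing,
    meta = meta,
    cohort = cohort,
    truth = list(latent = latent, base_meanlog = base_meanlog,
                 cohort_shifts = shifts, config = config)
  ), class = "exposome_panel")
}

#' @export
print.exposome_panel <- function(x, ...) {
  cat("Exposome panel:", nrow(x$conc), "subjects x", ncol(x$conc),
      "biomarkers in", length(unique(x$meta$family)), "families\n")
  cat(sprintf("  censored cells: %d (%.1f%%), missing cells: %d (%.1f%%)\n",
              sum(x$censored), 100 * mean(x$censored),
              sum(x$missing), 100 * mean(x$missing)))
  cat("  cohorts:", paste(sprintf("%s (n=%d)", levels(x$cohort),
                                  tabulate(x$cohort)), collapse = ", "),
      "\n")
  invisible(x)
}

# IQR-standardized transformed latent exposures: the scale on which the
# true log-IRRs are defined.
truth_standardized <- function(panel) {
  latent <- panel$truth$latent
  out <- latent
  for (j in seq_len(ncol(latent))) {
    v <- if (panel$meta$transform[j] == "ln") log(latent[, j])
         else log2(latent[, j])
    iqr <- diff(quantile(v, c(0.25, 0.75), names = FALSE, type = 7))
    out[, j] <- v / iqr
  }
  out
}

#' Generate count outcomes from the analysis model
#'
#' Inverts the analysis model: for each subject the mean is
#' \eqn{\mu = \exp(\alpha_{cohort} + X_{std} \beta + C \gamma)} where
#' \eqn{X_{std}} are the IQR-standardized transformed latent exposures and
#' \eqn{C \gamma} the configured covariate effects; scores are drawn from
#' NB2(\eqn{\mu}, \eqn{\theta}) and draws exceeding \code{outcome_max} are
#' resampled (capped after 100 rounds).
#'
#' @param panel an \code{exposome_panel}.
#' @param covariates covariate table from \code{generate_covariates} (its
#'   complete pre-missingness version is used when available).
#' @param config a \code{synth_config}.
#' @param seed integer seed.
#' @return data.frame with integer columns \code{externalizing} and
#'   \code{internalizing}.
#' @export
generate_outcomes <- function(panel, covariates, config, seed = config$seed) {
  stopifnot(inherits(panel, "exposome_panel"))
  set.seed(seed)
  cov_full <- attr(covariates, "complete") %||% covariates
  if (anyNA(cov_full[c("sex", "smoking")]))
    stop("outcome generation needs complete sex/smoking covariates")
  Xstd <- truth_standardized(panel)
  n <- nrow(Xstd)

  draw_outcome <- function(outcome) {
    eta <- config$cohort_log_means[[outcome]][as.integer(panel$cohort)] +
      drop(Xstd %*% config$true_log_irr[, outcome])
    eff <- config$covariate_effects[[outcome]]
    for (nm in names(eff)) {
      v <- switch(nm,
                  sex_male = as.numeric(cov_full$sex == "male"),
                  smoking_yes = as.numeric(cov_full$smoking == "yes"),
                  cov_full[[nm]])
      if (is.null(v)) stop("unknown covariate effect: ", nm)
      eta <- eta + eff[[nm]] * v
    }
    mu <- exp(eta)
    if (any(!is.finite(mu)) || any(mu > 1e6))
      stop("outcome mean overflow; check true_log_irr / covariate_effects")
    y <- rnbinom(n, size = config$dispersion_theta, mu = mu)
    for (i in seq_len(100)) {           # truncate by resampling overflows
      over <- which(y > config$outcome_max)
      if (!length(over)) break
      y[over] <- rnbinom(length(over), size = config$dispersion_theta,
                         mu = mu[over])
    }
    y[y > config$outcome_max] <- config$outcome_max
    as.integer(y)
  }

  data.frame(externalizing = draw_outcome("externalizing"),
             internalizing = draw_outcome("internalizing"))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper drawing covariates, the exposure panel and the two
#' outcomes from one master seed (stage seeds are derived deterministically,
#' so identical configuration and seed give bit-identical tables).
#'
#' @param config a \code{synth_config}.
#' @return object of class \code{synth_study}: \code{panel},
#'   \code{covariates}, \code{outcomes}, and \code{truth} (the panel's
#'   ground-truth element plus the true coefficient matrices).
#' @export
generate_study <- function(config = synth_config()) {
  seeds <- derive_seeds(config$seed, 3)
  covariates <- generate_covariates(config, seed = seeds[1])
  panel <- generate_exposures(config, seed = seeds[2])
  outcomes <- generate_outcomes(panel, covariates, config, seed = seeds[3])
  structure(list(panel = panel, covariates = covariates, outcomes = outcomes,
                 truth = c(panel$truth,
                           list(true_log_irr = config$true_log_irr,
                                covariate_effects = config$covariate_effects))),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  print(x$panel)
  cat("Outcomes: externalizing (mean ",
      round(mean(x$outcomes$externalizing), 2), "), internalizing (mean ",
      round(mean(x$outcomes$internalizing), 2), ")\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic study as delimited text
#'
#' Persists the three pipeline input tables (exposure concentrations with
#' censoring and missingness flags, biomarker metadata, covariates,
#' outcomes) as CSV plus a ground-truth JSON sidecar.
#'
#' @param study a \code{synth_study}.
#' @param dir output directory (created if needed).
#' @return \code{write_study} returns \code{dir} invisibly;
#'   \code{read_study} returns a \code{synth_study} (without the latent
#'   ground-truth matrix, which lives in the JSON sidecar).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  w(cbind(id = seq_len(nrow(study$panel$conc)),
          cohort = as.character(study$panel$cohort),
          as.data.frame(study$panel$conc)), "exposures.csv")
  w(as.data.frame(study$panel$censored * 1L), "censored_mask.csv")
  w(as.data.frame(study$panel$missing * 1L), "missing_mask.csv")
  w(study$panel$meta, "biomarkers.csv")
  w(study$covariates, "covariates.csv")
  w(study$outcomes, "outcomes.csv")
  truth <- list(true_log_irr = study$truth$true_log_irr,
                base_meanlog = study$truth$base_meanlog,
                cohort_shifts = study$truth$cohort_shifts)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  r <- function(f, ...) read.csv(file.path(dir, f), ...)
  expo <- r("exposures.csv")
  meta <- r("biomarkers.csv")
  cohort <- factor(expo$cohort, levels = unique(expo$cohort))
  conc <- as.matrix(expo[, meta$name, drop = FALSE])
  censored <- as.matrix(r("censored_mask.csv")) == 1
  missing <- as.matrix(r("missing_mask.csv")) == 1
  dimnames(censored) <- dimnames(missing) <- dimnames(conc)
  covariates <- r("covariates.csv")
  for (v in c("cohort", "season", "sex", "parity", "education", "work",
              "smoking", "bmi_class"))
    if (v %in% names(covariates)) covariates[[v]] <- factor(covariates[[v]])
  panel <- structure(list(conc = conc, censored = censored,
                          missing = missing, meta = meta, cohort = cohort,
                          truth = NULL), class = "exposome_panel")
  structure(list(panel = panel, covariates = covariates,
                 outcomes = r("outcomes.csv"), truth = NULL),
            class = "synth_study")
}
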