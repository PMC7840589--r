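#' Pipeline configuration
#'
#' Collects every stage's settings: the synthetic-data configuration (or a
#' directory of input tables), the imputation profile, the adjustment set,
#' outcomes, significance level, detection threshold, the LASSO profile and
#' the sensitivity-analysis toggles. All stage seeds derive
#' deterministically from \code{seed}.
#'
#' @param synth a \code{synth_config} (ignored when \code{input_dir} is
#'   given).
#' @param input_dir optional directory of study CSVs from
#'   \code{write_study}.
#' @param m imputed datasets (study-scale 100; desk-scale default 10).
#' @param n_iter chained-equation sweeps.
#' @param covariates adjustment covariates.
#' @param outcomes outcome columns to scan.
#' @param alpha FWER level.
#' @param min_detect detection-frequency filter.
#' @param n_lambda,k LASSO grid length and CV folds.
#' @param lasso_threshold stability-selection retention threshold.
#' @param sensitivity named list of logical toggles: \code{linearity},
#'   \code{coexposure}, \code{sex_interaction}, \code{gwg_stratification},
#'   \code{complete_case}, \code{cohort_exclusion}, \code{heterogeneity}.
#' @param exclude_cohort cohort dropped in the cohort-exclusion analysis
#'   (default: the smallest).
#' @param out_dir output directory.
#' @param seed master seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synth = synth_config(), input_dir = NULL,
                            m = 10L, n_iter = 5L,
                            covariates = default_covariates(),
                            outcomes = c("externalizing", "internalizing"),
                            alpha = 0.05, min_detect = 0.10,
                            n_lambda = 20L, k = 10L,
                            lasso_threshold = 0.5,
                            sensitivity = list(),
                            exclude_cohort = NULL,
                            out_dir = tempfile("expowas_run_"),
                            seed = 1L) {
  defaults <- list(linearity = TRUE, coexposure = TRUE,
                   sex_interaction = TRUE, gwg_stratification = TRUE,
                   complete_case = TRUE, cohort_exclusion = TRUE,
                   heterogeneity = TRUE)
  defaults[names(sensitivity)] <- sensitivity
  structure(list(synth = synth, input_dir = input_dir, m = as.integer(m),
                 n_iter = as.integer(n_iter), covariates = covariates,
                 outcomes = outcomes, alpha = alpha,
                 min_detect = min_detect, n_lambda = as.integer(n_lambda),
                 k = as.integer(k), lasso_threshold = lasso_threshold,
                 sensitivity = defaults, exclude_cohort = exclude_cohort,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the defaults of
#' \code{pipeline_config}; a \code{synth} block overrides fields of
#' \code{synth_config}.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (!is.null(synth_args$cohort_sizes))
    synth_args$cohort_sizes <- unlist(synth_args$cohort_sizes)
  if (!is.null(synth_args$family_sizes))
    synth_args$family_sizes <- unlist(synth_args$family_sizes)
  y$synth <- do.call(synth_config, synth_args)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, y[intersect(names(y), known)])
}

write_table_csv <- function(x, dir, name) {
  write.csv(as.data.frame(x), file.path(dir, name), row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes, in fixed order: synthetic data generation (or loading),
#' exposure preprocessing, chained-equations multiple imputation, stability
#' selection (adjusted LASSO) and the ExWAS per outcome, then the enabled
#' sensitivity analyses (linearity of detected associations, coexposure
#' adjustment, sex interactions, weight-gain stratification of the
#' organochlorines, complete-case scan, cohort-exclusion scan, and
#' between-cohort heterogeneity of the detected associations). Each stage
#' writes CSV/JSON artifacts into \code{config$out_dir}; a run log records
#' stages and seeds; \code{summary.json} cross-references the retained and
#' detected exposures.
#'
#' @param config a \code{pipeline_config}.
#' @return object of class \code{pipeline_result} (invisibly): all stage
#'   outputs plus the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|",
                            ..., "\n", file = log_path, append = TRUE)
  seeds <- derive_seeds(config$seed, 6)
  logf("pipeline start; master seed", config$seed)

  # --- data -----------------------------------------------------------
  if (!is.null(config$input_dir)) {
    study <- read_study(config$input_dir)
    logf("loaded study from", config$input_dir)
  } else {
    config$synth$seed <- seeds[1]
    study <- generate_study(config$synth)
    write_study(study, file.path(config$out_dir, "inputs"))
    logf("generated synthetic study; seed", seeds[1])
  }

  # --- prep -----------------------------------------------------------
  prep <- prepare_exposures(study$panel, study$covariates,
                            min_detect = config$min_detect,
                            seed = seeds[2])
  tab <- build_analysis_table(prep, study$outcomes)
  jsonlite::write_json(
    list(iqr = as.list(prep$spec$iqr),
         transform = as.list(prep$spec$transform),
         quartile_type = prep$spec$quartile_type),
    file.path(config$out_dir, "transform_spec.json"), auto_unbox = TRUE,
    digits = NA)
  logf("prep done;", length(attr(tab, "exposure_names")),
       "exposures retained; LOD-imputation seed", seeds[2])

  # --- multiple imputation -------------------------------------------
  stack <- impute_chained(tab, m = config$m, n_iter = config$n_iter,
                          seed = seeds[3])
  logf("imputation done; m =", config$m, "; seed", seeds[3])
  exposures <- stack$exposure_names

  results <- list(config = config, analysis_table = tab, stack = stack)
  summary_list <- list(n = nrow(tab), n_exposures = length(exposures),
                       m = config$m, alpha = config$alpha)
  sens <- config$sensitivity

  for (oc in config$outcomes) {
    # --- adjusted LASSO + stability selection ------------------------
    ss <- stability_select(stack, oc, exposures = exposures,
                           covariates = config$covariates,
                           threshold = config$lasso_threshold,
                           n_lambda = config$n_lambda, k = config$k,
                           seed = seeds[4])
    write_table_csv(data.frame(exposure = names(ss$frequency),
                               frequency = as.numeric(ss$frequency),
                               retained = names(ss$frequency) %in%
                                 ss$retained),
                    config$out_dir, paste0("lasso_", oc, ".csv"))
    logf("lasso done for", oc, "; retained:",
         paste(ss$retained, collapse = ", "))

    # --- ExWAS -------------------------------------------------------
    scan <- run_exwas(stack, oc, exposures = exposures,
                      covariates = config$covariates,
                      alpha = config$alpha)
    write_table_csv(scan, config$out_dir, paste0("exwas_", oc, ".csv"))
    logf("exwas done for", oc, "; M_e =",
         round(attr(scan, "m_e"), 2))

    hits <- scan$exposure[!is.na(scan$p) & scan$p < 0.05]
    results[[paste0("lasso_", oc)]] <- ss
    results[[paste0("exwas_", oc)]] <- scan
    out_summary <- list(
      lasso_retained = ss$retained,
      exwas_hits_uncorrected = hits,
      exwas_hits_corrected = scan$exposure[!is.na(scan$p) &
                                             scan$p < attr(scan,
                                                           "threshold")],
      m_e = attr(scan, "m_e"),
      fwer_threshold = attr(scan, "threshold"))

    # --- sensitivity battery -----------------------------------------
    if (isTRUE(sens$linearity) && length(hits)) {
      lin <- lapply(hits, function(e)
        linearity_scan(stack, e, oc, covariates = config$covariates))
      lin_df <- data.frame(exposure = hits,
                           p = vapply(lin, `[[`, 0, "p"),
                           linear = vapply(lin, `[[`, TRUE, "linear"))
      write_table_csv(lin_df, config$out_dir,
                      paste0("sensitivity_linearity_", oc, ".csv"))
      out_summary$nonlinear <- lin_df$exposure[!lin_df$linear]
    }
    if (isTRUE(sens$coexposure)) {
      cm <- coexposure_model(stack, oc, scan,
                             covariates = config$covariates)
      if (!is.null(cm))
        write_table_csv(cm, config$out_dir,
                        paste0("sensitivity_coexposure_", oc, ".csv"))
    }
    if (isTRUE(sens$sex_interaction) && length(hits)) {
      si <- do.call(rbind, lapply(hits, function(e) {
        r <- sex_interaction(stack, e, oc,
                             covariates = config$covariates)
        data.frame(exposure = e, estimate = r$estimate, p = r$p)
      }))
      write_table_csv(si, config$out_dir,
                      paste0("sensitivity_sex_interaction_", oc, ".csv"))
    }
    if (isTRUE(sens$heterogeneity) && length(hits)) {
      het <- do.call(rbind, lapply(hits, function(e) {
        h <- tryCatch(meta_heterogeneity(stack, e, oc,
                                         covariates = config$covariates),
                      error = function(err) NULL)
        if (is.null(h)) return(NULL)
        data.frame(exposure = e, q = h$q, tau2 = h$tau2, i2 = h$i2,
                   band = h$band)
      }))
      if (!is.null(het))
        write_table_csv(het, config$out_dir,
                        paste0("sensitivity_heterogeneity_", oc, ".csv"))
      out_summary$heterogeneity <- het
    }
    if (isTRUE(sens$complete_case)) {
      cc <- tryCatch(complete_case(tab, vars = c(exposures,
                                                 config$covariates, oc)),
                     error = function(e) NULL)
      if (!is.null(cc) && nrow(cc) > 10 * length(config$covariates)) {
        cc_scan <- run_exwas(cc, oc, exposures = exposures,
                             covariates = config$covariates,
                             alpha = config$alpha)
        write_table_csv(cc_scan, config$out_dir,
                        paste0("sensitivity_complete_case_", oc, ".csv"))
        out_summary$complete_case_n <- attr(cc, "n")
      }
    }
    if (isTRUE(sens$cohort_exclusion) && length(hits)) {
      drop_ch <- config$exclude_cohort %||%
        names(which.min(table(tab$cohort)))
      ce <- cohort_exclusion(stack, drop_ch, oc, exposures = hits,
                             covariates = config$covariates)
      write_table_csv(ce, config$out_dir,
                      paste0("sensitivity_cohort_exclusion_", oc, ".csv"))
      out_summary$cohort_exclusion <- list(cohort = drop_ch,
                                           n = attr(ce, "n"))
    }
    if (isTRUE(sens$gwg_stratification) && oc == "externalizing") {
      ocs <- exposures[grepl("^organochlorines", exposures)]
      if (length(ocs) && "gwg_cat" %in% names(tab)) {
        st <- suppressWarnings(
          stratified_exwas(stack, ocs, oc,
                           covariates = setdiff(config$covariates,
                                                "bmi")))
        if (length(st)) {
          st_df <- do.call(rbind, lapply(names(st), function(s)
            cbind(stratum = s, st[[s]])))
          write_table_csv(st_df, config$out_dir,
                          paste0("sensitivity_gwg_strata_", oc, ".csv"))
        }
      }
    }
    summary_list[[oc]] <- out_summary
  }

  jsonlite::write_json(summary_list,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_out <- config[setdiff(names(config),
                            c("synth", "out_dir", "input_dir"))]
  cfg_out$synth_seed <- config$synth$seed
  jsonlite::write_json(cfg_out, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  logf("pipeline complete")
  results$summary <- summary_list
  invisible(structure(results, class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Pipeline run: n =", s$n, ",", s$n_exposures, "exposures, m =",
      s$m, "\n")
  for (oc in x$config$outcomes) {
    so <- s[[oc]]
    cat("\n[", oc, "]\n")
    cat("  LASSO retained:",
        if (length(so$lasso_retained)) paste(so$lasso_retained,
                                             collapse = ", ")
        else "none", "\n")
    cat("  ExWAS hits (p<0.05):",
        if (length(so$exwas_hits_uncorrected))
          paste(so$exwas_hits_uncorrected, collapse = ", ")
        else "none", "\n")
    cat(sprintf("  M_e = %.2f; corrected threshold = %.4g; corrected hits: %s\n",
                so$m_e, so$fwer_threshold,
                if (length(so$exwas_hits_corrected))
                  paste(so$exwas_hits_corrected, collapse = ", ")
                else "none"))
  }
  invisible(x)
}
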