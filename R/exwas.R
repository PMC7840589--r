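# default a-priori adjustment set of the scan
default_covariates <- function() {
  c("cohort", "season", "sex", "child_age", "parity", "maternal_age",
    "education", "work", "smoking", "bmi")
}

# covariate design matrix with intercept, aliased columns dropped
build_design <- function(dat, covariates) {
  present <- intersect(covariates, names(dat))
  drop_aliased(model.matrix(~ ., data = dat[present]))
}

# normalise input: accept an imputed_stack or a single completed data.frame
as_stack <- function(x) {
  if (inherits(x, "imputed_stack")) return(x)
  if (is.data.frame(x)) return(as_imputed_stack(list(x)))
  stop("expected an imputed_stack or a data.frame")
}

# pool per-imputation (estimate, variance) pairs; m = 1 collapses to the
# single-fit Wald summary (B = 0 by construction)
pool_or_single <- function(est, vv, dfcom) {
  if (length(est) >= 2L) return(rubin_pool(est, vv, dfcom = dfcom))
  se <- sqrt(vv)
  crit <- if (is.finite(dfcom)) qt(0.975, dfcom) else qnorm(0.975)
  p <- if (is.finite(dfcom)) 2 * pt(-abs(est / se), dfcom)
       else 2 * pnorm(-abs(est / se))
  list(qbar = est, ubar = vv, b = 0, t = vv, se = se, df = dfcom,
       ci = c(est - crit * se, est + crit * se), p = p, m = 1L)
}

#' Exposome-wide association scan
#'
#' Fits one adjusted negative-binomial model per exposure on every imputed
#' dataset, pools the exposure coefficient by Rubin's rules, and attaches a
#' family-wise error correction based on the effective number of
#' independent exposures (eigenvalues of the Pearson correlation matrix of
#' the exposures, averaged across imputed datasets). Per-imputation fits
#' that do not converge are dropped from pooling; exposures with more than
#' 20\% dropped fits are flagged unreliable.
#'
#' @param stack an \code{imputed_stack} (or a single completed data.frame,
#'   in which case no pooling occurs).
#' @param outcome name of the count outcome column.
#' @param exposures character vector of exposure columns (default: the
#'   stack's recorded exposure set).
#' @param covariates adjustment covariates (default: cohort, season of
#'   conception, child sex and age, parity, maternal age, education, work
#'   status, smoking, pre-pregnancy BMI).
#' @param alpha FWER level for the corrected threshold.
#' @return object of class \code{exwas_scan}: a data.frame (one row per
#'   exposure, sorted by p-value) with IRR, 95\% CI, p, variance
#'   components and flags; attributes \code{m_e}, \code{threshold},
#'   \code{corr}, \code{alpha}, \code{outcome}, \code{n}.
#' @export
run_exwas <- function(stack, outcome, exposures = NULL,
                      covariates = default_covariates(), alpha = 0.05) {
  stack <- as_stack(stack)
  exposures <- exposures %||% stack$exposure_names
  if (is.null(exposures)) stop("no exposure set given or recorded")
  m <- stack$m
  nexp <- length(exposures)
  est <- matrix(NA_real_, m, nexp, dimnames = list(NULL, exposures))
  vv <- est
  conv <- matrix(FALSE, m, nexp, dimnames = list(NULL, exposures))
  corr_sum <- matrix(0, nexp, nexp)
  dfcom <- NA_real_

  for (j in seq_len(m)) {
    dat <- stack$data[[j]]
    y <- dat[[outcome]]
    X0 <- build_design(dat, covariates)
    base <- fit_negbin(y, X0)
    start <- c(base$coefficients, 0)
    for (e in exposures) {
      X <- cbind(X0, dat[[e]])
      colnames(X)[ncol(X)] <- e
      f <- tryCatch(fit_negbin(y, X, start = start),
                    error = function(err) NULL)
      if (!is.null(f) && f$converged) {
        est[j, e] <- f$coefficients[e]
        vv[j, e] <- f$vcov[e, e]
        conv[j, e] <- TRUE
      }
    }
    dfcom <- nrow(dat) - ncol(X0) - 1L
    corr_sum <- corr_sum + cor(as.matrix(dat[exposures]),
                               use = "pairwise.complete.obs")
  }

  corr <- corr_sum / m
  m_e <- effective_tests(corr)
  thr <- fwer_threshold(alpha, m_e)

  rows <- lapply(exposures, function(e) {
    ok <- conv[, e]
    if (sum(ok) < 1L)
      return(data.frame(exposure = e, outcome = outcome, irr = NA,
                        ci_low = NA, ci_high = NA, log_irr = NA, se = NA,
                        p = NA, b = NA, ubar = NA, m_used = 0L,
                        unreliable = TRUE))
    pl <- pool_or_single(est[ok, e], vv[ok, e], dfcom)
    data.frame(exposure = e, outcome = outcome,
               irr = exp(pl$qbar), ci_low = exp(pl$ci[1]),
               ci_high = exp(pl$ci[2]), log_irr = pl$qbar, se = pl$se,
               p = pl$p, b = pl$b, ubar = pl$ubar, m_used = sum(ok),
               unreliable = mean(ok) < 0.8)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  structure(res, class = c("exwas_scan", "data.frame"),
            m_e = as.numeric(m_e), threshold = thr, alpha = alpha,
            corr = corr, outcome = outcome, n = nrow(stack$data[[1]]),
            m = m, covariates = covariates)
}

#' @export
print.exwas_scan <- function(x, digits = 3, ...) {
  cat("ExWAS scan of", nrow(x), "exposures on", attr(x, "outcome"),
      " (n =", attr(x, "n"), ", m =", attr(x, "m"), ")\n")
  cat(sprintf("  M_e = %.2f, FWER-corrected threshold = %.4g (alpha = %g)\n",
              attr(x, "m_e"), attr(x, "threshold"), attr(x, "alpha")))
  hits <- x$p < attr(x, "threshold") & !is.na(x$p)
  cat("  hits at corrected threshold:", sum(hits),
      "| uncorrected p<0.05:", sum(x$p < 0.05, na.rm = TRUE), "\n")
  print.data.frame(head(as.data.frame(x)[c("exposure", "irr", "ci_low",
                                           "ci_high", "p")], 10),
                   digits = digits)
  if (nrow(x) > 10) cat("  ... (", nrow(x) - 10, "more )\n")
  invisible(x)
}

#' @export
summary.exwas_scan <- function(object, ...) {
  list(outcome = attr(object, "outcome"), n = attr(object, "n"),
       m = attr(object, "m"), m_e = attr(object, "m_e"),
       threshold = attr(object, "threshold"),
       hits_corrected = object$exposure[!is.na(object$p) &
                                          object$p < attr(object, "threshold")],
       hits_uncorrected = object$exposure[!is.na(object$p) &
                                            object$p < 0.05],
       table = as.data.frame(object))
}

#' Forest-style plot of a scan
#'
#' @param x an \code{exwas_scan}.
#' @param top number of lowest-p exposures to display.
#' @param ... passed to \code{plot}.
#' @export
plot.exwas_scan <- function(x, top = 20, ...) {
  d <- head(as.data.frame(x), top)
  d <- d[nrow(d):1, ]
  k <- nrow(d)
  rng <- range(c(d$ci_low, d$ci_high, 1), na.rm = TRUE)
  graphics::plot(d$irr, seq_len(k), xlim = rng, yaxt = "n",
                 xlab = "IRR per IQR change", ylab = "", pch = 15,
                 main = paste("ExWAS:", attr(x, "outcome")), log = "x",
                 ...)
  graphics::segments(d$ci_low, seq_len(k), d$ci_high, seq_len(k))
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::axis(2, at = seq_len(k), labels = d$exposure, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Between-cohort heterogeneity of an adjusted association
#'
#' Refits the adjusted exposure model within each cohort (cohort term
#' removed), pools per cohort across imputed datasets by Rubin's rules, and
#' combines the per-cohort estimates by DerSimonian-Laird random effects,
#' reporting Cochran's Q, tau-squared and I-squared with the qualitative
#' band (< 0.3 low, 0.3-0.6 moderate, >= 0.6 substantial-to-high).
#'
#' @inheritParams run_exwas
#' @param exposure single exposure name.
#' @return a \code{heterogeneity} object; per-cohort pooled estimates are
#'   in its \code{groups} table (forest-plot ready).
#' @export
meta_heterogeneity <- function(stack, exposure, outcome,
                               covariates = default_covariates()) {
  stack <- as_stack(stack)
  covs <- setdiff(covariates, "cohort")
  cohorts <- levels(stack$data[[1]]$cohort)
  if (length(cohorts) < 2L) stop("need at least 2 cohorts")
  ests <- vars <- numeric(0)
  labs <- character(0)
  for (ch in cohorts) {
    e_j <- v_j <- numeric(0)
    for (j in seq_len(stack$m)) {
      dat <- stack$data[[j]][stack$data[[j]]$cohort == ch, , drop = FALSE]
      if (!nrow(dat) || var(dat[[exposure]]) == 0) next
      X <- tryCatch(cbind(build_design(dat, covs),
                          setNames(dat[exposure], exposure)[[1]]),
                    error = function(err) NULL)
      if (is.null(X)) next
      colnames(X)[ncol(X)] <- exposure
      f <- tryCatch(fit_negbin(dat[[outcome]], drop_aliased(X)),
                    error = function(err) NULL)
      if (is.null(f) || !f$converged || !exposure %in% names(f$coefficients))
        next
      e_j <- c(e_j, f$coefficients[exposure])
      v_j <- c(v_j, f$vcov[exposure, exposure])
    }
    if (length(e_j) >= 1L) {
      pl <- pool_or_single(e_j, v_j, dfcom = Inf)
      ests <- c(ests, pl$qbar)
      vars <- c(vars, pl$t)
      labs <- c(labs, ch)
    }
  }
  if (length(ests) < 2L)
    stop("exposure informative in fewer than 2 cohorts")
  dl_meta(ests, vars, labels = labs)
}

#' Coexposure-adjusted model
#'
#' A single negative-binomial model per outcome containing every exposure
#' whose main-scan p-value is below \code{p_enter}, plus the adjustment
#' covariates. Before fitting, exposures are iteratively removed (highest
#' first) while any exposure's variance inflation factor in the joint
#' design exceeds \code{vif_cut}; removals are recorded in the
#' \code{"removed_by_vif"} attribute. Coefficients are Rubin-pooled.
#'
#' @inheritParams run_exwas
#' @param scan the main \code{exwas_scan} for this outcome.
#' @param p_enter inclusion threshold on the main-scan p-value.
#' @param vif_cut maximum tolerated VIF.
#' @return data.frame of pooled per-exposure associations (or NULL when no
#'   exposure enters).
#' @export
coexposure_model <- function(stack, outcome, scan, p_enter = 0.2,
                             vif_cut = 10,
                             covariates = default_covariates()) {
  stack <- as_stack(stack)
  included <- scan$exposure[!is.na(scan$p) & scan$p < p_enter]
  if (!length(included)) {
    message("no exposure enters the coexposure model (all p >= ", p_enter,
            ")")
    return(NULL)
  }
  dat1 <- stack$data[[1]]
  removed <- character(0)
  repeat {
    if (length(included) < 2L) break
    Z <- cbind(as.matrix(dat1[included]),
               build_design(dat1, covariates)[, -1, drop = FALSE])
    v <- vif(Z, columns = included)
    if (max(v) <= vif_cut) break
    worst <- names(which.max(v))
    removed <- c(removed, worst)
    included <- setdiff(included, worst)
  }
  if (length(removed))
    message("coexposure_model: removed by VIF rule: ",
            paste(removed, collapse = ", "))

  m <- stack$m
  est <- matrix(NA_real_, m, length(included),
                dimnames = list(NULL, included))
  vv <- est
  dfcom <- NA_real_
  for (j in seq_len(m)) {
    dat <- stack$data[[j]]
    X <- cbind(build_design(dat, covariates), as.matrix(dat[included]))
    f <- tryCatch(fit_negbin(dat[[outcome]], drop_aliased(X)),
                  error = function(err) NULL)
    if (is.null(f) || !f$converged) next
    for (e in intersect(included, names(f$coefficients))) {
      est[j, e] <- f$coefficients[e]
      vv[j, e] <- f$vcov[e, e]
    }
    dfcom <- nrow(dat) - length(f$coefficients)
  }
  rows <- lapply(included, function(e) {
    ok <- !is.na(est[, e])
    if (!any(ok)) return(NULL)
    pl <- pool_or_single(est[ok, e], vv[ok, e], dfcom)
    data.frame(exposure = e, outcome = outcome, irr = exp(pl$qbar),
               ci_low = exp(pl$ci[1]), ci_high = exp(pl$ci[2]),
               log_irr = pl$qbar, se = pl$se, p = pl$p,
               m_used = sum(ok))
  })
  out <- do.call(rbind, rows)
  attr(out, "removed_by_vif") <- removed
  out
}

#' Exposure-by-sex interaction test
#'
#' Adds an exposure-by-sex product term to the adjusted model and pools the
#' interaction coefficient across imputed datasets.
#'
#' @inheritParams meta_heterogeneity
#' @return list with pooled interaction \code{estimate}, \code{se},
#'   \code{p} and \code{m_used}.
#' @export
sex_interaction <- function(stack, exposure, outcome,
                            covariates = default_covariates()) {
  stack <- as_stack(stack)
  if (nlevels(factor(stack$data[[1]]$sex)) < 2L)
    stop("both sexes must be present")
  est <- vv <- numeric(0)
  dfcom <- NA_real_
  for (j in seq_len(stack$m)) {
    dat <- stack$data[[j]]
    male <- as.numeric(dat$sex == "male")
    X <- cbind(build_design(dat, covariates), dat[[exposure]],
               dat[[exposure]] * male)
    colnames(X)[ncol(X) - 1:0] <- c(exposure, paste0(exposure, ":male"))
    f <- tryCatch(fit_negbin(dat[[outcome]], X), error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    term <- paste0(exposure, ":male")
    est <- c(est, unname(f$coefficients[term]))
    vv <- c(vv, f$vcov[term, term])
    dfcom <- nrow(dat) - ncol(X)
  }
  if (!length(est)) stop("no converged interaction fits")
  pl <- pool_or_single(est, vv, dfcom)
  list(exposure = exposure, outcome = outcome, estimate = pl$qbar,
       se = pl$se, p = pl$p, m_used = length(est))
}

#' Scan stratified on gestational weight gain
#'
#' Re-runs the per-exposure adjusted models within each stratum of the
#' weight-gain category (pre-pregnancy BMI removed from the adjustment set,
#' since the stratification variable is BMI-specific); stratum membership
#' is taken per imputed dataset. Strata smaller than \code{min_n} are
#' skipped with a warning.
#'
#' @inheritParams run_exwas
#' @param strata_var stratification column (a factor, default the IOM
#'   weight-gain category).
#' @param min_n minimum stratum size.
#' @return named list of per-stratum pooled association tables.
#' @export
stratified_exwas <- function(stack, exposures, outcome,
                             strata_var = "gwg_cat",
                             covariates = setdiff(default_covariates(),
                                                  "bmi"),
                             min_n = 50L) {
  stack <- as_stack(stack)
  lev <- levels(factor(stack$data[[1]][[strata_var]]))
  out <- list()
  for (s in lev) {
    sizes <- vapply(stack$data,
                    function(d) sum(d[[strata_var]] == s, na.rm = TRUE),
                    0L)
    if (min(sizes) < min_n) {
      warning("stratum '", s, "' below minimum size (", min(sizes),
              " < ", min_n, "); skipped")
      next
    }
    sub <- as_imputed_stack(lapply(stack$data, function(d)
      d[!is.na(d[[strata_var]]) & d[[strata_var]] == s, , drop = FALSE]),
      exposure_names = stack$exposure_names)
    scan <- run_exwas(sub, outcome, exposures = exposures,
                      covariates = covariates)
    out[[s]] <- as.data.frame(scan)
    attr(out[[s]], "n") <- round(mean(sizes))
  }
  out
}

#' Scan after excluding one cohort
#'
#' @inheritParams run_exwas
#' @param cohort cohort label to drop.
#' @return an \code{exwas_scan} on the remaining subjects (its \code{n}
#'   attribute reports the reduced sample size).
#' @export
cohort_exclusion <- function(stack, cohort, outcome, exposures = NULL,
                             covariates = default_covariates(), ...) {
  stack <- as_stack(stack)
  if (!cohort %in% levels(stack$data[[1]]$cohort))
    stop("unknown cohort: ", cohort)
  sub <- as_imputed_stack(lapply(stack$data, function(d) {
    d <- d[d$cohort != cohort, , drop = FALSE]
    d$cohort <- droplevels(d$cohort)
    d
  }), exposure_names = stack$exposure_names)
  run_exwas(sub, outcome, exposures = exposures, covariates = covariates,
            ...)
}

#' Pooled linearity assessment for one exposure
#'
#' Runs the restricted-cubic-spline likelihood-ratio test on every imputed
#' dataset and combines the p-values by their median; the association is
#' declared linear when the combined p is at least \code{alpha}.
#'
#' @inheritParams meta_heterogeneity
#' @param n_knots spline knots (3-5).
#' @param alpha declaration threshold.
#' @return list with \code{p} (median), \code{linear} (logical) and the
#'   per-imputation p-values.
#' @export
linearity_scan <- function(stack, exposure, outcome,
                           covariates = default_covariates(),
                           n_knots = 3L, alpha = 0.05) {
  stack <- as_stack(stack)
  ps <- vapply(stack$data, function(dat) {
    as.numeric(tryCatch(
      test_linearity(dat[[outcome]], build_design(dat, covariates),
                     dat[[exposure]], n_knots = n_knots),
      error = function(e) NA_real_))
  }, numeric(1))
  p <- median(ps, na.rm = TRUE)
  list(exposure = exposure, outcome = outcome, p = p,
       linear = is.finite(p) && p >= alpha, per_imputation = ps)
}
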