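#' Drop biomarkers with low detection frequency
#'
#' Detection frequency is the share of non-missing values at or above the
#' limit of detection. Biomarkers detected in fewer than \code{min_freq} of
#' their measured samples are removed (removals are recorded in the
#' \code{"removed"} attribute).
#'
#' @param panel an \code{exposome_panel}.
#' @param min_freq minimum detection frequency in (0, 1].
#' @return filtered \code{exposome_panel}.
#' @export
filter_by_detection <- function(panel, min_freq = 0.10) {
  stopifnot(inherits(panel, "exposome_panel"))
  if (min_freq <= 0 || min_freq > 1) stop("min_freq must be in (0, 1]")
  measured <- !panel$missing
  detected <- measured & !panel$censored
  det_freq <- colSums(detected) / pmax(colSums(measured), 1L)
  keep <- det_freq >= min_freq
  removed <- names(det_freq)[!keep]
  panel$conc <- panel$conc[, keep, drop = FALSE]
  panel$censored <- panel$censored[, keep, drop = FALSE]
  panel$missing <- panel$missing[, keep, drop = FALSE]
  panel$meta <- panel$meta[keep, , drop = FALSE]
  panel$meta$detection_frequency <- det_freq[keep]
  attr(panel, "removed") <- removed
  if (length(removed))
    message("filter_by_detection: removed ", length(removed),
            " biomarker(s) below ", min_freq, " detection: ",
            paste(removed, collapse = ", "))
  panel
}

#' Impute concentrations below the limit of detection
#'
#' Single imputation of left-censored values by regression on order
#' statistics: the observed (above-LOD) log concentrations are regressed on
#' their normal quantiles (Blom plotting positions over the full sample,
#' censored values occupying the lowest ranks), giving a fitted log-normal;
#' censored entries are then replaced by inverse-CDF draws from its left
#' tail truncated at the LOD. Observed values are never altered. When fewer
#' than 30\% of the values are observed the tail cannot be calibrated and
#' the conventional LOD/sqrt(2) substitution is used instead (flagged in
#' the \code{"fallback"} attribute).
#'
#' @param values concentration vector (censored entries may hold NA).
#' @param censored logical mask of below-LOD entries.
#' @param lod the limit of detection (> 0).
#' @param seed integer seed for the tail draws.
#' @return numeric vector with censored entries imputed (all < \code{lod}).
#' @export
impute_below_lod <- function(values, censored, lod, seed = 1L) {
  stopifnot(length(values) == length(censored), lod > 0)
  k <- sum(censored)
  if (k == 0) return(values)
  n <- length(values)
  if (k == n) stop("cannot calibrate tail: all values censored")
  obs <- values[!censored]
  if (any(is.na(obs))) stop("observed values must be non-missing")
  out <- values
  set.seed(seed)
  if ((n - k) / n < 0.30) {
    out[censored] <- lod / sqrt(2)
    attr(out, "fallback") <- "lod_sqrt2"
    return(out)
  }
  # Blom plotting positions; censored values occupy ranks 1..k
  ord <- order(obs)
  ranks <- k + seq_len(n - k)
  pp <- (ranks - 0.375) / (n + 0.25)
  fit <- lm.fit(cbind(1, qnorm(pp)), log(obs[ord]))
  mu <- fit$coefficients[1]
  sigma <- max(fit$coefficients[2], 1e-8)
  p_lod <- pnorm((log(lod) - mu) / sigma)
  u <- runif(k, 0, p_lod)
  draws <- exp(mu + sigma * qnorm(u))
  draws <- pmin(draws, lod * (1 - 1e-12))   # numerical guard: strictly < LOD
  out[censored] <- draws
  out
}

# apply impute_below_lod column-wise over a panel
impute_panel_lod <- function(panel, seed = 1L) {
  stopifnot(inherits(panel, "exposome_panel"))
  seeds <- derive_seeds(seed, ncol(panel$conc))
  fallbacks <- character(0)
  for (j in seq_len(ncol(panel$conc))) {
    meas <- !panel$missing[, j]
    if (!any(panel$censored[meas, j])) next
    v <- impute_below_lod(panel$conc[meas, j], panel$censored[meas, j],
                          panel$meta$lod[j], seed = seeds[j])
    if (!is.null(attr(v, "fallback")))
      fallbacks <- c(fallbacks, panel$meta$name[j])
    panel$conc[meas, j] <- as.numeric(v)
  }
  attr(panel, "lod_fallback") <- fallbacks
  panel
}

#' Standardize concentrations by creatinine or total lipids
#'
#' Urinary biomarkers are divided by creatinine (g/L) to micrograms per gram
#' creatinine; lipophilic blood biomarkers are divided by total serum lipids
#' (g/L) to nanograms per gram lipid; all other biomarkers pass through
#' unchanged. Rows lacking the required denominator get a missing value
#' (counted in the \code{"denominator_missing"} attribute).
#'
#' @param values concentration vector for one biomarker.
#' @param standardize one of \code{"creatinine"}, \code{"lipids"},
#'   \code{"none"}.
#' @param creatinine,total_lipids per-subject denominators (g/L).
#' @return standardized concentration vector.
#' @export
standardize_concentration <- function(values, standardize,
                                      creatinine = NULL,
                                      total_lipids = NULL) {
  standardize <- match.arg(standardize, c("creatinine", "lipids", "none"))
  if (standardize == "none") return(values)
  den <- if (standardize == "creatinine") creatinine else total_lipids
  if (is.null(den)) stop("missing denominator vector for ", standardize,
                         " standardization")
  bad <- is.na(den) | den <= 0
  out <- values / den
  out[bad] <- NA
  attr(out, "denominator_missing") <- sum(bad & !is.na(values))
  out
}

standardize_panel <- function(panel, covariates) {
  stopifnot(inherits(panel, "exposome_panel"))
  for (j in seq_len(ncol(panel$conc))) {
    panel$conc[, j] <- as.numeric(standardize_concentration(
      panel$conc[, j], panel$meta$standardize[j],
      creatinine = covariates$creatinine_gl,
      total_lipids = covariates$lipids_gl))
  }
  panel
}

#' Log-transform and IQR-standardize the exposure matrix
#'
#' Each biomarker is transformed by its rule (natural log for cotinine,
#' log2 otherwise) and divided by the interquartile range of its transformed
#' values, computed on pooled non-missing data with the type-7 quartile
#' convention. A unit increase of the result is an IQR change of the
#' log-transformed concentration. Biomarkers with zero IQR are dropped with
#' a warning. When a persisted \code{transform_spec} is supplied the stored
#' divisors are reused, so projecting the same data twice is idempotent.
#'
#' @param panel an \code{exposome_panel} (LOD-imputed, standardized).
#' @param spec optional \code{transform_spec} from a previous call.
#' @return list with \code{exposures} (numeric matrix, NA where missing)
#'   and \code{spec} (a \code{transform_spec}: per-biomarker IQR divisor,
#'   transform rule and quartile convention).
#' @export
transform_and_scale <- function(panel, spec = NULL) {
  stopifnot(inherits(panel, "exposome_panel"))
  p <- ncol(panel$conc)
  trans <- panel$meta$transform
  tx <- panel$conc
  for (j in seq_len(p)) {
    v <- panel$conc[, j]
    if (any(v[!is.na(v)] <= 0)) stop("non-positive concentration in ",
                                     panel$meta$name[j])
    tx[, j] <- if (trans[j] == "ln") log(v) else log2(v)
  }
  if (is.null(spec)) {
    iqr <- apply(tx, 2, function(v)
      diff(quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                    type = 7)))
    spec <- structure(list(iqr = setNames(iqr, panel$meta$name),
                           transform = setNames(trans, panel$meta$name),
                           quartile_type = 7L), class = "transform_spec")
  } else {
    stopifnot(inherits(spec, "transform_spec"))
    if (!all(panel$meta$name %in% names(spec$iqr)))
      stop("transform_spec does not cover all biomarkers")
  }
  keep <- spec$iqr[panel$meta$name] > 0
  if (any(!keep))
    warning("dropping constant biomarker(s) with zero IQR: ",
            paste(panel$meta$name[!keep], collapse = ", "))
  exposures <- sweep(tx[, keep, drop = FALSE], 2,
                     spec$iqr[panel$meta$name[keep]], "/")
  list(exposures = exposures, spec = spec)
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("Transform spec for", length(x$iqr), "biomarkers",
      "(type-", x$quartile_type, " quartiles)\n", sep = "")
  print(head(data.frame(transform = x$transform, iqr = x$iqr), 10))
  if (length(x$iqr) > 10) cat("...\n")
  invisible(x)
}

#' Classify gestational weight gain against IOM recommendations
#'
#' Total gestational weight gain is compared with the Institute of Medicine
#' recommended range for the mother's pre-pregnancy BMI class:
#' BMI < 18.5 kg/m2: 12.5-18.0 kg; 18.5-24.9: 11.5-16.0 kg;
#' 25.0-29.9: 7.0-11.5 kg; >= 30: 5.0-9.0 kg. Gains below the band are
#' "insufficient", within it (inclusive) "adequate", above it "excessive".
#'
#' @param pre_bmi pre-pregnancy BMI (kg/m2).
#' @param total_gain total gestational weight gain (kg).
#' @return factor with levels insufficient/adequate/excessive (NA where an
#'   input is missing).
#' @export
classify_gwg <- function(pre_bmi, total_gain) {
  stopifnot(length(pre_bmi) == length(total_gain))
  if (any(pre_bmi <= 0, na.rm = TRUE)) stop("pre_bmi must be positive")
  lo <- ifelse(pre_bmi < 18.5, 12.5,
               ifelse(pre_bmi < 25, 11.5, ifelse(pre_bmi < 30, 7.0, 5.0)))
  hi <- ifelse(pre_bmi < 18.5, 18.0,
               ifelse(pre_bmi < 25, 16.0, ifelse(pre_bmi < 30, 11.5, 9.0)))
  out <- ifelse(total_gain < lo, "insufficient",
                ifelse(total_gain > hi, "excessive", "adequate"))
  factor(out, levels = c("insufficient", "adequate", "excessive"))
}

#' Run the full exposure preprocessing pipeline
#'
#' Fixed order: detection filtering, below-LOD single imputation,
#' creatinine/lipid standardization, log transform and IQR scaling. Also
#' derives the gestational-weight-gain category from the covariates.
#'
#' @param panel raw \code{exposome_panel}.
#' @param covariates covariate table (denominators + BMI/weight gain).
#' @param min_detect detection-frequency threshold.
#' @param seed seed for the censored-tail draws.
#' @param spec optional persisted \code{transform_spec}.
#' @return list: \code{exposures} (IQR-standardized matrix), \code{spec},
#'   \code{panel} (the processed panel), \code{covariates} (with
#'   \code{gwg_cat} added).
#' @export
prepare_exposures <- function(panel, covariates, min_detect = 0.10,
                              seed = 1L, spec = NULL) {
  panel <- filter_by_detection(panel, min_detect)
  panel <- impute_panel_lod(panel, seed = seed)
  panel <- standardize_panel(panel, covariates)
  ts <- transform_and_scale(panel, spec = spec)
  covariates$gwg_cat <- classify_gwg(covariates$bmi, covariates$gwg_kg)
  list(exposures = ts$exposures, spec = ts$spec, panel = panel,
       covariates = covariates)
}

#' Assemble the analysis table
#'
#' Binds the processed exposures, adjustment covariates and outcomes into
#' one data frame, the unit every downstream stage (imputation, LASSO,
#' ExWAS) consumes.
#'
#' @param prep result of \code{prepare_exposures}.
#' @param outcomes outcome table (integer scores).
#' @return data.frame with attribute \code{"exposure_names"}.
#' @export
build_analysis_table <- function(prep, outcomes) {
  ex <- as.data.frame(prep$exposures)
  tab <- cbind(prep$covariates, ex, outcomes)
  attr(tab, "exposure_names") <- colnames(prep$exposures)
  tab
}
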