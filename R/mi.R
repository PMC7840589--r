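# drop aliased columns from a design matrix via pivoted QR
drop_aliased <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

# Bayesian-draw predictive mean matching (continuous conditionals):
# fit OLS on observed rows, draw (sigma*, beta*) from their posterior,
# match each missing row's predicted value to its k nearest observed
# predictions and copy a randomly chosen donor's observed value.
pmm_impute <- function(y_obs, X_obs, X_mis, donors = 5L) {
  p <- ncol(X_obs)
  XtX <- crossprod(X_obs) + diag(1e-5, p)
  Xty <- crossprod(X_obs, y_obs)
  U <- chol(XtX)
  beta_hat <- backsolve(U, forwardsolve(t(U), Xty))
  res <- y_obs - drop(X_obs %*% beta_hat)
  nu <- max(length(y_obs) - p, 1L)
  sigma2_star <- sum(res^2) / rchisq(1, nu)
  beta_star <- beta_hat +
    sqrt(sigma2_star) * backsolve(U, rnorm(p))
  pred_obs <- drop(X_obs %*% beta_hat)
  pred_mis <- drop(X_mis %*% beta_star)
  k <- min(donors, length(y_obs))
  vapply(pred_mis, function(pm) {
    d <- abs(pred_obs - pm)
    cand <- order(d)[seq_len(k)]
    y_obs[cand[sample.int(k, 1L)]]
  }, numeric(1))
}

# multinomial-draw conditional for categorical variables
cat_impute <- function(y_obs, X_obs, X_mis) {
  lev <- levels(y_obs)
  if (length(lev) == 2L) {
    f <- suppressWarnings(glm.fit(X_obs, as.numeric(y_obs) - 1,
                                  family = stats::binomial()))
    pr <- 1 / (1 + exp(-drop(X_mis %*% f$coefficients)))
    pr[is.na(pr)] <- mean(as.numeric(y_obs) - 1)
    factor(lev[1L + rbinom(nrow(X_mis), 1, pr)], levels = lev)
  } else {
    df_obs <- data.frame(.y = y_obs, X_obs[, -1, drop = FALSE])
    df_mis <- data.frame(X_mis[, -1, drop = FALSE])
    f <- suppressWarnings(nnet::multinom(.y ~ ., data = df_obs,
                                         trace = FALSE, maxit = 100,
                                         MaxNWts = 5000))
    pr <- predict(f, newdata = df_mis, type = "probs")
    if (is.null(dim(pr))) pr <- rbind(pr)
    draw <- apply(pr, 1, function(p) sample(colnames(pr), 1L, prob = p))
    factor(draw, levels = lev)
  }
}

# passive (derived) covariates recomputed from their parents
refresh_derived <- function(dat) {
  if (all(c("bmi", "bmi_class") %in% names(dat)))
    dat$bmi_class <- cut(dat$bmi, c(0, 18.5, 25, 30, Inf),
                         labels = c("underweight", "normal", "overweight",
                                    "obese"), right = FALSE)
  if (all(c("bmi", "gwg_kg", "gwg_cat") %in% names(dat)))
    dat$gwg_cat <- classify_gwg(dat$bmi, dat$gwg_kg)
  dat
}

#' Multiple imputation by chained equations
#'
#' Fully conditional specification producing \code{m} completed copies of
#' the analysis table. Missing cells are initialised by random draws from
#' the observed margins, then each incomplete variable is revisited for
#' \code{n_iter} sweeps: continuous variables are imputed by predictive
#' mean matching (Bayesian linear-regression parameter draw, \code{donors}
#' nearest observed donors on the predicted value, random donor);
#' categorical variables by draws from a fitted multinomial (or logistic)
#' model. The outcome scores, child sex and child age are never imputed;
#' all other variables (cohort indicator included, so biomarkers missing in
#' a whole cohort borrow strength across cohorts) serve as predictors.
#' Derived covariates (BMI class, weight-gain category) are recomputed from
#' their parents rather than imputed.
#'
#' @param data analysis table (data.frame) with missing values.
#' @param m number of imputed datasets (study-scale default 100; use 5-10
#'   for desk-scale work).
#' @param n_iter chained-equation sweeps per dataset.
#' @param donors donor-pool size for predictive mean matching.
#' @param seed master seed; per-dataset streams are derived from it.
#' @param never_impute variables left untouched even if incomplete.
#' @param predictors optional character vector restricting the predictor
#'   set (default: all other variables).
#' @return object of class \code{imputed_stack}: list of \code{m} completed
#'   data.frames plus provenance.
#' @export
impute_chained <- function(data, m = 5L, n_iter = 10L, donors = 5L,
                           seed = 1L,
                           never_impute = c("externalizing",
                                            "internalizing", "sex",
                                            "child_age"),
                           predictors = NULL) {
  stopifnot(is.data.frame(data), m >= 2L, n_iter >= 1L)
  derived <- intersect(c("bmi_class", "gwg_cat"), names(data))
  excluded <- c("id", never_impute, derived)
  candidates <- setdiff(names(data), excluded)
  na_count <- vapply(data[candidates], function(v) sum(is.na(v)), 0L)
  if (any(na_count == nrow(data)))
    stop("variable(s) 100% missing: ",
         paste(candidates[na_count == nrow(data)], collapse = ", "))
  vars <- candidates[na_count > 0]
  vars <- vars[order(na_count[vars])]
  pred_pool <- predictors %||% setdiff(names(data), c("id", derived))
  na_mask <- lapply(data[vars], is.na)

  seeds <- derive_seeds(seed, m)
  stack <- vector("list", m)
  for (j in seq_len(m)) {
    set.seed(seeds[j])
    dat <- data
    for (v in vars) {              # initialise from observed margins
      mis <- na_mask[[v]]
      obs <- dat[[v]][!mis]
      dat[[v]][mis] <- sample(obs, sum(mis), replace = TRUE)
    }
    dat <- refresh_derived(dat)
    for (it in seq_len(n_iter)) {
      for (v in vars) {
        mis <- na_mask[[v]]
        preds <- setdiff(pred_pool, v)
        X <- model.matrix(~ ., data = dat[preds])
        X <- drop_aliased(X)
        y <- data[[v]]             # true observed values for this variable
        if (is.numeric(y)) {
          dat[[v]][mis] <- pmm_impute(y[!mis], X[!mis, , drop = FALSE],
                                      X[mis, , drop = FALSE], donors)
        } else {
          dat[[v]][mis] <- cat_impute(factor(y[!mis]),
                                      X[!mis, , drop = FALSE],
                                      X[mis, , drop = FALSE])
        }
      }
      dat <- refresh_derived(dat)
    }
    stack[[j]] <- dat
  }
  structure(list(data = stack, m = m, n_iter = n_iter, donors = donors,
                 seed = seed, imputed_variables = vars,
                 exposure_names = attr(data, "exposure_names")),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("Imputed stack: m =", x$m, "completed datasets,",
      length(x$imputed_variables), "imputed variable(s),",
      x$n_iter, "chained-equation sweeps\n")
  if (length(x$imputed_variables))
    cat("  variables:", paste(x$imputed_variables, collapse = ", "), "\n")
  invisible(x)
}

# wrap already-complete data (or externally completed copies) as a stack
as_imputed_stack <- function(datasets, exposure_names = NULL) {
  structure(list(data = datasets, m = length(datasets), n_iter = 0L,
                 donors = NA, seed = NA, imputed_variables = character(0),
                 exposure_names = exposure_names %||%
                   attr(datasets[[1]], "exposure_names")),
            class = "imputed_stack")
}

#' Complete-case restriction
#'
#' Removes every row with a missing value in \code{vars} (default: all
#' columns), reporting the resulting sample size.
#'
#' @param table data.frame.
#' @param vars columns whose completeness is required.
#' @return filtered data.frame with attribute \code{"n"}.
#' @export
complete_case <- function(table, vars = names(table)) {
  keep <- complete.cases(table[, vars, drop = FALSE])
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("complete-case restriction removed all rows")
  attr(out, "n") <- nrow(out)
  attr(out, "exposure_names") <- attr(table, "exposure_names")
  out
}
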