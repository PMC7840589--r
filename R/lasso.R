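# IRLS weights / working response for log-link counts with fixed dispersion
irls_parts <- function(y, eta, theta, family) {
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  w <- if (family == "negbin") mu * theta / (theta + mu) else mu
  list(mu = mu, w = w, z = eta + (y - mu) / mu)
}

loglik_counts <- function(y, mu, theta, family) {
  if (family == "negbin") sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  else sum(stats::dpois(y, mu, log = TRUE))
}

# one penalized fit at a single lambda: IRLS outer loop; inner solver is
# compiled block descent (exact WLS on the free covariate block, cyclic
# soft-threshold coordinate descent on the penalized exposures)
nb_lasso_one <- function(y, X_unpen, X_pen, lambda, theta, family,
                         beta_u, beta_p, tol = 1e-7, maxit = 100L) {
  for (it in seq_len(maxit)) {
    eta <- drop(X_unpen %*% beta_u + X_pen %*% beta_p)
    parts <- irls_parts(y, eta, theta, family)
    sol <- cd_block_lasso(X_unpen, X_pen, parts$z, parts$w, lambda,
                          beta_u, beta_p, 1e-9, 1000L)
    if (any(!is.finite(sol$beta_u)) || any(!is.finite(sol$beta_p)))
      return(NULL)
    delta <- max(abs(c(sol$beta_u - beta_u, sol$beta_p - beta_p)))
    beta_u <- drop(sol$beta_u)
    beta_p <- drop(sol$beta_p)
    if (delta < tol) break
  }
  list(beta_u = beta_u, beta_p = beta_p)
}

#' Penalty grid for the adjusted negative-binomial LASSO
#'
#' The largest penalty \eqn{\lambda_{max}} is the maximum absolute
#' score component (per observation) of the penalized columns at the
#' covariates-only fit -- the smallest penalty at which every penalized
#' coefficient is exactly zero. The grid is log-spaced down to
#' \eqn{\lambda_{max} \cdot} \code{lambda_min_ratio}.
#'
#' @param y count response.
#' @param X_pen penalized (exposure) design columns, already on the
#'   per-IQR scale.
#' @param X_unpen unpenalized columns (intercept + covariates).
#' @param n_lambda grid length.
#' @param lambda_min_ratio ratio of smallest to largest penalty.
#' @param theta fixed NB2 dispersion (estimated from the covariates-only
#'   fit when NULL; ignored for \code{family = "poisson"}).
#' @param family penalized working likelihood, \code{"negbin"} (default)
#'   or \code{"poisson"}.
#' @return decreasing numeric vector of penalties, \code{theta} attached
#'   as an attribute.
#' @export
lambda_grid <- function(y, X_pen, X_unpen, n_lambda = 100L,
                        lambda_min_ratio = 1e-3, theta = NULL,
                        family = c("negbin", "poisson")) {
  family <- match.arg(family)
  X_pen <- as.matrix(X_pen)
  if (any(apply(X_pen, 2, var) == 0))
    stop("penalized columns must not be constant")
  base <- if (family == "negbin") fit_negbin(y, X_unpen, theta = theta)
          else fit_negbin(y, X_unpen, theta = 1e8)
  theta <- if (family == "negbin" && is.null(theta)) {
    f <- fit_negbin(y, X_unpen)
    f$theta
  } else if (family == "negbin") theta else Inf
  mu0 <- if (family == "negbin")
    fit_negbin(y, X_unpen, theta = theta)$fitted.values
  else base$fitted.values
  wres <- if (family == "negbin") theta * (y - mu0) / (theta + mu0)
          else (y - mu0)
  score <- abs(drop(crossprod(X_pen, wres))) / length(y)
  # a hair above the exact score so finite-tolerance refits of the
  # covariates-only model cannot push a coefficient over the boundary
  lmax <- max(score, 1e-10) * 1.000001
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  attr(grid, "theta") <- theta
  grid
}

#' Fit the adjusted LASSO path
#'
#' Penalized log-link count regression over a decreasing penalty grid:
#' coordinate descent with soft thresholding on the IRLS working problem,
#' warm starts along the grid, exposures penalized and adjustment
#' covariates free. The dispersion is held fixed along the path (estimated
#' once from the covariates-only fit), because re-estimating it in the
#' high-sparsity region is unstable.
#'
#' @inheritParams lambda_grid
#' @param grid penalty grid from \code{lambda_grid} (built automatically
#'   when NULL).
#' @return object of class \code{nb_lasso_path}: coefficient matrix
#'   (rows = columns of the joint design, columns = penalties), per-penalty
#'   count of nonzero penalized coefficients and training log-likelihood,
#'   the grid, \code{theta} and the family.
#' @export
fit_nb_lasso_path <- function(y, X_pen, X_unpen, grid = NULL, theta = NULL,
                              family = c("negbin", "poisson")) {
  family <- match.arg(family)
  X_pen <- as.matrix(X_pen)
  X_unpen <- as.matrix(X_unpen)
  if (is.null(colnames(X_pen)))
    colnames(X_pen) <- paste0("pen", seq_len(ncol(X_pen)))
  if (is.null(grid))
    grid <- lambda_grid(y, X_pen, X_unpen, theta = theta, family = family)
  theta <- attr(grid, "theta") %||% theta %||%
    (if (family == "negbin") fit_negbin(y, X_unpen)$theta else Inf)

  base <- if (family == "negbin") fit_negbin(y, X_unpen, theta = theta)
          else fit_negbin(y, X_unpen, theta = 1e8)
  beta_u <- base$coefficients
  beta_p <- rep(0, ncol(X_pen))

  nl <- length(grid)
  B <- matrix(NA_real_, ncol(X_unpen) + ncol(X_pen), nl,
              dimnames = list(c(colnames(X_unpen), colnames(X_pen)), NULL))
  nzero <- integer(nl)
  ll <- rep(NA_real_, nl)
  failed <- logical(nl)
  for (l in seq_len(nl)) {
    bl <- nb_lasso_one(y, X_unpen, X_pen, grid[l], theta, family,
                       beta_u, beta_p)
    if (is.null(bl)) { failed[l] <- TRUE; next }
    beta_u <- bl$beta_u
    beta_p <- bl$beta_p
    B[, l] <- c(beta_u, beta_p)
    nzero[l] <- sum(beta_p != 0)
    mu <- exp(pmin(drop(X_unpen %*% beta_u + X_pen %*% beta_p), 30))
    ll[l] <- loglik_counts(y, mu, theta, family)
  }
  structure(list(lambda = as.numeric(grid), beta = B, nzero = nzero,
                 loglik = ll, failed = failed, theta = theta,
                 family = family, pen_names = colnames(X_pen),
                 unpen_names = colnames(X_unpen)),
            class = "nb_lasso_path")
}

#' @export
print.nb_lasso_path <- function(x, ...) {
  cat("Adjusted", x$family, "LASSO path:", length(x$lambda), "penalties,",
      length(x$pen_names), "penalized +", length(x$unpen_names),
      "free columns, theta =", format(x$theta, digits = 4), "\n")
  cat("  nonzero penalized coefficients:", x$nzero[1], "at lambda_max ->",
      x$nzero[length(x$nzero)], "at lambda_min\n")
  invisible(x)
}

#' @export
coef.nb_lasso_path <- function(object, lambda = NULL, ...) {
  if (is.null(lambda)) return(object$beta)
  l <- which.min(abs(object$lambda - lambda))
  object$beta[, l]
}

#' @export
plot.nb_lasso_path <- function(x, ...) {
  pen <- x$beta[x$pen_names, , drop = FALSE]
  graphics::matplot(log(x$lambda), t(pen), type = "l", lty = 1,
                    xlab = "log(lambda)", ylab = "Coefficient (per IQR)",
                    main = "Adjusted LASSO path", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Cross-validated penalty choice with the one-standard-error sparsest rule
#'
#' Ten-fold (by default) cross-validation of the held-out log-likelihood,
#' folds stratified by cohort. The chosen penalty is the sparsest (fewest
#' nonzero penalized coefficients on the full-data path) among those whose
#' mean held-out log-likelihood is within one standard error of the
#' maximum; ties break toward the larger penalty.
#'
#' @inheritParams fit_nb_lasso_path
#' @param k number of folds.
#' @param cohort optional factor used to stratify fold assignment.
#' @param seed seed for the fold shuffle.
#' @param se_rule anchor the one-SE band at the SE of the maximising
#'   penalty (\code{"argmax"}, default) or at each penalty's own SE
#'   (\code{"per_lambda"}).
#' @return object of class \code{cv_curve}: per-penalty mean and SE of the
#'   held-out log-likelihood, the maximising and chosen penalties, the
#'   full-data path, and the selected exposure set at the chosen penalty.
#' @export
cv_select_lambda <- function(y, X_pen, X_unpen, grid = NULL, k = 10L,
                             cohort = NULL, seed = 1L, theta = NULL,
                             family = c("negbin", "poisson"),
                             se_rule = c("argmax", "per_lambda")) {
  family <- match.arg(family)
  se_rule <- match.arg(se_rule)
  if (k < 2L) stop("k must be >= 2")
  X_pen <- as.matrix(X_pen)
  X_unpen <- as.matrix(X_unpen)
  n <- length(y)
  if (is.null(grid))
    grid <- lambda_grid(y, X_pen, X_unpen, theta = theta, family = family)
  theta <- attr(grid, "theta") %||% theta %||%
    (if (family == "negbin") fit_negbin(y, X_unpen)$theta else Inf)

  assign_folds <- function(s) {
    set.seed(s)
    fold <- integer(n)
    strata <- if (is.null(cohort)) rep(1L, n) else as.integer(cohort)
    for (g in unique(strata)) {
      idx <- sample(which(strata == g))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
  fold <- assign_folds(seed)
  if (any(tapply(y, fold, var) == 0)) {
    fold <- assign_folds(seed + 1L)
    if (any(tapply(y, fold, var) == 0))
      stop("a fold has a constant outcome; cannot cross-validate")
  }

  nl <- length(grid)
  ll_fold <- matrix(NA_real_, k, nl)
  for (f in seq_len(k)) {
    tr <- fold != f
    path_f <- fit_nb_lasso_path(y[tr], X_pen[tr, , drop = FALSE],
                                X_unpen[tr, , drop = FALSE], grid = grid,
                                theta = theta, family = family)
    Xte <- cbind(X_unpen[!tr, , drop = FALSE], X_pen[!tr, , drop = FALSE])
    for (l in seq_len(nl)) {
      if (path_f$failed[l]) next
      mu <- exp(pmin(drop(Xte %*% path_f$beta[, l]), 30))
      ll_fold[f, l] <- loglik_counts(y[!tr], mu, theta, family) / sum(!tr)
    }
  }
  cv_mean <- colMeans(ll_fold)
  cv_se <- apply(ll_fold, 2, sd) / sqrt(k)
  ok <- is.finite(cv_mean)
  i_max <- which(ok)[which.max(cv_mean[ok])]
  band <- if (se_rule == "argmax") cv_se[i_max] else cv_se
  candidates <- which(ok & cv_mean >= cv_mean[i_max] - band)

  path <- fit_nb_lasso_path(y, X_pen, X_unpen, grid = grid, theta = theta,
                            family = family)
  nz <- path$nzero
  nz[path$failed] <- NA
  cand_nz <- nz[candidates]
  sparsest <- candidates[which(cand_nz == min(cand_nz, na.rm = TRUE))]
  i_chosen <- min(sparsest)      # grid is decreasing: ties -> larger lambda

  sel <- path$pen_names[path$beta[path$pen_names, i_chosen] != 0]
  structure(list(lambda = as.numeric(grid), cv_mean = cv_mean,
                 cv_se = cv_se, lambda_max_ll = grid[i_max],
                 lambda_chosen = grid[i_chosen], index_chosen = i_chosen,
                 nzero_chosen = path$nzero[i_chosen], selected = sel,
                 path = path, k = k, seed = seed, theta = theta,
                 family = family),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("Cross-validated", x$family, "LASSO (", x$k, "folds )\n")
  cat(sprintf("  lambda at max CV log-lik: %.4g; chosen (one-SE sparsest): %.4g\n",
              x$lambda_max_ll, x$lambda_chosen))
  cat("  nonzero at chosen lambda:", x$nzero_chosen,
      if (length(x$selected)) paste0("(", paste(x$selected,
                                                collapse = ", "), ")")
      else "", "\n")
  invisible(x)
}

#' @export
plot.cv_curve <- function(x, ...) {
  graphics::plot(log(x$lambda), x$cv_mean, type = "b", pch = 16,
                 cex = 0.6, xlab = "log(lambda)",
                 ylab = "Held-out log-likelihood / observation",
                 main = "Cross-validation curve", ...)
  graphics::arrows(log(x$lambda), x$cv_mean - x$cv_se, log(x$lambda),
                   x$cv_mean + x$cv_se, angle = 90, code = 3,
                   length = 0.02, col = "grey60")
  graphics::abline(v = log(x$lambda_chosen), lty = 2)
  graphics::abline(v = log(x$lambda_max_ll), lty = 3)
  invisible(x)
}

#' Stability selection across imputed datasets
#'
#' Runs the full cross-validated one-SE LASSO on every imputed dataset
#' (per-dataset fold seeds derived deterministically from the master seed)
#' and records, for each exposure, the share of runs in which it had a
#' nonzero coefficient at that run's chosen penalty. Exposures selected in
#' at least \code{threshold} of the runs (inclusive) are retained. A
#' dataset-level failure counts as "not selected" for every exposure in
#' that run.
#'
#' @inheritParams run_exwas
#' @param threshold retention threshold on the selection frequency.
#' @param n_lambda penalty-grid length per run.
#' @param k CV folds.
#' @param seed master seed.
#' @param family working likelihood of the penalized fits.
#' @return object of class \code{stability_selection}: per-exposure
#'   selection \code{frequency}, the \code{retained} set, and per-run
#'   selections.
#' @export
stability_select <- function(stack, outcome, exposures = NULL,
                             covariates = default_covariates(),
                             threshold = 0.5, n_lambda = 20L, k = 10L,
                             seed = 1L,
                             family = c("negbin", "poisson")) {
  family <- match.arg(family)
  stack <- as_stack(stack)
  if (stack$m < 2L) stop("stability selection needs m >= 2")
  exposures <- exposures %||% stack$exposure_names
  seeds <- derive_seeds(seed, stack$m)
  sel <- matrix(FALSE, stack$m, length(exposures),
                dimnames = list(NULL, exposures))
  failures <- 0L
  for (j in seq_len(stack$m)) {
    dat <- stack$data[[j]]
    res <- tryCatch({
      X_unpen <- build_design(dat, covariates)
      X_pen <- as.matrix(dat[exposures])
      grid <- lambda_grid(dat[[outcome]], X_pen, X_unpen,
                          n_lambda = n_lambda, family = family)
      cv <- cv_select_lambda(dat[[outcome]], X_pen, X_unpen, grid = grid,
                             k = k, cohort = dat$cohort, seed = seeds[j],
                             family = family)
      cv$selected
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      warning("stability_select: run ", j, " failed (",
              conditionMessage(res), "); counted as no selection")
    } else {
      sel[j, res] <- TRUE
    }
  }
  freq <- colMeans(sel)
  structure(list(frequency = freq,
                 retained = names(freq)[freq >= threshold],
                 threshold = threshold, m = stack$m, failures = failures,
                 selections = sel, seed = seed, family = family),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("Stability selection over m =", x$m, "imputed datasets (threshold",
      x$threshold, ")\n")
  if (x$failures) cat("  failed runs:", x$failures, "\n")
  if (length(x$retained)) {
    cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  } else cat("  retained: none\n")
  nz <- sort(x$frequency[x$frequency > 0], decreasing = TRUE)
  if (length(nz)) {
    cat("  nonzero frequencies:\n")
    print(round(head(nz, 15), 3))
  }
  invisible(x)
}

#' @export
plot.stability_selection <- function(x, top = 20, ...) {
  f <- sort(x$frequency, decreasing = TRUE)[seq_len(min(top,
                                                        length(x$frequency)))]
  graphics::barplot(rev(f), horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "Selection frequency", xlim = c(0, 1),
                    main = "Stability selection", ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}
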