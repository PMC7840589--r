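#' Fit a negative-binomial (NB2) regression by IRLS with ML dispersion
#'
#' Fits a log-link NB2 model (variance \eqn{\mu + \mu^2/\theta}) to a count
#' response and a design matrix, alternating iteratively reweighted least
#' squares for the regression coefficients with maximum-likelihood updating
#' of the dispersion \eqn{\theta}, until the log-likelihood changes by less
#' than \code{tol}.
#'
#' @param y non-negative integer response vector.
#' @param X design matrix including an intercept column; must have full
#'   column rank.
#' @param theta optional fixed dispersion. When supplied, \eqn{\theta} is not
#'   estimated (used, e.g., along a penalized path where re-estimating the
#'   dispersion at every penalty value is unstable).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param maxit maximum number of outer iterations.
#' @param start optional starting coefficients.
#'
#' @return An object of class \code{nb_fit}: coefficients on the log scale
#'   (exponentiate for incidence-rate ratios), their covariance matrix,
#'   \code{theta}, the log-likelihood, a convergence flag and the sample size.
#' @examples
#' set.seed(1)
#' y <- rnbinom(200, mu = 5, size = 2)
#' f <- fit_negbin(y, cbind(`(Intercept)` = 1))
#' coef(f)  # close to log(5)
#' @export
fit_negbin <- function(y, X, theta = NULL, tol = 1e-8, maxit = 200L,
                       start = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must contain non-negative integers")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }

  fixed_theta <- !is.null(theta)
  # initialise via a Poisson fit; moment estimate of theta from its residuals
  fit0 <- suppressWarnings(
    glm.fit(X, y, family = stats::poisson(), start = start)
  )
  mu <- fit0$fitted.values
  if (!fixed_theta) {
    num <- sum((y - mu)^2 - mu)
    theta <- if (num > 0) sum(mu^2) / num else 1e4
    theta <- min(max(theta, 1e-3), 1e7)
  }
  beta <- fit0$coefficients
  ll <- nb_loglik(y, mu, theta)

  converged <- FALSE
  iter <- 0L
  fit <- fit0
  for (it in seq_len(maxit)) {
    iter <- it
    fit <- suppressWarnings(
      glm.fit(X, y, family = MASS::negative.binomial(theta = theta),
              start = beta)
    )
    beta <- fit$coefficients
    mu <- fit$fitted.values
    if (!fixed_theta) {
      theta_new <- tryCatch(
        suppressWarnings(as.numeric(
          MASS::theta.ml(y, mu, limit = 50, trace = FALSE)
        )),
        error = function(e) theta
      )
      if (is.finite(theta_new) && theta_new > 0) theta <- theta_new
    }
    ll_new <- nb_loglik(y, mu, theta)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  w <- as.numeric(mu * theta / (theta + mu))  # IRLS weights, log link, NB2
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) solve(info))
  dimnames(vc) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(X)),
    vcov = vc,
    theta = theta,
    theta_fixed = fixed_theta,
    logLik = ll,
    converged = converged && fit$converged,
    iter = iter,
    n = length(y),
    fitted.values = mu,
    y = y,
    X = X
  ), class = "nb_fit")
}

# NB2 log-likelihood at mean mu and dispersion theta
nb_loglik <- function(y, mu, theta) {
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# score vector of the NB2 log-likelihood in beta (log link)
nb_score <- function(fit) {
  mu <- fit$fitted.values
  as.numeric(crossprod(fit$X, (fit$y - mu) * fit$theta / (fit$theta + mu)))
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial (NB2) fit, n =", x$n, "\n")
  cat("theta =", format(x$theta, digits = 4),
      if (x$theta_fixed) "(fixed)" else "(ML)",
      " logLik =", format(x$logLik, digits = 8),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  cat("Coefficients (log scale):\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' @export
coef.nb_fit <- function(object, ...) object$coefficients

#' @export
vcov.nb_fit <- function(object, ...) object$vcov

#' @export
logLik.nb_fit <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coefficients) + !object$theta_fixed,
            nobs = object$n, class = "logLik")
}

#' @export
summary.nb_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  p <- 2 * pnorm(-abs(z))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               IRR = exp(object$coefficients),
               `IRR 2.5%` = exp(object$coefficients - 1.96 * se),
               `IRR 97.5%` = exp(object$coefficients + 1.96 * se),
               `z value` = z, `Pr(>|z|)` = p)
  structure(list(coefficients = tab, theta = object$theta,
                 logLik = object$logLik, n = object$n,
                 converged = object$converged),
            class = "summary.nb_fit")
}

#' @export
print.summary.nb_fit <- function(x, ...) {
  cat("Negative-binomial (NB2) fit, n =", x$n, ", theta =",
      format(x$theta, digits = 4), "\n")
  stats::printCoefmat(x$coefficients, has.Pvalue = TRUE, ...)
  invisible(x)
}

#' @export
predict.nb_fit <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  eta <- drop(X %*% object$coefficients)
  if (type == "response") exp(eta) else eta
}

#' @export
residuals.nb_fit <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  mu <- object$fitted.values
  y <- object$y
  th <- object$theta
  if (type == "pearson") {
    (y - mu) / sqrt(mu + mu^2 / th)
  } else {
    d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) -
                (y + th) * log((y + th) / (mu + th)))
    sign(y - mu) * sqrt(pmax(d, 0))
  }
}

#' @export
simulate.nb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim,
                   rnbinom(object$n, size = object$theta,
                           mu = object$fitted.values),
                   simplify = FALSE)
  as.data.frame(setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
plot.nb_fit <- function(x, ...) {
  graphics::plot(x$fitted.values, residuals(x, "pearson"),
                 xlab = "Fitted mean", ylab = "Pearson residual",
                 main = "NB2 fit diagnostics", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis with knots at standard sample
#' quantiles: 10/50/90\% for 3 knots, 5/35/65/95\% for 4, and
#' 5/27.5/50/72.5/95\% for 5. The basis is linear beyond the boundary knots
#' and has \code{n_knots - 1} columns (including the linear direction).
#'
#' @param x numeric vector.
#' @param n_knots number of knots (3, 4 or 5).
#' @return An object of class \code{rcs_basis} with elements \code{basis}
#'   (matrix with \code{n_knots - 1} columns), \code{knots} and \code{x}.
#' @export
rcs_basis <- function(x, n_knots = 3L) {
  if (!n_knots %in% 3:5) stop("n_knots must be 3, 4 or 5")
  probs <- switch(as.character(n_knots),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95))
  knots <- quantile(x, probs, na.rm = TRUE, names = FALSE, type = 7)
  if (anyDuplicated(knots))
    stop("tied quantiles collapse spline knots; too few distinct values")
  inner <- knots[-c(1L, n_knots)]
  bk <- knots[c(1L, n_knots)]
  B <- splines::ns(x, knots = inner, Boundary.knots = bk)
  B <- matrix(as.numeric(B), nrow = length(x),
              dimnames = list(NULL, paste0("rcs", seq_len(ncol(B)))))
  structure(list(basis = B, knots = knots, x = x), class = "rcs_basis")
}

#' Likelihood-ratio test of dose-response linearity
#'
#' Compares an NB2 model with a linear exposure term against one replacing
#' the exposure by a restricted-cubic-spline basis with \code{n_knots}
#' knots. The test statistic is twice the log-likelihood difference on
#' \code{n_knots - 2} degrees of freedom.
#'
#' @param y count response.
#' @param X_cov covariate design matrix (with intercept).
#' @param exposure exposure vector.
#' @param n_knots number of spline knots.
#' @return p-value of the likelihood-ratio test, with the two fits attached
#'   as attributes.
#' @export
test_linearity <- function(y, X_cov, exposure, n_knots = 3L) {
  X_cov <- as.matrix(X_cov)
  fit_lin <- fit_negbin(y, cbind(X_cov, exposure = exposure))
  B <- rcs_basis(exposure, n_knots)$basis
  fit_spl <- fit_negbin(y, cbind(X_cov, B))
  if (!fit_spl$converged) {
    out <- NA_real_
    attr(out, "inconclusive") <- TRUE
    return(out)
  }
  lrt <- 2 * (fit_spl$logLik - fit_lin$logLik)
  p <- pchisq(max(lrt, 0), df = n_knots - 2L, lower.tail = FALSE)
  attr(p, "lrt") <- lrt
  attr(p, "fit_linear") <- fit_lin
  attr(p, "fit_spline") <- fit_spl
  p
}

#' Variance inflation factors of design-matrix columns
#'
#' \eqn{VIF_j = 1/(1 - R^2_j)} where \eqn{R^2_j} comes from regressing
#' column \eqn{j} on all remaining columns (plus an intercept). Exact
#' collinearity yields \code{Inf}.
#'
#' @param X numeric matrix (intercept column, if present, is skipped as a
#'   target but used as a predictor).
#' @param columns optional names/indices of the columns to report.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X, columns = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  is_const <- apply(X, 2, function(v) var(v) == 0)
  targets <- colnames(X)[!is_const]
  if (!is.null(columns)) {
    targets <- if (is.numeric(columns)) colnames(X)[columns] else columns
  }
  out <- setNames(numeric(length(targets)), targets)
  for (j in targets) {
    yj <- X[, j]
    Zp <- cbind(1, X[, setdiff(colnames(X), j), drop = FALSE])
    f <- lm.fit(Zp, yj)
    rss <- sum(f$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss <= 0) { out[j] <- Inf; next }
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}
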