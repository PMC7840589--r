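#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Combines \code{m} per-imputation estimates and variances: pooled
#' estimate \eqn{\bar{Q}} (mean), within-imputation variance \eqn{\bar{U}}
#' (mean of variances), between-imputation variance \eqn{B} (sample
#' variance of estimates), total variance \eqn{T = \bar{U} + (1 + 1/m)B},
#' with a Wald interval on Barnard-Rubin adjusted degrees of freedom when
#' the complete-data degrees of freedom \code{dfcom} are supplied.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param variances matching vector of squared standard errors.
#' @param dfcom complete-data residual degrees of freedom (\code{Inf} gives
#'   the classic large-sample Rubin df).
#' @param conf confidence level.
#' @return list with \code{qbar}, \code{ubar}, \code{b}, \code{t},
#'   \code{se}, \code{df}, \code{ci}, \code{p}, \code{m}.
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf, conf = 0.95) {
  m <- length(estimates)
  if (m < 2L) stop("Rubin pooling needs at least 2 imputations")
  if (length(variances) != m) stop("estimates and variances must match")
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- var(estimates)
  tt <- ubar + (1 + 1 / m) * b
  if (b <= 0 || tt <= 0) {
    df <- dfcom
  } else {
    lam <- (1 + 1 / m) * b / tt
    df_old <- (m - 1) / lam^2
    df <- if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lam)
      df_old * df_obs / (df_old + df_obs)
    } else df_old
  }
  se <- sqrt(tt)
  alpha2 <- (1 - conf) / 2
  crit <- if (is.finite(df)) qt(1 - alpha2, df) else qnorm(1 - alpha2)
  p <- if (is.finite(df)) 2 * pt(-abs(qbar / se), df)
       else 2 * pnorm(-abs(qbar / se))
  list(qbar = qbar, ubar = ubar, b = b, t = tt, se = se, df = df,
       ci = c(qbar - crit * se, qbar + crit * se), p = p, m = m)
}

#' Effective number of independent exposures
#'
#' From the eigenvalues \eqn{\lambda_i} of the exposure correlation matrix,
#' \eqn{M_e = M - \sum_i I(\lambda_i > 1)(\lambda_i - 1)}, clamped to
#' \eqn{[1, M]}: an identity matrix (independent exposures) gives
#' \eqn{M_e = M}, total correlation gives 1. \code{printed_form = TRUE}
#' returns the bare sum \eqn{\sum_i I(\lambda_i > 1)(\lambda_i - 1)}
#' instead (degenerate at independence; kept for comparability).
#'
#' @param corr symmetric unit-diagonal correlation matrix.
#' @param printed_form return the uncorrected sum instead.
#' @return \eqn{M_e}, with eigenvalues attached as an attribute.
#' @export
effective_tests <- function(corr, printed_form = FALSE) {
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  M <- nrow(corr)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  s <- sum(pmax(ev - 1, 0))
  me <- if (printed_form) s else min(max(M - s, 1), M)
  attr(me, "eigenvalues") <- ev
  attr(me, "M") <- M
  me
}

#' Bonferroni-type FWER threshold using the effective number of tests
#'
#' @param alpha family-wise error rate to control, in (0, 1).
#' @param m_e effective number of independent exposures (>= 1).
#' @return corrected p-value threshold \code{alpha / m_e}.
#' @export
fwer_threshold <- function(alpha = 0.05, m_e) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m_e < 1) stop("m_e must be >= 1")
  alpha / as.numeric(m_e)
}

#' DerSimonian-Laird random-effects combination with I-squared
#'
#' Fixed-effect weights give Cochran's \eqn{Q}; the method-of-moments
#' between-study variance is
#' \eqn{\tau^2 = \max(0, (Q - df) / (\sum w - \sum w^2 / \sum w))} and
#' \eqn{I^2 = \max(0, (Q - df)/Q)}. Bands: \eqn{I^2 < 0.3} low,
#' \eqn{0.3 \le I^2 < 0.6} moderate, \eqn{\ge 0.6} substantial-to-high.
#'
#' @param estimates per-group (e.g., per-cohort) effect estimates.
#' @param variances their variances.
#' @param labels optional group labels.
#' @return object of class \code{heterogeneity}: \code{q}, \code{df},
#'   \code{tau2}, \code{i2}, \code{band}, the random-effects pooled
#'   estimate and SE, and the per-group table.
#' @export
dl_meta <- function(estimates, variances, labels = NULL) {
  k <- length(estimates)
  if (k < 2L) stop("need at least 2 groups for heterogeneity")
  stopifnot(length(variances) == k, all(variances > 0))
  w <- 1 / variances
  fe <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - fe)^2)
  df <- k - 1
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  w_re <- 1 / (variances + tau2)
  re <- sum(w_re * estimates) / sum(w_re)
  se_re <- sqrt(1 / sum(w_re))
  band <- if (i2 < 0.3) "low" else if (i2 < 0.6) "moderate"
          else "substantial-to-high"
  structure(list(
    q = q, df = df, tau2 = tau2, i2 = i2, band = band,
    estimate = re, se = se_re, fixed_effect = fe,
    groups = data.frame(label = labels %||% paste0("group", seq_len(k)),
                        estimate = estimates, variance = variances)
  ), class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf(
    "Between-group heterogeneity: Q = %.3f on %d df, tau2 = %.4f, I2 = %.3f (%s)\n",
    x$q, x$df, x$tau2, x$i2, x$band))
  cat(sprintf("Random-effects estimate: %.4f (SE %.4f)\n", x$estimate,
              x$se))
  print(x$groups)
  invisible(x)
}
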