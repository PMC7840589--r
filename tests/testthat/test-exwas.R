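test_that("Rubin pooling matches the closed forms", {
  # hand computation: estimates {0.1, 0.3}, variances {0.04, 0.04}
  pl <- rubin_pool(c(0.1, 0.3), c(0.04, 0.04))
  expect_equal(pl$qbar, 0.2)
  expect_equal(pl$ubar, 0.04)
  expect_equal(pl$b, 0.02)
  expect_equal(pl$t, 0.04 + (1 + 1 / 2) * 0.02)  # 0.07
  expect_equal(pl$t, 0.07)
  # identical estimates: no between-imputation variance
  pl0 <- rubin_pool(rep(0.25, 5), rep(0.01, 5))
  expect_equal(pl0$b, 0)
  expect_equal(pl0$t, pl0$ubar)
  # CI width grows with B at fixed Ubar
  w <- vapply(c(0, 0.01, 0.05), function(b) {
    est <- c(0.2 - sqrt(b), 0.2 + sqrt(b))
    p <- rubin_pool(est, c(0.04, 0.04))
    diff(p$ci)
  }, 0)
  expect_true(all(diff(w) > 0))
  expect_error(rubin_pool(0.1, 0.04), "at least 2")
})

test_that("effective number of tests spans identity to rank one", {
  expect_equal(as.numeric(effective_tests(diag(10))), 10)
  ones <- matrix(1, 2, 2)
  expect_equal(as.numeric(effective_tests(ones)), 1)
  eq3 <- matrix(0.5, 3, 3); diag(eq3) <- 1
  # eigenvalues {2, 0.5, 0.5}: M_e = 3 - (2 - 1) = 2
  expect_equal(as.numeric(effective_tests(eq3)), 2)
  # printed (uncorrected) form kept as a flag
  expect_equal(as.numeric(effective_tests(eq3, printed_form = TRUE)), 1)
  expect_error(effective_tests(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
  # monotone: stronger equicorrelation cannot increase M_e
  me <- vapply(seq(0, 0.9, by = 0.1), function(r) {
    m <- matrix(r, 5, 5); diag(m) <- 1
    as.numeric(effective_tests(m))
  }, 0)
  expect_true(all(diff(me) <= 1e-12))
})

test_that("the corrected threshold is alpha over M_e", {
  expect_equal(fwer_threshold(0.05, 1), 0.05)
  expect_equal(fwer_threshold(0.05, 25), 0.002)
  expect_error(fwer_threshold(1.2, 5), "alpha")
  expect_error(fwer_threshold(0.05, 0.5), "m_e")
  # correlated families put the threshold strictly between alpha/M and alpha
  for (s in 1:3) {
    p <- generate_exposures(synth_config(seed = 300 + s))
    lx <- log(p$truth$latent)
    me <- effective_tests(cor(lx))
    thr <- fwer_threshold(0.05, me)
    expect_gt(thr, 0.05 / ncol(lx))
    expect_lt(thr, 0.05)
  }
})

test_that("a degenerate stack pools to the single-dataset fit", {
  tab <- complete_table(seed = 9, n_per_cohort = 70)
  stack <- impute_chained(tab, m = 3, n_iter = 1, seed = 2)
  covs <- c("cohort", "sex", "child_age", "smoking")
  scan <- run_exwas(stack, "externalizing",
                    exposures = attr(tab, "exposure_names")[1:3],
                    covariates = covs)
  expect_true(all(scan$b == 0))
  # oracle: direct single fit of the same model
  X0 <- model.matrix(~ cohort + sex + child_age + smoking, tab)
  e <- scan$exposure[1]
  f <- fit_negbin(tab$externalizing, cbind(X0, tab[[e]]))
  expect_equal(scan$log_irr[1], unname(coef(f)[ncol(X0) + 1]),
               tolerance = 1e-8)
  expect_true(all(scan$ci_low < scan$irr & scan$irr < scan$ci_high))
  expect_true(!is.unsorted(scan$p))
})

test_that("heterogeneity layer reproduces DL closed forms and metafor", {
  h0 <- dl_meta(rep(0.3, 4), rep(0.02, 4))
  expect_equal(h0$i2, 0)
  expect_equal(h0$band, "low")
  # Q below its df truncates I2 and tau2 at zero
  h1 <- dl_meta(c(0.29, 0.3, 0.31), rep(0.5, 3))
  expect_equal(h1$i2, 0)
  expect_equal(h1$tau2, 0)
  set.seed(11)
  est <- rnorm(6, 0.2, 0.3)
  v <- runif(6, 0.02, 0.2)
  h <- dl_meta(est, v)
  skip_if_not_installed("metafor")
  m <- metafor::rma(yi = est, vi = v, method = "DL")
  expect_equal(h$tau2, m$tau2, tolerance = 1e-10)
  expect_equal(h$q, as.numeric(m$QE), tolerance = 1e-10)
  expect_equal(h$estimate, as.numeric(m$beta), tolerance = 1e-10)
  # fixed-effect consistency at tau2 = 0
  w <- 1 / v
  expect_equal(h$fixed_effect, sum(w * est) / sum(w))
  # bands follow the stated cuts
  expect_equal(dl_meta(c(0, 1), c(0.01, 0.01))$band, "substantial-to-high")
})

test_that("injected between-cohort variance is recovered on average", {
  # within-variance 0.08 reflects per-cohort adjusted fits dominated by
  # the small cohorts (SE ~ 0.28); the analytic form is an approximation
  # whose accuracy degrades at high precision ratios with few cohorts
  set.seed(13)
  tau2 <- 0.04; v <- 0.08; k <- 5
  i2 <- replicate(200, {
    dl_meta(rnorm(k, 0, sqrt(v + tau2)), rep(v, k))$i2
  })
  expect_lt(abs(mean(i2) - tau2 / (tau2 + v)), 0.1)
})

test_that("per-cohort fits feed the heterogeneity summary", {
  tab <- complete_table(seed = 14, n_per_cohort = 90)
  stack <- impute_chained(tab, m = 2, n_iter = 1, seed = 3)
  e <- attr(tab, "exposure_names")[1]
  h <- meta_heterogeneity(stack, e, "externalizing",
                          covariates = c("cohort", "sex", "child_age"))
  expect_s3_class(h, "heterogeneity")
  expect_equal(nrow(h$groups), 3L)
  expect_true(h$i2 >= 0 && h$i2 <= 1)
})

test_that("cohort exclusion drops exactly the named cohort", {
  cfg <- synth_config(seed = 55)    # 46/193/218/83/168
  st <- generate_study(cfg)
  prep <- prepare_exposures(st$panel, st$covariates, seed = 55)
  tab <- build_analysis_table(prep, st$outcomes)
  tab_cc <- tab
  tab_cc[] <- lapply(tab_cc, function(v) { v[is.na(v)] <- v[!is.na(v)][1]; v })
  attr(tab_cc, "exposure_names") <- attr(tab, "exposure_names")
  scan <- cohort_exclusion(tab_cc, "coh1", "externalizing",
                           exposures = attr(tab, "exposure_names")[1:2])
  expect_equal(attr(scan, "n"), 708 - 46)   # 662
  expect_error(cohort_exclusion(tab_cc, "nope", "externalizing",
                                exposures = attr(tab, "exposure_names")[1]),
               "unknown cohort")
})

test_that("sex interaction model nests the main model", {
  tab <- complete_table(seed = 16, n_per_cohort = 80)
  e <- attr(tab, "exposure_names")[1]
  covs <- c("cohort", "sex", "child_age")
  X0 <- cbind(model.matrix(~ cohort + sex + child_age, tab),
              exp = tab[[e]])
  male <- as.numeric(tab$sex == "male")
  f_main <- fit_negbin(tab$externalizing, X0)
  f_int <- fit_negbin(tab$externalizing, cbind(X0, inter = tab[[e]] * male))
  expect_gte(f_int$logLik, f_main$logLik - 1e-6)
  r <- sex_interaction(tab, e, "externalizing", covariates = covs)
  expect_true(r$p > 0 && r$p <= 1)
  expect_equal(r$estimate, unname(coef(f_int)["inter"]), tolerance = 1e-6)
  one_sex <- tab[tab$sex == "male", ]
  one_sex$sex <- droplevels(one_sex$sex)
  expect_error(sex_interaction(one_sex, e, "externalizing",
                               covariates = covs), "both sexes")
})

test_that("coexposure model applies the VIF exclusion rule", {
  set.seed(17)
  n <- 400
  z <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  e1 <- z[, 1]
  e2 <- 0.97 * e1 + sqrt(1 - 0.97^2) * z[, 2]   # corr exactly 0.97
  e3 <- z[, 3]
  sex <- factor(sample(c("female", "male"), n, TRUE))
  y <- rnbinom(n, size = 2, mu = exp(1.3 + 8 * e1 + 6 * e3))
  dat <- data.frame(e1 = e1, e2 = e2, e3 = e3, sex = sex,
                    externalizing = y)
  scan <- data.frame(exposure = c("e1", "e2", "e3"),
                     p = c(0.01, 0.01, 0.01))
  expect_message(
    cm <- coexposure_model(dat, "externalizing", scan,
                           covariates = "sex"),
    "removed by VIF")
  expect_length(attr(cm, "removed_by_vif"), 1L)
  expect_equal(nrow(cm), 2L)
  # empty inclusion set is a no-op with a message
  scan0 <- data.frame(exposure = "e1", p = 0.9)
  expect_message(out <- coexposure_model(dat, "externalizing", scan0,
                                         covariates = "sex"),
                 "no exposure enters")
  expect_null(out)
})

test_that("single-level stratification equals the unstratified fit", {
  tab <- complete_table(seed = 18, n_per_cohort = 70)
  tab$stratum <- factor(rep("adequate", nrow(tab)),
                        levels = c("adequate"))
  es <- attr(tab, "exposure_names")[1:2]
  covs <- c("cohort", "sex", "child_age")
  stack <- impute_chained(tab, m = 2, n_iter = 1, seed = 4)
  st <- stratified_exwas(stack, es, "externalizing",
                         strata_var = "stratum", covariates = covs)
  expect_named(st, "adequate")
  ref <- run_exwas(stack, "externalizing", exposures = es,
                   covariates = covs)
  got <- st$adequate[order(st$adequate$exposure), ]
  ref_df <- as.data.frame(ref)[order(ref$exposure), ]
  expect_equal(got$log_irr, ref_df$log_irr, tolerance = 1e-10)
  # tiny strata are skipped with a warning
  tab2 <- tab
  tab2$stratum <- factor(c("rare", rep("adequate", nrow(tab) - 1)),
                         levels = c("adequate", "rare"))
  stack2 <- impute_chained(tab2, m = 2, n_iter = 1, seed = 4)
  expect_warning(st2 <- stratified_exwas(stack2, es, "externalizing",
                                         strata_var = "stratum",
                                         covariates = covs),
                 "below minimum")
  expect_false("rare" %in% names(st2))
})
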