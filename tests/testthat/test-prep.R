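# hand-built panel for the detection filter
make_panel <- function(det = c(0.05, 0.50, 0.95), n = 100) {
  p <- length(det)
  conc <- matrix(rlnorm(n * p), n, p,
                 dimnames = list(NULL, paste0("b", seq_len(p))))
  censored <- matrix(FALSE, n, p, dimnames = dimnames(conc))
  for (j in seq_len(p)) {
    k <- round((1 - det[j]) * n)
    if (k > 0) censored[seq_len(k), j] <- TRUE
  }
  conc[censored] <- NA
  structure(list(conc = conc, censored = censored,
                 missing = matrix(FALSE, n, p, dimnames = dimnames(conc)),
                 meta = data.frame(name = colnames(conc), family = "f",
                                   medium = "blood", lod = 0.5,
                                   transform = "log2",
                                   standardize = "none"),
                 cohort = factor(rep("a", n)), truth = NULL),
            class = "exposome_panel")
}

test_that("detection filter removes poorly detected biomarkers", {
  set.seed(1)
  pan <- make_panel(c(0.05, 0.50, 0.95))
  suppressMessages(out <- filter_by_detection(pan, 0.10))
  expect_equal(ncol(out$conc), 2L)
  expect_identical(attr(out, "removed"), "b1")
  # a biomarker detected in 1.5% of samples is removed at the default cut
  pan2 <- make_panel(c(0.015, 0.95))
  suppressMessages(out2 <- filter_by_detection(pan2, 0.10))
  expect_false("b1" %in% out2$meta$name)
  # vanishing threshold keeps everything
  out3 <- filter_by_detection(pan, 1e-9)
  expect_equal(ncol(out3$conc), 3L)
  expect_error(filter_by_detection(pan, 0), "min_freq")
  expect_error(filter_by_detection(pan, 1.2), "min_freq")
})

test_that("below-LOD imputation fills the left tail and only the tail", {
  set.seed(10)
  x <- rlnorm(1000)
  lod <- quantile(x, 0.2, names = FALSE)
  cens <- x < lod
  x_obs <- x
  x_obs[cens] <- NA
  out <- impute_below_lod(x_obs, cens, lod, seed = 3)
  expect_true(all(out[cens] < lod))
  expect_identical(out[!cens], x_obs[!cens])
  # no censoring: identity
  expect_identical(impute_below_lod(x, rep(FALSE, 1000), lod), x)
  # all censored: cannot calibrate
  expect_error(impute_below_lod(rep(NA_real_, 5), rep(TRUE, 5), 1),
               "cannot calibrate")
  # heavy censoring falls back to LOD/sqrt(2)
  cens80 <- x < quantile(x, 0.8)
  x80 <- x; x80[cens80] <- NA
  out80 <- impute_below_lod(x80, cens80, quantile(x, 0.8, names = FALSE),
                            seed = 3)
  expect_equal(unique(out80[cens80]),
               quantile(x, 0.8, names = FALSE) / sqrt(2))
  expect_identical(attr(out80, "fallback"), "lod_sqrt2")
})

test_that("imputed tail matches the true sub-LOD distribution (KS)", {
  pass <- 0L
  for (s in 1:25) {
    set.seed(s)
    x <- rlnorm(1000)            # lognormal(0, 1)
    lod <- quantile(x, 0.2, names = FALSE)
    cens <- x < lod
    x_obs <- x; x_obs[cens] <- NA
    out <- impute_below_lod(x_obs, cens, lod, seed = s + 1000)
    ks <- suppressWarnings(stats::ks.test(out[cens], x[cens]))$statistic
    pass <- pass + (ks < 0.15)
  }
  expect_gte(pass, 23L)          # >= 90% of seeds
})

test_that("concentration standardization does the unit arithmetic", {
  expect_equal(standardize_concentration(2, "creatinine",
                                         creatinine = 1), 2,
               ignore_attr = TRUE)
  expect_equal(standardize_concentration(10, "lipids",
                                         total_lipids = 5), 2,
               ignore_attr = TRUE)
  expect_identical(standardize_concentration(7, "none"), 7)
  out <- standardize_concentration(c(2, 2), "creatinine",
                                   creatinine = c(1, NA))
  expect_true(is.na(out[2]) && out[1] == 2)
})

test_that("transform and IQR scaling follow the type-7 convention", {
  pan <- make_panel(c(1, 1), n = 4)
  pan$conc[, 1] <- c(2, 4, 8, 16)
  pan$conc[, 2] <- c(1, 3, 9, 27)
  ts <- transform_and_scale(pan)
  # log2 of {2,4,8,16} = {1,2,3,4}; type-7 quartiles 1.75/3.25 -> IQR 1.5
  expect_equal(unname(ts$spec$iqr["b1"]), 1.5)
  expect_equal(unname(ts$exposures[, "b1"]),
               c(1, 2, 3, 4) / 1.5, tolerance = 1e-12)
  # output IQR is 1 by construction
  q <- quantile(ts$exposures[, "b1"], c(0.25, 0.75), type = 7)
  expect_equal(unname(diff(q)), 1)
  # reusing the persisted spec is idempotent
  ts2 <- transform_and_scale(pan, spec = ts$spec)
  expect_identical(ts2$exposures, ts$exposures)
  # constant column is dropped with a warning
  pan$conc[, 2] <- 5
  expect_warning(ts3 <- transform_and_scale(pan), "zero IQR")
  expect_false("b2" %in% colnames(ts3$exposures))
  # cotinine rule uses the natural log
  pan4 <- make_panel(1, n = 4)
  pan4$conc[, 1] <- exp(c(1, 2, 3, 4))
  pan4$meta$transform <- "ln"
  ts4 <- transform_and_scale(pan4)
  expect_equal(unname(ts4$spec$iqr["b1"]), 1.5)
})

test_that("weight-gain classification follows the IOM bands", {
  expect_equal(as.character(classify_gwg(17, 10)), "insufficient")
  expect_equal(as.character(classify_gwg(31, 7)), "adequate")
  expect_equal(as.character(classify_gwg(27, 13)), "excessive")
  # band edges are inclusive
  expect_equal(as.character(classify_gwg(22, 11.5)), "adequate")
  expect_equal(as.character(classify_gwg(22, 16.0)), "adequate")
  expect_true(is.na(classify_gwg(NA, 10)))
  expect_true(is.na(classify_gwg(22, NA)))
  expect_error(classify_gwg(-1, 10), "positive")
})

test_that("the pipeline never alters observed concentrations", {
  cfg <- tiny_config(seed = 5)
  st <- generate_study(cfg)
  before <- st$panel$conc
  obs <- !(st$panel$censored | st$panel$missing)
  prep <- prepare_exposures(st$panel, st$covariates, seed = 9)
  kept <- colnames(prep$panel$conc)
  # LOD imputation fills censored cells but observed raw values feed the
  # standardization unchanged: recompute the expected standardized values
  for (j in kept) {
    std <- prep$panel$meta$standardize[prep$panel$meta$name == j]
    den <- switch(std, creatinine = st$covariates$creatinine_gl,
                  lipids = st$covariates$lipids_gl, 1)
    expect_equal(prep$panel$conc[obs[, j], j],
                 (before[, j] / den)[obs[, j]], tolerance = 1e-12)
  }
})
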