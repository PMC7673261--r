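# The gene-wise REML fitter against lme4/lmerTest, the field-standard
# implementations of the same model.

make_lmm_data <- function(seed = 42, g = 25, n_don = 8, spd = 3, k = 4,
                          donor_sd = 0.7, resid_sd = 0.5) {
  set.seed(seed)
  subject <- rep(sprintf("d%d", seq_len(n_don)), each = spd)
  subtype <- factor(rep(rep(sprintf("s%d", seq_len(k)), length.out = n_don),
                        each = spd))
  n <- length(subject)
  y <- matrix(0, g, n, dimnames = list(sprintf("g%02d", seq_len(g)),
                                       sprintf("smp%02d", seq_len(n))))
  for (gi in seq_len(g)) {
    b <- rnorm(n_don, 0, donor_sd)[as.integer(factor(subject))]
    eff <- rnorm(k, 0, 0.5)[as.integer(subtype)]
    y[gi, ] <- 5 + eff + b + rnorm(n, 0, resid_sd)
  }
  list(y = y, subject = subject, subtype = subtype,
       x = stats::model.matrix(~subtype))
}

test_that("REML estimates match lme4 gene by gene", {
  skip_if_not_installed("lme4")
  d <- make_lmm_data()
  # boundary semantics to mirror lme4's singular classification
  fit <- orthocat:::lmm_fit_genes(d$y, d$x, d$subject,
                                  reml_keep_threshold = 0)
  for (gi in seq_len(nrow(d$y))) {
    df <- data.frame(y = d$y[gi, ], subtype = d$subtype,
                     subject = d$subject)
    lf <- suppressMessages(lme4::lmer(y ~ subtype + (1 | subject),
                                      data = df, REML = TRUE))
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(unname(fit$beta[gi, ]), unname(lme4::fixef(lf)),
                 tolerance = 1e-6)
    expect_equal(fit$sigma2[gi], vc$vcov[2], tolerance = 1e-3)
    if (!lme4::isSingular(lf)) {
      expect_equal(fit$lambda[gi], vc$vcov[1] / vc$vcov[2],
                   tolerance = 1e-2)
    }
    expect_equal(fit$singular[gi], lme4::isSingular(lf))
  }
})

test_that("native Satterthwaite df and p-values match lmerTest", {
  skip_if_not_installed("lmerTest")
  d <- make_lmm_data(seed = 7, g = 15)
  fit <- orthocat:::lmm_fit_genes(d$y, d$x, d$subject,
                                  reml_keep_threshold = 0)
  fit <- orthocat:::ensure_satt_cache(fit)
  l_rows <- cbind(0, diag(ncol(d$x) - 1))
  for (gi in which(!fit$singular)) {
    df <- data.frame(y = d$y[gi, ], subtype = d$subtype,
                     subject = d$subject)
    lf <- suppressMessages(lmerTest::lmer(y ~ subtype + (1 | subject),
                                          data = df))
    an <- suppressWarnings(stats::anova(lf, ddf = "Satterthwaite"))
    expect_equal(orthocat:::satt_f_ddf(fit, gi, l_rows),
                 an[["DenDF"]][1], tolerance = 0.05)
    # 1-D contrast df via contest1D
    cv <- c(0, 1, rep(0, ncol(d$x) - 2))
    ct <- as.data.frame(lmerTest::contest1D(lf, cv))
    expect_equal(orthocat:::satt_contrast_df(fit, gi, cv), ct$df,
                 tolerance = 0.05)
  }
})

test_that("one sample per subject leaves the model unidentified (singular)", {
  set.seed(1)
  n <- 12
  y <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:n)))
  fit <- orthocat:::lmm_fit_genes(y, matrix(1, n, 1),
                                  sprintf("d%02d", 1:n))
  expect_true(all(fit$singular))
  expect_true(all(fit$lambda == 0))
})

test_that("Kenward-Roger null p-values are calibrated at the boundary", {
  # true donor variance zero, donors crossed with subtypes: the overall
  # F-test's raw p-values must be approximately uniform
  set.seed(31)
  k <- 8; spd <- 4; n <- k * spd; g <- 1500
  subtype <- rep(sprintf("s%d", 1:k), each = spd)
  donor <- sprintf("d%d", rep(1:spd, k))
  y <- matrix(rnorm(g * n), g, n,
              dimnames = list(sprintf("g%04d", 1:g), sprintf("c%02d", 1:n)))
  nm <- normalized_matrix(y, "vst", species = "sim")
  meta <- tibble::tibble(sample_id = colnames(y), species = "sim",
                         tissue = "t", subtype = subtype,
                         subject_id = donor)
  ft <- overall_f_test(nm, meta, df_method = "kenward-roger")
  expect_gt(stats::ks.test(ft$p_value, "punif")$p.value, 0.01)
  expect_lt(mean(ft$p_value < 0.05), 0.07)
  expect_gt(mean(ft$p_value < 0.05), 0.03)
})

test_that("real donor effects are detected and regressed out", {
  set.seed(13)
  n_don <- 12; spd <- 4; n <- n_don * spd; g <- 60
  subject <- rep(sprintf("d%02d", 1:n_don), each = spd)
  y <- matrix(0, g, n, dimnames = list(sprintf("g%03d", 1:g),
                                       sprintf("s%03d", 1:n)))
  for (gi in 1:g) {
    off <- rnorm(n_don, 0, 1)
    y[gi, ] <- 3 + off[rep(1:n_don, each = spd)] + rnorm(n, 0, 0.2)
  }
  fit <- orthocat:::lmm_fit_genes(y, matrix(1, n, 1), subject)
  expect_gt(mean(!fit$singular), 0.95)
  expect_true(all(fit$lambda[!fit$singular] > 1))
})
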