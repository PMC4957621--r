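test_that("Rubin pooling reproduces hand-computed combinations", {
  # identical pairs: no between-imputation variance
  pr <- pool_rubin(rep(0.05, 4), rep(2e-4, 4), dfcom = 100)
  expect_equal(pr$estimate, 0.05)
  expect_equal(pr$between_var, 0)
  expect_equal(pr$total_var, 2e-4)
  expect_equal(pr$df, 100)

  # m = 2 hand computation
  pr2 <- pool_rubin(c(0.06, 0.08), c(1e-4, 1e-4))
  expect_equal(pr2$estimate, 0.07)
  expect_equal(pr2$between_var, 2e-4)
  expect_equal(pr2$total_var, 1e-4 + 1.5 * 2e-4)

  # shift equivariance
  pr3 <- pool_rubin(c(0.06, 0.08) + 1, c(1e-4, 1e-4))
  expect_equal(pr3$estimate, pr2$estimate + 1)
  expect_equal(pr3$total_var, pr2$total_var)
  expect_equal(pr3$between_var, pr2$between_var)

  # order invariance
  pr4 <- pool_rubin(c(0.08, 0.06), c(1e-4, 1e-4))
  expect_equal(pr4$estimate, pr2$estimate)
  expect_equal(pr4$total_var, pr2$total_var)

  expect_error(pool_rubin(0.05, 1e-4), "2")
  expect_error(pool_rubin(c(0.05, 0.06), c(1e-4, 0)), "positive")
})

test_that("Barnard-Rubin df shrink with between-variance and bound dfcom", {
  pr_small_b <- pool_rubin(c(0.05, 0.051, 0.049), rep(1e-4, 3), dfcom = 50)
  pr_big_b <- pool_rubin(c(0.02, 0.08, 0.05), rep(1e-4, 3), dfcom = 50)
  expect_lt(pr_big_b$df, pr_small_b$df)
  expect_lte(pr_small_b$df, 50)
  # dfcom = Inf reduces to the classical large-sample formula
  pr_inf <- pool_rubin(c(0.02, 0.08, 0.05), rep(1e-4, 3))
  lambda <- (1 + 1 / 3) * pr_inf$between_var / pr_inf$total_var
  expect_equal(pr_inf$df, 2 / lambda^2)
})

test_that("complete tables impute to identical copies; m = 1 is rejected", {
  tab <- toy_analysis_table(100, seed = 301)
  imp <- mice_impute(tab, m = 3, seed = 1)
  expect_identical(imp$m, 3L)
  expect_identical(imp$tables[[1]], imp$tables[[2]])
  expect_identical(imp$tables[[1]]$father_weight_kg, tab$father_weight_kg)
  expect_error(mice_impute(tab, m = 1), "m >= 2")
})

test_that("imputation fills all cells, differs across chains, is seeded", {
  tab <- toy_analysis_table(300, seed = 302, miss_rate = 0.14)
  imp <- mice_impute(tab, m = 3, seed = 7)
  for (tb in imp$tables) {
    expect_false(anyNA(tb$father_weight_kg))
    expect_false(anyNA(tb$father_height_cm))
    expect_false(anyNA(tb$father_bmi))
  }
  mis <- is.na(tab$father_weight_kg)
  # observed cells untouched; imputed cells vary across chains
  expect_identical(imp$tables[[1]]$father_weight_kg[!mis],
                   tab$father_weight_kg[!mis])
  expect_false(identical(imp$tables[[1]]$father_weight_kg[mis],
                         imp$tables[[2]]$father_weight_kg[mis]))
  imp2 <- mice_impute(tab, m = 3, seed = 7)
  expect_identical(imp$tables, imp2$tables)
  expect_s3_class(imp$convergence, "data.frame")
})

test_that("MCAR masking of known truth imputes without systematic bias", {
  tab <- toy_analysis_table(5000, seed = 303)
  truth_fw <- tab$father_weight_kg
  set.seed(304)
  mis <- runif(5000) < 0.14
  tab$father_weight_kg[mis] <- NA
  tab$father_height_cm[mis] <- NA
  tab$father_bmi[mis] <- NA
  imp <- mice_impute(tab, m = 5, seed = 305)
  imputed_mean <- mean(vapply(imp$tables,
                              function(tb) mean(tb$father_weight_kg[mis]),
                              numeric(1)))
  se <- sd(truth_fw[mis]) / sqrt(sum(mis))
  expect_lt(abs(imputed_mean - mean(truth_fw[mis])), 4 * se)
})

test_that("pooled estimates converge to complete-case as missingness vanishes", {
  sim <- simulate_trios(trio_config(n_trios = 2000, seed = 306,
                                    missing_father_rate = 0))
  an <- build_analysis_table(sim$trios, sim$ref)
  cc <- fit_model(an, "bmi_z", "mother_bmi", adjusted = TRUE)$beta

  beta_at <- function(rate, seed) {
    tab <- an
    if (rate > 0) {
      set.seed(seed)
      mis <- runif(nrow(tab)) < rate
      tab$father_weight_kg[mis] <- NA
      tab$father_height_cm[mis] <- NA
      tab$father_bmi[mis] <- NA
    }
    imp <- mice_impute(tab, m = 5, seed = seed)
    est <- vapply(imp$tables, function(tb)
      fit_model(tb, "bmi_z", "mother_bmi", adjusted = TRUE)$beta, numeric(1))
    v <- vapply(imp$tables, function(tb)
      fit_model(tb, "bmi_z", "mother_bmi", adjusted = TRUE)$se, numeric(1))^2
    pool_rubin(est, v)$estimate
  }
  expect_equal(beta_at(0, 307), cc, tolerance = 1e-12)
  expect_lt(abs(beta_at(0.01, 308) - cc), 0.004)
  expect_lt(abs(beta_at(0.14, 309) - cc), 0.02)
})

test_that("pooled CIs cover the generating coefficients at nominal rate", {
  cover_m <- cover_f <- 0L
  truth <- implied_marginal_beta(trio_config(), "bmi_z")
  for (i in 1:100) {
    sim <- simulate_trios(trio_config(n_trios = 511, seed = 400 + i))
    an <- build_analysis_table(sim$trios, sim$ref)
    imp <- mice_impute(an, m = 5, seed = 500 + i)
    for (exp_ in c("mother_bmi", "father_bmi")) {
      fits <- lapply(imp$tables, fit_model, outcome = "bmi_z",
                     exposure = exp_, adjusted = TRUE)
      pr <- pool_rubin(vapply(fits, `[[`, numeric(1), "beta"),
                       vapply(fits, `[[`, numeric(1), "se")^2,
                       dfcom = fits[[1]]$df)
      tgt <- truth[[if (exp_ == "mother_bmi") "mother" else "father"]]
      hit <- pr$ci_low <= tgt && tgt <= pr$ci_high
      if (exp_ == "mother_bmi") cover_m <- cover_m + hit else
        cover_f <- cover_f + hit
    }
  }
  expect_gte(cover_m, 90L)
  expect_gte(cover_f, 90L)
})

test_that("MCAR p-values are uniform under the null and small under violation", {
  set.seed(401)
  pvals <- replicate(500, {
    n <- 120
    tab <- data.frame(bmi_z = rnorm(n), fmi_z = rnorm(n), lmi_z = rnorm(n),
                      mother_bmi = rnorm(n, 25, 4),
                      father_bmi = ifelse(runif(n) < 0.15, NA, rnorm(n, 26, 4)))
    mcar_check(tab)$p_value[1]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  # force missingness on high-z rows: strongly non-random
  set.seed(402)
  n <- 400
  tab <- data.frame(bmi_z = rnorm(n), fmi_z = rnorm(n), lmi_z = rnorm(n),
                    mother_bmi = rnorm(n, 25, 4),
                    father_bmi = rnorm(n, 26, 4))
  tab$father_bmi[tab$bmi_z > quantile(tab$bmi_z, 0.8)] <- NA
  chk <- mcar_check(tab)
  expect_lt(chk$p_value[chk$response == "bmi_z"], 1e-6)

  # no missing rows: empty result
  tab$father_bmi <- 26
  expect_identical(nrow(mcar_check(tab)), 0L)

  # tiny missing group: flagged not-applicable
  tab$father_bmi[1] <- NA
  chk1 <- mcar_check(tab)
  expect_false(any(chk1$applicable))
  expect_true(all(is.na(chk1$p_value)))
})

test_that("imputation guards its preconditions", {
  tab <- toy_analysis_table(100, seed = 403, miss_rate = 0.2)
  tab$mother_bmi[5] <- NA
  expect_error(mice_impute(tab, m = 2, seed = 1), "outside paternal")

  tab2 <- toy_analysis_table(35, seed = 404, miss_rate = 0.4)
  expect_error(mice_impute(tab2, m = 2, seed = 1), "30 complete")
})
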