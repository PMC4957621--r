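test_that("parental draws recover the configured assortative correlation", {
  cfg0 <- flat_config(rho = 0)
  set.seed(101)
  p0 <- draw_parents(20000, cfg0)
  expect_lt(abs(cor(p0$mother_bmi, p0$father_bmi)), 3 / sqrt(20000))

  set.seed(102)
  pd <- draw_parents(50000, trio_config())
  expect_lt(abs(cor(pd$mother_bmi, pd$father_bmi) - 0.143), 0.01)

  # near-degenerate correlation still yields valid in-range pairs
  cfg99 <- flat_config(rho = 0.99)
  set.seed(103)
  p99 <- draw_parents(2000, cfg99)
  expect_true(all(is.finite(p99$mother_bmi), is.finite(p99$father_bmi)))
  expect_gt(cor(p99$mother_bmi, p99$father_bmi), 0.9)
  expect_true(all(p99$father_bmi >= 16 & p99$father_bmi <= 44))
})

test_that("parental BMI means match the range-truncated normal at large n", {
  set.seed(104)
  p <- draw_parents(50000, trio_config())
  # marginal truncation oracle; joint resampling perturbs it only slightly
  em <- truncnorm_mean(25.4, 5.0, 16, 44)
  ef <- truncnorm_mean(26.4, 3.9, 16, 44)
  expect_equal(mean(p$mother_bmi), em, tolerance = 0.01)
  expect_equal(mean(p$father_bmi), ef, tolerance = 0.01)
})

test_that("offspring z-scores follow the configured transmission model", {
  cfg <- trio_config()
  set.seed(105)
  # no transmission: pure residual noise
  z0 <- draw_offspring_z(rep(25, 5000), rep(26, 5000),
                         rep("M", 5000), "bmi_z",
                         flat_config(b_mother = 0, b_father = 0))
  expect_equal(sd(z0), 1, tolerance = 0.05)
  expect_equal(mean(z0), 0, tolerance = 0.06)

  # noiseless limit with unit deviations is exactly beta_m + beta_f
  cfg0 <- flat_config(b_mother = 0.06, b_father = 0.04, resid = 0)
  z1 <- draw_offspring_z(cfg0$maternal_bmi_mean + 1,
                         cfg0$paternal_bmi_mean + 1, "F", "bmi_z", cfg0)
  expect_equal(z1, 0.10, tolerance = 1e-12)

  # OLS on generated truth recovers the sex-specific defaults
  set.seed(106)
  par <- draw_parents(20000, cfg)
  z <- draw_offspring_z(par$mother_bmi, par$father_bmi,
                        rep("M", 20000), "bmi_z", cfg)
  fit <- lm(z ~ par$mother_bmi + par$father_bmi)
  se <- sqrt(diag(vcov(fit)))[2:3]
  expect_lt(abs(coef(fit)[2] - 0.074), 4 * se[1])
  expect_lt(abs(coef(fit)[3] - 0.057), 4 * se[2])

  expect_error(draw_offspring_z(25, 26, "M", "height_z", cfg),
               "no transmission entry")
})

test_that("realized raw measurements round-trip through the pipeline", {
  cfg <- trio_config(n_trios = 3000, seed = 107)
  sim <- simulate_trios(cfg)
  complete <- sim$trios
  an <- build_analysis_table(complete, sim$ref)
  expect_equal(an$bmi_z, sim$truth$bmi_z, tolerance = 1e-6)
  expect_equal(an$fmi_z, sim$truth$fmi_z, tolerance = 1e-6)
  # only two z-scores are free; the third is implied by mass additivity
  expect_equal(an$lmi_z, sim$truth$lmi_z_implied, tolerance = 1e-6)
  # definitional hydration and BMC fractions
  expect_equal(complete$tbw_kg / an$lean_mass_kg,
               rep(0.73, nrow(complete)), tolerance = 1e-9)
  expect_equal(complete$bmc_kg / complete$weight_kg,
               rep(0.04, nrow(complete)), tolerance = 1e-9)
})

test_that("non-paternity replacement preserves structure and attenuates slopes", {
  cfg <- flat_config(n = 50000, rho = 0, b_mother = 0, b_father = 0.06,
                     seed = 108)
  set.seed(108)
  par <- draw_parents(cfg$n_trios, cfg)
  truth <- data.frame(mother_bmi = par$mother_bmi,
                      father_bmi_bio = par$father_bmi)

  t0 <- apply_nonpaternity(truth, p = 0, cfg)
  expect_identical(t0$father_bmi_reported, t0$father_bmi_bio)
  expect_true(all(t0$reported_is_biological))

  z <- draw_offspring_z(truth$mother_bmi, truth$father_bmi_bio,
                        rep("M", cfg$n_trios), "bmi_z", cfg)

  t1 <- apply_nonpaternity(truth, p = 1, cfg)
  expect_false(any(t1$reported_is_biological))
  f1 <- lm(z ~ t1$father_bmi_reported)
  expect_lt(abs(coef(f1)[2]), 4 * sqrt(diag(vcov(f1)))[2])

  th <- apply_nonpaternity(truth, p = 0.5, cfg)
  fh <- lm(z ~ th$father_bmi_reported)
  # analytic attenuation: observed slope = (1 - p) * beta_f when rho = 0
  expect_lt(abs(coef(fh)[2] - 0.5 * 0.06), 4 * sqrt(diag(vcov(fh)))[2])
})

test_that("MCAR masking hits the requested rate and the boundary cases", {
  cfg <- trio_config(n_trios = 400, seed = 109)
  sim <- simulate_trios(trio_config(n_trios = 400, seed = 109,
                                    missing_father_rate = 0))
  expect_false(anyNA(sim$trios$father_weight_kg))

  set.seed(110)
  m1 <- apply_missingness(sim$trios, 1)
  expect_true(all(is.na(m1$father_weight_kg)))
  expect_true(all(is.na(m1$father_height_cm)))

  set.seed(111)
  m14 <- apply_missingness(sim$trios, 0.14)
  expect_identical(is.na(m14$father_weight_kg), is.na(m14$father_height_cm))
})

test_that("the generator is deterministic in the seed and only the seed", {
  cfg <- trio_config(n_trios = 300, seed = 112)
  s1 <- simulate_trios(cfg)
  s2 <- simulate_trios(cfg)
  expect_identical(s1$trios, s2$trios)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_trios(trio_config(n_trios = 300, seed = 113))
  expect_false(identical(s1$trios$weight_kg, s3$trios$weight_kg))

  path1 <- withr::local_tempfile(fileext = ".csv")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trios(s1$trios, path1)
  write_trios(s2$trios, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("noiseless complete data return the configured coefficients everywhere", {
  cfg <- flat_config(n = 3000, seed = 114, b_mother = 0.08, b_father = 0.04,
                     rho = 0, resid = 0)
  sim <- simulate_trios(cfg)
  tab <- truth_table(sim)
  grid <- fit_grid(tab)
  # adjusted cells recover the generating coefficients exactly
  adj <- grid[grid$adjusted, ]
  want <- ifelse(adj$exposure == "mother_bmi", 0.08, 0.04)
  expect_equal(adj$beta, want, tolerance = 1e-6)
  # unadjusted cells equal the omitted-variable closed form from sample
  # moments (finite-sample in-sample correlation is not exactly zero)
  for (i in which(!grid$adjusted)) {
    sub <- if (grid$stratum[i] == "all") tab else
      tab[tab$sex == ifelse(grid$stratum[i] == "male", "M", "F"), ]
    x <- sub[[grid$exposure[i]]]
    other <- sub[[setdiff(c("mother_bmi", "father_bmi"), grid$exposure[i])]]
    b_x <- if (grid$exposure[i] == "mother_bmi") 0.08 else 0.04
    b_o <- if (grid$exposure[i] == "mother_bmi") 0.04 else 0.08
    want_i <- b_x + b_o * cov(x, other) / var(x)
    expect_equal(grid$beta[i], want_i, tolerance = 1e-9)
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(trio_config(assortative_rho = 1), "abs")
  expect_error(trio_config(missing_father_rate = 1.2), "missing_father_rate")
  expect_error(trio_config(residual_cor = c(bmi_fmi = 0.99, bmi_lmi = -0.99,
                                            fmi_lmi = 0.99)),
               "positive definite")
  bad_tr <- trio_config()$transmission
  bad_tr$bmi_z$M <- c(mom = 0.1, father = 0.1)
  expect_error(trio_config(transmission = bad_tr), "transmission")
})
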