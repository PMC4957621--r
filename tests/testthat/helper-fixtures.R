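# shared fixtures: all built in code at test time

# config in which every outcome and sex shares one (mother, father) pair
flat_config <- function(n = 1000, seed = 1, b_mother = 0.06,
                        b_father = 0.04, rho = 0.143, resid = 1,
                        missing = 0, nonpat = 0, ...) {
  tr1 <- c(mother = b_mother, father = b_father)
  trio_config(
    n_trios = n, seed = seed, assortative_rho = rho,
    transmission = list(bmi_z = list(M = tr1, F = tr1),
                        fmi_z = list(M = tr1, F = tr1),
                        lmi_z = list(M = tr1, F = tr1)),
    residual_sd = c(bmi_z = resid, fmi_z = resid, lmi_z = resid),
    missing_father_rate = missing, nonpaternity_rate = nonpat, ...)
}

# regression table taken from the generator's truth (drawn z-scores,
# reported father)
truth_table <- function(sim) {
  data.frame(mother_bmi = sim$truth$mother_bmi,
             father_bmi = sim$truth$father_bmi_reported,
             sex = sim$truth$sex,
             bmi_z = sim$truth$bmi_z, fmi_z = sim$truth$fmi_z,
             lmi_z = sim$truth$lmi_z)
}

# mean of a normal truncated to [lo, hi] (closed form)
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# analysis-shaped table with no 4C plumbing, for imputation/regression units
toy_analysis_table <- function(n = 200, seed = 1, miss_rate = 0) {
  set.seed(seed)
  mother_bmi <- rnorm(n, 25, 4)
  father_height_cm <- rnorm(n, 177, 6.5)
  father_weight_kg <- (0.3 * (mother_bmi - 25) + rnorm(n, 26, 3.5)) *
    (father_height_cm / 100)^2
  tb <- data.frame(
    sex = sample(c("M", "F"), n, replace = TRUE),
    age_y = runif(n, 5, 21), mother_bmi = mother_bmi,
    father_weight_kg = father_weight_kg,
    father_height_cm = father_height_cm,
    bmi_z = rnorm(n), fmi_z = rnorm(n), lmi_z = rnorm(n))
  tb <- add_parent_bmi(cbind(tb,
                             mother_weight_kg = mother_bmi * (1.64)^2,
                             mother_height_cm = 164))
  if (miss_rate > 0) {
    mask <- runif(n) < miss_rate
    tb$father_weight_kg[mask] <- NA
    tb$father_height_cm[mask] <- NA
    tb$father_bmi[mask] <- NA
  }
  tb
}
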