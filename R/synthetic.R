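#' Configuration of the synthetic trio generator
#'
#' Returns the full parameter set of the synthetic parent-offspring study,
#' with defaults calibrated to the cohort the package emulates: parental BMI
#' means/SDs and observed ranges, an assortative-mating correlation of
#' 0.143, sex-specific transmission coefficients equal to the adjusted
#' regression coefficients of the source cohort, residual SDs chosen so the
#' offspring z-score SDs are ~1.0-1.15, offspring ages uniform on
#' [5, 21.9] with a 0.485 male fraction, and a 14% MCAR paternal
#' missingness rate. Non-paternity is a sensitivity scenario, not a feature
#' of the observed-data model, so its default rate is 0.
#'
#' @param n_trios number of trios.
#' @param seed integer seed; fully determines the generated study.
#' @param maternal_bmi_mean,maternal_bmi_sd latent maternal BMI moments
#'   (kg/m^2) before range truncation.
#' @param paternal_bmi_mean,paternal_bmi_sd latent paternal BMI moments.
#' @param assortative_rho latent (pre-truncation) mother-father BMI
#'   correlation, |rho| < 1. Range truncation shrinks the marginal
#'   variances and with them the realised correlation by a closed-form
#'   factor (about 0.914 at the default bounds); the default latent value
#'   0.1565 is chosen so the realised, truncated correlation is 0.143, the
#'   assortative-mating strength the generator is calibrated to.
#' @param bmi_range parental BMI bounds enforced by joint resampling.
#' @param transmission nested list \code{[[outcome]][[sex]]} of
#'   \code{c(mother=, father=)} coefficients (z per kg/m^2); outcomes
#'   \code{bmi_z, fmi_z, lmi_z}, sexes \code{M, F}.
#' @param residual_sd named vector of residual SDs per outcome.
#' @param residual_cor pairwise correlations of the per-subject residuals
#'   across outcomes (\code{bmi_fmi, bmi_lmi, fmi_lmi}). Within a subject
#'   the index z-scores are strongly dependent (fat mass drives BMI), and
#'   without this dependence the lean-mass index implied by weight minus
#'   fat mass would be unrealistically dispersed.
#' @param age_range offspring age span (years).
#' @param sex_ratio proportion of male offspring.
#' @param missing_father_rate MCAR probability that paternal weight and
#'   height are jointly missing.
#' @param nonpaternity_rate probability that the reported father is not the
#'   biological father.
#' @param hydration lean-tissue hydration fraction (TBW = hydration * LM).
#' @param bmc_frac bone mineral content as a fraction of body weight.
#' @param mother_height_mean,mother_height_sd,father_height_mean,father_height_sd
#'   parental height models (cm).
#' @param height_sd offspring height residual SD (cm) around the age/sex
#'   mean curve.
#' @return object of class \code{trio_config}.
#' @export
trio_config <- function(n_trios = 511,
                        seed = 20160205,
                        maternal_bmi_mean = 25.4, maternal_bmi_sd = 5.0,
                        paternal_bmi_mean = 26.4, paternal_bmi_sd = 3.9,
                        assortative_rho = 0.1565,
                        bmi_range = c(16, 44),
                        transmission = list(
                          bmi_z = list(M = c(mother = 0.074, father = 0.057),
                                       F = c(mother = 0.071, father = 0.029)),
                          fmi_z = list(M = c(mother = 0.064, father = 0.041),
                                       F = c(mother = 0.055, father = 0.017)),
                          lmi_z = list(M = c(mother = 0.040, father = 0.029),
                                       F = c(mother = 0.057, father = 0.028))),
                        residual_sd = c(bmi_z = 1.07, fmi_z = 0.95,
                                        lmi_z = 1.04),
                        residual_cor = c(bmi_fmi = 0.85, bmi_lmi = 0.50,
                                         fmi_lmi = 0.00),
                        age_range = c(5, 21.9),
                        sex_ratio = 0.485,
                        missing_father_rate = 0.14,
                        nonpaternity_rate = 0,
                        hydration = 0.73,
                        bmc_frac = 0.04,
                        mother_height_mean = 163.5, mother_height_sd = 6.3,
                        father_height_mean = 177.0, father_height_sd = 6.7,
                        height_sd = 7.0) {
  cfg <- list(n_trios = n_trios, seed = as.integer(seed),
              maternal_bmi_mean = maternal_bmi_mean,
              maternal_bmi_sd = maternal_bmi_sd,
              paternal_bmi_mean = paternal_bmi_mean,
              paternal_bmi_sd = paternal_bmi_sd,
              assortative_rho = assortative_rho,
              bmi_range = bmi_range,
              transmission = transmission,
              residual_sd = residual_sd,
              residual_cor = residual_cor,
              age_range = age_range, sex_ratio = sex_ratio,
              missing_father_rate = missing_father_rate,
              nonpaternity_rate = nonpaternity_rate,
              hydration = hydration, bmc_frac = bmc_frac,
              mother_height_mean = mother_height_mean,
              mother_height_sd = mother_height_sd,
              father_height_mean = father_height_mean,
              father_height_sd = father_height_sd,
              height_sd = height_sd)
  class(cfg) <- "trio_config"
  validate_trio_config(cfg)
  cfg
}

validate_trio_config <- function(cfg) {
  stopifnot(cfg$n_trios >= 1,
            abs(cfg$assortative_rho) < 1,
            cfg$maternal_bmi_sd > 0, cfg$paternal_bmi_sd > 0,
            all(cfg$residual_sd >= 0),
            cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
            cfg$missing_father_rate >= 0, cfg$missing_father_rate <= 1,
            cfg$nonpaternity_rate >= 0, cfg$nonpaternity_rate <= 1,
            cfg$hydration > 0, cfg$hydration < 1,
            cfg$bmc_frac > 0, cfg$bmc_frac < 1,
            length(cfg$age_range) == 2, cfg$age_range[1] < cfg$age_range[2])
  for (oc in c("bmi_z", "fmi_z", "lmi_z")) {
    for (sx in c("M", "F")) {
      b <- cfg$transmission[[oc]][[sx]]
      if (is.null(b) || !all(c("mother", "father") %in% names(b))) {
        stop("transmission coefficients missing for (", oc, ", ", sx, ")",
             call. = FALSE)
      }
    }
  }
  ev <- eigen(residual_cor_matrix(cfg), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    stop("residual_cor is not positive definite", call. = FALSE)
  }
  invisible(cfg)
}

residual_cor_matrix <- function(cfg) {
  rc <- cfg$residual_cor
  matrix(c(1, rc[["bmi_fmi"]], rc[["bmi_lmi"]],
           rc[["bmi_fmi"]], 1, rc[["fmi_lmi"]],
           rc[["bmi_lmi"]], rc[["fmi_lmi"]], 1), 3, 3,
         dimnames = list(c("bmi_z", "fmi_z", "lmi_z"),
                         c("bmi_z", "fmi_z", "lmi_z")))
}

# joint draw of (bmi_z, fmi_z, lmi_z) with correlated residuals
draw_offspring_z_joint <- function(mother_bmi, father_bmi, sex, config) {
  n <- length(mother_bmi)
  corm <- residual_cor_matrix(config)
  eps <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(corm)
  out <- data.frame(bmi_z = numeric(n), fmi_z = numeric(n),
                    lmi_z = numeric(n))
  for (j in seq_along(colnames(corm))) {
    oc <- colnames(corm)[j]
    out[[oc]] <- draw_offspring_z(mother_bmi, father_bmi, sex, oc, config,
                                  resid = eps[, j] *
                                    config$residual_sd[[oc]])
  }
  out
}

#' Draw assortatively mated parental BMI pairs
#'
#' Bivariate normal maternal and biological-paternal BMI with the configured
#' means, SDs and assortative correlation, truncated to the configured
#' plausible range by joint resampling of out-of-range pairs.
#'
#' @param n number of pairs.
#' @param config a \code{\link{trio_config}}.
#' @return data.frame with \code{mother_bmi}, \code{father_bmi} (biological).
#' @export
draw_parents <- function(n, config = trio_config()) {
  rho <- config$assortative_rho
  lo <- config$bmi_range[1]; hi <- config$bmi_range[2]
  draw <- function(k) {
    zm <- stats::rnorm(k)
    zf <- rho * zm + sqrt(1 - rho^2) * stats::rnorm(k)
    data.frame(
      mother_bmi = config$maternal_bmi_mean + config$maternal_bmi_sd * zm,
      father_bmi = config$paternal_bmi_mean + config$paternal_bmi_sd * zf)
  }
  out <- draw(n)
  for (iter in seq_len(100)) {
    bad <- out$mother_bmi < lo | out$mother_bmi > hi |
      out$father_bmi < lo | out$father_bmi > hi
    if (!any(bad)) break
    out[bad, ] <- draw(sum(bad))
  }
  out
}

#' Draw offspring z-scores from the transmission model
#'
#' \deqn{z = \beta_m (M - \mu_m) + \beta_f (B - \mu_f) + \epsilon,\quad
#'   \epsilon \sim N(0, \sigma_{out}^2)}
#' with sex-specific coefficients and the biological father's BMI. The
#' parental deviations are taken from the configured latent means, so
#' E[z] = 0 by construction.
#'
#' @param mother_bmi,father_bmi parental BMI vectors (father = biological).
#' @param sex offspring sex vector ("M"/"F").
#' @param outcome one of \code{"bmi_z"}, \code{"fmi_z"}, \code{"lmi_z"}.
#' @param config a \code{\link{trio_config}}.
#' @param resid optional pre-drawn residual vector (used by the joint
#'   cross-outcome draw); by default residuals are drawn here.
#' @return numeric z-score vector.
#' @export
draw_offspring_z <- function(mother_bmi, father_bmi, sex, outcome,
                             config = trio_config(), resid = NULL) {
  tr <- config$transmission[[outcome]]
  if (is.null(tr)) stop("no transmission entry for outcome '", outcome, "'",
                        call. = FALSE)
  n <- length(mother_bmi)
  bm <- bf <- numeric(n)
  for (sx in c("M", "F")) {
    b <- tr[[sx]]
    if (is.null(b)) stop("no transmission entry for (", outcome, ", ", sx,
                         ")", call. = FALSE)
    bm[sex == sx] <- b[["mother"]]
    bf[sex == sx] <- b[["father"]]
  }
  if (is.null(resid)) {
    resid <- stats::rnorm(n, 0, config$residual_sd[[outcome]])
  }
  bm * (mother_bmi - config$maternal_bmi_mean) +
    bf * (father_bmi - config$paternal_bmi_mean) + resid
}

offspring_height_mean <- function(age, sex) {
  ifelse(sex == "M",
         86 + 7.0 * age - 0.12 * age^2,
         84 + 7.0 * age - 0.135 * age^2)
}

#' Realise raw 4C measurements from generated z-scores
#'
#' Inverse construction making the raw inputs self-consistent with the
#' body-composition pipeline: offspring height comes from an age/sex mean
#' curve plus noise, weight from the inverse-LMS of the drawn BMI z-score,
#' fat mass from the inverse-LMS of the drawn FMI z-score, lean mass as the
#' complement, TBW as \code{hydration * LM}, BMC as \code{bmc_frac *
#' weight}, and body volume by solving the 4C equation so that
#' \code{\link{compute_fat_mass}} recovers the fat mass exactly.
#'
#' Only two of the three index z-scores can be prescribed freely (the three
#' indices satisfy FMI + LMI = BMI); BMI and FMI are realised from their
#' drawn values and the implied LMI z-score is recorded in the truth table
#' as \code{lmi_z_implied}. Draws for which the inverse LMS leaves the
#' Box-Cox domain, or which would imply non-positive lean mass, have their
#' residuals redrawn (bounded retries, with a warning).
#'
#' @param truth truth table carrying \code{sex, age_y, mother_bmi,
#'   father_bmi_bio, father_bmi_reported, bmi_z, fmi_z, lmi_z}.
#' @param ref LMS reference covering all ages and sexes.
#' @param config a \code{\link{trio_config}}.
#' @param max_retries bounded residual-redraw attempts per pass.
#' @return list of \code{trios} (raw-measurement CSV dialect) and
#'   \code{truth} (input truth plus realised columns).
#' @export
realize_measurements <- function(truth, ref, config = trio_config(),
                                 max_retries = 20) {
  n <- nrow(truth)
  height <- offspring_height_mean(truth$age_y, truth$sex) +
    stats::rnorm(n, 0, config$height_sd)
  height <- pmax(height, 60)
  lms_b <- lookup_lms(ref, "bmi", truth$sex, truth$age_y)
  lms_f <- lookup_lms(ref, "fmi", truth$sex, truth$age_y)
  lms_l <- lookup_lms(ref, "lmi", truth$sex, truth$age_y)

  bmi <- lms_inverse(truth$bmi_z, lms_b$L, lms_b$M, lms_b$S)
  fmi <- lms_inverse(truth$fmi_z, lms_f$L, lms_f$M, lms_f$S)
  bad <- is.na(bmi) | is.na(fmi) | fmi >= bmi
  retries <- 0L
  while (any(bad) && retries < max_retries) {
    retries <- retries + 1L
    idx <- which(bad)
    zj <- draw_offspring_z_joint(truth$mother_bmi[idx],
                                 truth$father_bmi_bio[idx],
                                 truth$sex[idx], config)
    for (oc in c("bmi_z", "fmi_z", "lmi_z")) truth[[oc]][idx] <- zj[[oc]]
    bmi[idx] <- lms_inverse(truth$bmi_z[idx], lms_b$L[idx], lms_b$M[idx],
                            lms_b$S[idx])
    fmi[idx] <- lms_inverse(truth$fmi_z[idx], lms_f$L[idx], lms_f$M[idx],
                            lms_f$S[idx])
    bad <- is.na(bmi) | is.na(fmi) | fmi >= bmi
  }
  if (retries > 0L) {
    warning("redrew z-score residuals for out-of-domain inverse-LMS draws ",
            "(", retries, " pass(es))", call. = FALSE)
  }
  if (any(bad)) {
    stop("inverse-LMS construction failed after ", max_retries,
         " retries for ", sum(bad), " subject(s)", call. = FALSE)
  }

  h2 <- (height / 100)^2
  weight <- bmi * h2
  fm <- fmi * h2
  lm_ <- weight - fm
  tbw <- config$hydration * lm_
  bmc <- config$bmc_frac * weight
  # solve the 4C equation for body volume so the pipeline recovers FM exactly
  bv <- (fm + 0.710 * tbw - 1.460 * bmc + 2.050 * weight) / 2.747
  truth$lmi_z_implied <- lms_zscore(lm_ / h2, lms_l$L, lms_l$M, lms_l$S)

  mother_height <- stats::rnorm(n, config$mother_height_mean,
                                config$mother_height_sd)
  father_height <- stats::rnorm(n, config$father_height_mean,
                                config$father_height_sd)
  trios <- data.frame(
    subject_id = truth$subject_id,
    sex = truth$sex, age_y = truth$age_y,
    weight_kg = weight, height_cm = height,
    bv_l = bv, tbw_kg = tbw, bmc_kg = bmc,
    mother_weight_kg = truth$mother_bmi * (mother_height / 100)^2,
    mother_height_cm = mother_height,
    father_weight_kg = truth$father_bmi_reported * (father_height / 100)^2,
    father_height_cm = father_height)
  list(trios = trios, truth = truth)
}

#' Replace a fraction of reported fathers (non-paternity)
#'
#' With probability \code{p} per trio the reported father's BMI is replaced
#' by a fresh draw from the conditional distribution of a partner's BMI
#' given the mother's BMI, preserving the configured mother-reported-father
#' covariance (the equal-correlation convention, a = 1). Offspring z-scores
#' stay tied to the biological father.
#'
#' @param truth truth table with \code{mother_bmi}, \code{father_bmi_bio}.
#' @param p non-paternity probability.
#' @param config a \code{\link{trio_config}}.
#' @return truth with \code{father_bmi_reported} and
#'   \code{reported_is_biological} set.
#' @export
apply_nonpaternity <- function(truth, p = NULL, config = trio_config()) {
  if (is.null(p)) p <- config$nonpaternity_rate
  stopifnot(p >= 0, p <= 1)
  n <- nrow(truth)
  swap <- stats::runif(n) < p
  truth$reported_is_biological <- !swap
  truth$father_bmi_reported <- truth$father_bmi_bio
  if (any(swap)) {
    rho <- config$assortative_rho
    mu <- config$paternal_bmi_mean +
      rho * (config$paternal_bmi_sd / config$maternal_bmi_sd) *
        (truth$mother_bmi[swap] - config$maternal_bmi_mean)
    newf <- stats::rnorm(sum(swap), mu,
                         config$paternal_bmi_sd * sqrt(1 - rho^2))
    lo <- config$bmi_range[1]; hi <- config$bmi_range[2]
    for (iter in seq_len(100)) {
      bad <- newf < lo | newf > hi
      if (!any(bad)) break
      newf[bad] <- stats::rnorm(sum(bad), mu[bad],
                                config$paternal_bmi_sd * sqrt(1 - rho^2))
    }
    truth$father_bmi_reported[swap] <- newf
  }
  truth
}

#' MCAR masking of paternal anthropometry
#'
#' Blanks \code{father_weight_kg} and \code{father_height_cm} jointly with
#' the given Bernoulli probability, independent of everything else
#' (missing completely at random).
#'
#' @param trios trio table in the raw-measurement CSV dialect.
#' @param rate missingness probability in [0, 1].
#' @return trio table with masked paternal cells.
#' @export
apply_missingness <- function(trios, rate = 0.14) {
  stopifnot(rate >= 0, rate <= 1)
  mask <- stats::runif(nrow(trios)) < rate
  trios$father_weight_kg[mask] <- NA_real_
  trios$father_height_cm[mask] <- NA_real_
  trios
}

#' Simulate a complete synthetic trio study
#'
#' Orchestrates the generator end to end: assortative parental BMI pairs,
#' non-paternity replacement of reported fathers, sex-specific transmission
#' of parental BMI to offspring z-scores, inverse construction of raw 4C
#' measurements, and MCAR paternal missingness. Fully deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{trio_config}}.
#' @param ref LMS reference; defaults to \code{\link{synthetic_lms_reference}}.
#' @return list with \code{trios} (observed table, possibly with missing
#'   paternal cells), \code{truth} (complete generating truth) and
#'   \code{ref}.
#' @export
simulate_trios <- function(config = trio_config(),
                           ref = synthetic_lms_reference()) {
  validate_trio_config(config)
  set.seed(config$seed)
  n <- config$n_trios
  parents <- draw_parents(n, config)
  truth <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = ifelse(stats::runif(n) < config$sex_ratio, "M", "F"),
    age_y = stats::runif(n, config$age_range[1], config$age_range[2]),
    mother_bmi = parents$mother_bmi,
    father_bmi_bio = parents$father_bmi)
  truth <- apply_nonpaternity(truth, config$nonpaternity_rate, config)
  zj <- draw_offspring_z_joint(truth$mother_bmi, truth$father_bmi_bio,
                               truth$sex, config)
  truth <- cbind(truth, zj)
  realized <- realize_measurements(truth, ref, config)
  trios <- apply_missingness(realized$trios, config$missing_father_rate)
  list(trios = trios, truth = realized$truth, ref = ref)
}

#' Read / write trio tables in the package CSV dialect
#'
#' One header row; columns \code{subject_id, sex, age_y, weight_kg,
#' height_cm, bv_l, tbw_kg, bmc_kg, mother_weight_kg, mother_height_cm,
#' father_weight_kg, father_height_cm}; empty cells are missing values.
#'
#' @param path CSV path.
#' @return data.frame (for \code{read_trios}).
#' @export
read_trios <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("subject_id", "sex", "age_y", "weight_kg", "height_cm")
  if (!all(need %in% names(tr))) {
    stop("trio CSV needs at least columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tr
}

#' @rdname read_trios
#' @param trios trio data.frame.
#' @export
write_trios <- function(trios, path) {
  utils::write.csv(trios, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a truth table with its generating parameters as a header comment
#'
#' @param truth truth data.frame from \code{\link{simulate_trios}}.
#' @param config the generating \code{\link{trio_config}}.
#' @param path output CSV path.
#' @export
write_truth <- function(truth, config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  scalars <- Filter(function(x) is.atomic(x) && length(x) <= 2,
                    unclass(config))
  for (nm in names(scalars)) {
    writeLines(sprintf("# %s=%s", nm,
                       paste(scalars[[nm]], collapse = ",")), con)
  }
  utils::write.csv(truth, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Derive parental BMI columns from weights and heights
#'
#' @param trios trio table in the raw CSV dialect.
#' @return the table with \code{mother_bmi} and \code{father_bmi} columns
#'   (NA where parental anthropometry is missing).
#' @export
add_parent_bmi <- function(trios) {
  trios$mother_bmi <- trios$mother_weight_kg / (trios$mother_height_cm / 100)^2
  trios$father_bmi <- trios$father_weight_kg / (trios$father_height_cm / 100)^2
  trios
}

#' Marginal (all-offspring) transmission coefficient implied by a config
#'
#' With sex-specific transmission, the all-offspring regression targets the
#' sex-ratio-weighted average of the male and female coefficients (parental
#' BMI is independent of offspring sex in the generator).
#'
#' @param config a \code{\link{trio_config}}.
#' @param outcome outcome name.
#' @return named vector \code{c(mother=, father=)}.
#' @export
implied_marginal_beta <- function(config, outcome) {
  tr <- config$transmission[[outcome]]
  w <- config$sex_ratio
  c(mother = w * tr$M[["mother"]] + (1 - w) * tr$F[["mother"]],
    father = w * tr$M[["father"]] + (1 - w) * tr$F[["father"]])
}
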