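# Non-paternity sensitivity analysis.
#
# When a fraction p of reported fathers are not biological, the fitted
# paternal coefficient is attenuated and part of the paternal signal leaks
# into the maternal coefficient through assortative mating. The correction
# follows from the moment structure of the misattribution model: with
# maternal BMI variance sigma_mm, reported-paternal variance sigma_ff,
# mother/reported-father covariance sigma_fm and mother/biological-father
# covariance sigma_bm (parametrized through the indicator weight a), the
# covariance between reported and biological father is
#   sigma_fb = (1 - p) sigma_ff + p sigma_fm sigma_bm / sigma_mm,
# and the corrected coefficients are Lambda %*% c(beta1, beta2) with
# Lambda = A^-1 Sigma, A = [[sigma_mm, sigma_bm], [sigma_fm, sigma_fb]],
# Sigma the observed parental covariance matrix. Lambda is upper
# triangular with unit leading entry; for a = 1 it reduces to
#   beta1* = beta1 - p/(1-p) * beta2 * sigma_fm / sigma_mm,
#   beta2* = beta2 / (1 - p).

#' Parameters of the non-paternity attenuation model
#'
#' @param p non-paternity probability in [0, 1).
#' @param sigma_mm variance of maternal BMI.
#' @param sigma_ff variance of reported paternal BMI.
#' @param sigma_fm covariance of maternal and reported paternal BMI.
#' @param a indicator weight: 1 assumes the mother/biological-father
#'   covariance equals the mother/reported-father covariance (the
#'   equal-correlation convention, the default); \code{1 - p} assumes the
#'   biological father is uncorrelated with the mother.
#' @return object of class \code{attenuation_params}.
#' @export
attenuation_params <- function(p, sigma_mm, sigma_ff, sigma_fm, a = 1) {
  p <- unname(p); a <- unname(a)
  sigma_mm <- unname(sigma_mm); sigma_ff <- unname(sigma_ff)
  sigma_fm <- unname(sigma_fm)
  stopifnot(p >= 0, p < 1, sigma_mm > 0, sigma_ff > 0)
  if (sigma_fm^2 > sigma_mm * sigma_ff) {
    stop("invalid covariance: sigma_fm^2 exceeds sigma_mm * sigma_ff",
         call. = FALSE)
  }
  sigma_bm <- if (p == 0) sigma_fm else (a - 1 + p) / p * sigma_fm
  out <- list(p = p, a = a, sigma_mm = sigma_mm, sigma_ff = sigma_ff,
              sigma_fm = sigma_fm, sigma_bm = sigma_bm)
  class(out) <- "attenuation_params"
  out
}

#' Non-paternity correction matrix
#'
#' The 2x2 matrix Lambda mapping fitted (maternal, paternal) coefficients
#' from the adjusted model to their non-paternity-corrected values,
#' computed by solving the attenuated moment system numerically. Equals the
#' identity at p = 0 with a = 1.
#'
#' @param params an \code{\link{attenuation_params}}.
#' @return 2x2 numeric matrix.
#' @export
attenuation_matrix <- function(params) {
  stopifnot(inherits(params, "attenuation_params"))
  with(params, {
    sigma_fb <- (1 - p) * sigma_ff + p * sigma_fm * sigma_bm / sigma_mm
    A <- matrix(c(sigma_mm, sigma_fm, sigma_bm, sigma_fb), 2, 2)
    if (abs(det(A)) < 1e-12 * sigma_mm * sigma_ff) {
      stop("singular attenuation system", call. = FALSE)
    }
    Sigma <- matrix(c(sigma_mm, sigma_fm, sigma_fm, sigma_ff), 2, 2)
    solve(A, Sigma)
  })
}

#' Correct regression coefficients for non-paternity
#'
#' Applies the closed-form correction expressions and verifies them against
#' the independent matrix-solve route (\code{\link{attenuation_matrix}});
#' the two must agree to 1e-10 relative, guarding the algebra.
#'
#' @param beta1 fitted adjusted maternal coefficient.
#' @param beta2 fitted adjusted paternal coefficient.
#' @param params an \code{\link{attenuation_params}}.
#' @return named vector \code{c(beta1_star=, beta2_star=)}.
#' @export
adjust_coefficients <- function(beta1, beta2, params) {
  stopifnot(inherits(params, "attenuation_params"))
  beta1 <- unname(beta1); beta2 <- unname(beta2)
  dt <- with(params, (1 - p) * (sigma_ff * sigma_mm - sigma_fm * sigma_bm))
  if (abs(dt) < 1e-12 * params$sigma_mm * params$sigma_ff) {
    stop("singular attenuation system", call. = FALSE)
  }
  l12 <- with(params,
              ((1 - p) * sigma_ff * sigma_fm +
                 sigma_bm * (p * sigma_fm^2 / sigma_mm - sigma_ff)) / dt)
  l22 <- with(params, (sigma_mm * sigma_ff - sigma_fm^2) / dt)
  out <- c(beta1_star = beta1 + l12 * beta2, beta2_star = l22 * beta2)
  lam <- attenuation_matrix(params)
  alt <- drop(lam %*% c(beta1, beta2))
  scale <- max(abs(out), 1e-8)
  if (max(abs(out - alt)) > 1e-10 * max(1, scale)) {
    stop("internal inconsistency between explicit and matrix-solve ",
         "correction routes", call. = FALSE)
  }
  out
}

#' Rubin-pooled parental BMI (co)variances from an imputation set
#'
#' Sample variances of maternal and reported paternal BMI and their
#' covariance, computed in every completed table and pooled by the mean
#' rule.
#'
#' @param imp an \code{imputation_set}.
#' @return named vector \code{c(sigma_mm=, sigma_ff=, sigma_fm=)}.
#' @export
variance_of_parental_bmi <- function(imp) {
  stopifnot(inherits(imp, "imputation_set"))
  per <- vapply(imp$tables, function(tb) {
    c(stats::var(tb$mother_bmi), stats::var(tb$father_bmi),
      stats::cov(tb$mother_bmi, tb$father_bmi))
  }, numeric(3))
  out <- rowMeans(per)
  names(out) <- c("sigma_mm", "sigma_ff", "sigma_fm")
  if (any(out[1:2] <= 0)) stop("degenerate parental BMI variance",
                               call. = FALSE)
  out
}

# adjusted-model coefficients (mother, father) and their 2x2 vcov
adjusted_fit_vcov <- function(table, outcome) {
  keep <- stats::complete.cases(
    table[, c(outcome, "mother_bmi", "father_bmi")])
  tb <- table[keep, , drop = FALSE]
  fit <- stats::lm(stats::reformulate(c("mother_bmi", "father_bmi"),
                                      response = outcome), data = tb)
  idx <- c("mother_bmi", "father_bmi")
  list(beta = stats::coef(fit)[idx], vcov = stats::vcov(fit)[idx, idx],
       df = fit$df.residual, n = nrow(tb))
}

#' Non-paternity sensitivity sweep
#'
#' For each outcome and each assumed non-paternity probability p: fits the
#' assortative-mating-adjusted model on every completed table, pools the
#' (maternal, paternal) coefficient vector and its covariance by Rubin's
#' rules, pools the parental BMI (co)variances, corrects the coefficients
#' with the attenuation model, and (optionally) attaches the bootstrap
#' one-sided p-value for the maternal-minus-paternal difference. Failures
#' at a given p are flagged and the sweep continues.
#'
#' @param imp an \code{imputation_set} (its \code{original} table is used
#'   for the bootstrap).
#' @param p_grid non-paternity probabilities in [0, 1).
#' @param outcomes outcome z-score columns to sweep.
#' @param a indicator weight convention, see
#'   \code{\link{attenuation_params}}; the value \code{"1-p"} selects
#'   \code{a = 1 - p} per grid point.
#' @param B bootstrap replicates for the difference test; 0 skips it.
#' @param m_boot imputations per bootstrap replicate.
#' @param seed seed for the bootstrap stage.
#' @return data.frame: \code{outcome, p, beta_m_adj, beta_f_adj, var_m,
#'   var_f, p_one_sided}.
#' @export
sensitivity_sweep <- function(imp, p_grid = c(0, 0.01, 0.02, 0.05, 0.10,
                                              0.15, 0.20),
                              outcomes = c("bmi_z", "fmi_z", "lmi_z"),
                              a = 1, B = 0, m_boot = 2, seed = NULL) {
  stopifnot(inherits(imp, "imputation_set"), all(p_grid >= 0 & p_grid < 1))
  sig <- variance_of_parental_bmi(imp)
  rows <- list()
  for (oc in outcomes) {
    fits <- lapply(imp$tables, adjusted_fit_vcov, outcome = oc)
    est <- t(vapply(fits, `[[`, numeric(2), "beta"))
    w <- Reduce(`+`, lapply(fits, `[[`, "vcov")) / imp$m
    bmat <- stats::cov(est)
    t_mat <- w + (1 + 1 / imp$m) * bmat
    qbar <- colMeans(est)
    for (p in p_grid) {
      rows[[length(rows) + 1L]] <- tryCatch({
        a_p <- if (identical(a, "1-p")) 1 - p else a
        params <- attenuation_params(p, sig["sigma_mm"], sig["sigma_ff"],
                                     sig["sigma_fm"], a = a_p)
        bstar <- adjust_coefficients(qbar[1], qbar[2], params)
        lam <- attenuation_matrix(params)
        vstar <- lam %*% t_mat %*% t(lam)
        pval <- if (B > 0) {
          bootstrap_difference_test(imp$original, p = p, B = B, m = m_boot,
                                    seed = seed, outcome = oc, a = a_p)
        } else NA_real_
        data.frame(outcome = oc, p = p, beta_m_adj = bstar[["beta1_star"]],
                   beta_f_adj = bstar[["beta2_star"]],
                   var_m = vstar[1, 1], var_f = vstar[2, 2],
                   p_one_sided = pval)
      }, error = function(e) {
        warning("sensitivity sweep failed at (", oc, ", p = ", p, "): ",
                conditionMessage(e), call. = FALSE)
        data.frame(outcome = oc, p = p, beta_m_adj = NA_real_,
                   beta_f_adj = NA_real_, var_m = NA_real_,
                   var_f = NA_real_, p_one_sided = NA_real_)
      })
    }
  }
  do.call(rbind, rows)
}

#' Bootstrap one-sided test of the maternal-minus-paternal difference
#'
#' Resamples trios with replacement; each replicate re-imputes missing
#' paternal anthropometry (m imputations through the chained-equations
#' engine), refits the adjusted model, pools the coefficients, corrects
#' them for non-paternity at the assumed p, and records the difference
#' d = beta1* - beta2*. The one-sided p-value for the alternative
#' "maternal effect larger than paternal" is the fraction of the
#' resampling distribution consistent with the null (d <= 0), with the
#' (count + 1)/(B + 1) continuity correction. Deterministic given
#' \code{seed}. Degenerate replicates are dropped and counted; more than
#' 5% drops is an error.
#'
#' @param table analysis table (may contain missing paternal cells).
#' @param p assumed non-paternity probability.
#' @param B bootstrap replicates (>= 100).
#' @param m imputations per replicate (2 is the tractable default; the
#'   difference statistic uses pooled point estimates only).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param outcome outcome z-score column.
#' @param a indicator weight, see \code{\link{attenuation_params}}.
#' @param cycles chained-equation cycles per replicate imputation.
#' @return one-sided p-value.
#' @export
bootstrap_difference_test <- function(table, p = 0, B = 10000, m = 2,
                                      seed = NULL, outcome = "bmi_z",
                                      a = 1, cycles = 10) {
  if (B < 100) stop("need B >= 100 bootstrap replicates", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table)
  y_full <- as.numeric(table[[outcome]])
  mbmi_full <- as.numeric(table$mother_bmi)
  fw_full <- as.numeric(table$father_weight_kg)
  fh_full <- as.numeric(table$father_height_cm)
  X0_full <- predictor_matrix(table, default_predictors(table))
  d <- rep(NA_real_, B)
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      fw <- fw_full[idx]; fh <- fh_full[idx]
      miss <- list(father_weight_kg = is.na(fw),
                   father_height_cm = is.na(fh))
      y <- y_full[idx]; mb <- mbmi_full[idx]
      betas <- matrix(NA_real_, m, 2)
      sig <- matrix(NA_real_, m, 3)
      if (!any(miss$father_weight_kg) && !any(miss$father_height_cm)) {
        fb <- fw / (fh / 100)^2
        cf <- .lm.fit(cbind(1, mb, fb), y)$coefficients
        betas <- matrix(cf[2:3], m, 2, byrow = TRUE)
        sig <- matrix(c(stats::var(mb), stats::var(fb),
                        stats::cov(mb, fb)), m, 3, byrow = TRUE)
      } else {
        eng <- impute_engine(X0_full[idx, , drop = FALSE],
                             list(father_weight_kg = fw,
                                  father_height_cm = fh),
                             miss, m, cycles, log = FALSE)
        for (j in seq_len(m)) {
          fb <- eng$chains[[j]]$father_weight_kg /
            (eng$chains[[j]]$father_height_cm / 100)^2
          cf <- .lm.fit(cbind(1, mb, fb), y)$coefficients
          betas[j, ] <- cf[2:3]
          sig[j, ] <- c(stats::var(mb), stats::var(fb), stats::cov(mb, fb))
        }
      }
      qbar <- colMeans(betas)
      sbar <- colMeans(sig)
      params <- attenuation_params(p, sbar[1], sbar[2], sbar[3], a = a)
      bstar <- adjust_coefficients(qbar[1], qbar[2], params)
      bstar[["beta1_star"]] - bstar[["beta2_star"]]
    }, error = function(e) NA_real_)
    if (is.na(res) || !is.finite(res)) dropped <- dropped + 1L else d[b] <- res
  }
  if (dropped > 0.05 * B) {
    stop("bootstrap degenerate: ", dropped, " of ", B,
         " replicates dropped", call. = FALSE)
  }
  d <- d[!is.na(d)]
  (sum(d <= 0) + 1) / (length(d) + 1)
}
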