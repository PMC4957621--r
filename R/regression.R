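#' Fit one parent-offspring association model
#'
#' Ordinary least squares of an offspring z-score on parental BMI, with an
#' intercept, optionally adjusted for the other parent's BMI (the
#' assortative-mating adjustment), optionally restricted to one offspring
#' sex. Coefficients are per one kg/m^2 of the exposure; exposures are not
#' standardised. Confidence intervals use the t distribution with residual
#' degrees of freedom.
#'
#' @param table analysis table with columns \code{mother_bmi},
#'   \code{father_bmi}, \code{sex} and the outcome z-score.
#' @param outcome one of \code{"bmi_z"}, \code{"fmi_z"}, \code{"lmi_z"}.
#' @param exposure \code{"mother_bmi"} or \code{"father_bmi"}.
#' @param adjusted include the other parent's BMI as a covariate.
#' @param stratum \code{"all"}, \code{"male"} or \code{"female"}.
#' @param conf confidence level.
#' @param robust use heteroscedasticity-robust (HC3) standard errors.
#' @return one-row data.frame: \code{outcome, exposure, stratum, adjusted,
#'   beta, se, ci_low, ci_high, n, df, pooled, m}.
#' @export
fit_model <- function(table, outcome, exposure = "mother_bmi",
                      adjusted = FALSE, stratum = "all", conf = 0.95,
                      robust = FALSE) {
  stopifnot(outcome %in% names(table),
            exposure %in% c("mother_bmi", "father_bmi"),
            stratum %in% c("all", "male", "female"))
  if (stratum != "all") {
    table <- table[table$sex == ifelse(stratum == "male", "M", "F"), ,
                   drop = FALSE]
  }
  other <- setdiff(c("mother_bmi", "father_bmi"), exposure)
  vars <- c(outcome, exposure, if (adjusted) other)
  keep <- stats::complete.cases(table[, vars, drop = FALSE])
  table <- table[keep, , drop = FALSE]
  n <- nrow(table)
  k <- 2L + adjusted
  if (n <= k) stop("too few complete rows (", n, ") for the model",
                   call. = FALSE)
  fml <- stats::reformulate(c(exposure, if (adjusted) other),
                            response = outcome)
  fit <- stats::lm(fml, data = table)
  if (fit$rank < k) stop("singular design: rank-deficient model matrix",
                         call. = FALSE)
  vc <- if (robust) robust_vcov_hc3(fit) else stats::vcov(fit)
  beta <- stats::coef(fit)[[exposure]]
  se <- sqrt(vc[exposure, exposure])
  df <- fit$df.residual
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  data.frame(outcome = outcome, exposure = exposure, stratum = stratum,
             adjusted = adjusted, beta = beta, se = se,
             ci_low = beta - tq * se, ci_high = beta + tq * se,
             n = n, df = df, pooled = FALSE, m = NA_integer_,
             row.names = NULL)
}

# HC3 sandwich covariance, written out so the flag has no extra dependency
robust_vcov_hc3 <- function(fit) {
  X <- stats::model.matrix(fit)
  h <- stats::hatvalues(fit)
  u <- stats::residuals(fit) / (1 - h)
  bread <- chol2inv(qr.R(fit$qr))
  meat <- crossprod(X * u)
  vc <- bread %*% meat %*% bread
  dimnames(vc) <- list(colnames(X), colnames(X))
  vc
}

#' Fit the full grid of parent-offspring association models
#'
#' Enumerates all cells of the association table: 3 outcomes (BMI, FMI, LMI
#' z-scores) x 2 exposures (maternal, paternal BMI) x unadjusted/adjusted x
#' 3 strata (all, female, male offspring) = 36 fits. Given a single
#' complete-case table the cells are plain OLS fits; given an
#' \code{\link{mice_impute}} result each cell is fitted on every completed
#' table and pooled by Rubin's rules with Barnard-Rubin degrees of freedom.
#' Per-cell failures are flagged (row of NAs) without aborting the grid.
#'
#' @param x analysis table or an \code{imputation_set}.
#' @param conf confidence level.
#' @param robust passed to \code{\link{fit_model}}.
#' @return data.frame of 36 fit rows.
#' @export
fit_grid <- function(x, conf = 0.95, robust = FALSE) {
  cells <- expand.grid(outcome = c("bmi_z", "fmi_z", "lmi_z"),
                       exposure = c("mother_bmi", "father_bmi"),
                       adjusted = c(FALSE, TRUE),
                       stratum = c("all", "female", "male"),
                       stringsAsFactors = FALSE)
  pooled <- inherits(x, "imputation_set")
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    rows[[i]] <- tryCatch({
      if (!pooled) {
        fit_model(x, cl$outcome, cl$exposure, cl$adjusted, cl$stratum,
                  conf = conf, robust = robust)
      } else {
        fits <- lapply(x$tables, fit_model, outcome = cl$outcome,
                       exposure = cl$exposure, adjusted = cl$adjusted,
                       stratum = cl$stratum, conf = conf, robust = robust)
        est <- vapply(fits, `[[`, numeric(1), "beta")
        v <- vapply(fits, `[[`, numeric(1), "se")^2
        pr <- pool_rubin(est, v, dfcom = fits[[1]]$df, conf = conf)
        data.frame(outcome = cl$outcome, exposure = cl$exposure,
                   stratum = cl$stratum, adjusted = cl$adjusted,
                   beta = pr$estimate, se = sqrt(pr$total_var),
                   ci_low = pr$ci_low, ci_high = pr$ci_high,
                   n = fits[[1]]$n, df = pr$df, pooled = TRUE,
                   m = x$m, row.names = NULL)
      }
    }, error = function(e) {
      data.frame(outcome = cl$outcome, exposure = cl$exposure,
                 stratum = cl$stratum, adjusted = cl$adjusted,
                 beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, n = NA_integer_, df = NA_real_,
                 pooled = pooled, m = if (pooled) x$m else NA_integer_,
                 row.names = NULL)
    })
  }
  out <- do.call(rbind, rows)
  if (anyNA(out$beta)) {
    warning(sum(is.na(out$beta)), " grid cell(s) failed to fit",
            call. = FALSE)
  }
  out
}

#' Variance inflation factor of a two-predictor model
#'
#' For a linear model with two predictors whose sample correlation is r,
#' both predictors share the collinearity diagnostic
#' \deqn{VIF = 1 / (1 - r^2).}
#'
#' @param r correlation between the two predictors, |r| < 1.
#' @return the variance inflation factor.
#' @export
vif_two_predictor <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  1 / (1 - r^2)
}

#' Pearson correlation between maternal and paternal BMI
#'
#' @param table analysis table with \code{mother_bmi}, \code{father_bmi};
#'   incomplete pairs are dropped.
#' @return list with \code{r}, \code{p_value} and \code{n} (complete pairs).
#' @export
parent_correlation <- function(table) {
  keep <- stats::complete.cases(table[, c("mother_bmi", "father_bmi")])
  if (sum(keep) < 3) stop("need at least 3 complete parent pairs",
                          call. = FALSE)
  ct <- stats::cor.test(table$mother_bmi[keep], table$father_bmi[keep],
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}
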