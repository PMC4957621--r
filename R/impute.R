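# Chained-equations imputation of paternal anthropometry.
#
# The elementary imputation method is Bayesian normal-linear regression:
# for each incomplete variable, draw the residual variance from its scaled
# inverse-chi-square posterior, draw coefficients from their normal
# posterior given that variance, and impute from the posterior predictive.
# Father weight and height are imputed on the raw scale (BMI is derived
# afterwards), keeping completed tables in the trio CSV schema.

default_predictors <- function(table) {
  cand <- c("mother_bmi", "bmi_z", "fmi_z", "lmi_z", "age_y", "sex")
  missing_cols <- setdiff(cand, names(table))
  if (length(missing_cols)) {
    stop("imputation predictors absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cand
}

# numeric predictor matrix (with intercept); sex coded M = 1
predictor_matrix <- function(table, predictors) {
  cols <- lapply(predictors, function(p) {
    v <- table[[p]]
    if (p == "sex") as.numeric(v == "M") else as.numeric(v)
  })
  X <- do.call(cbind, cols)
  if (anyNA(X)) {
    stop("imputation predictors must be fully observed", call. = FALSE)
  }
  cbind(1, X)
}

# one Bayesian normal-linear imputation of y[miss] given X
draw_imputation <- function(X_obs, y_obs, X_mis) {
  qr_ <- qr(X_obs)
  if (qr_$rank < ncol(X_obs)) {
    stop("unimputable: rank-deficient imputation model", call. = FALSE)
  }
  betahat <- qr.coef(qr_, y_obs)
  res <- y_obs - X_obs %*% betahat
  df <- length(y_obs) - ncol(X_obs)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qr_)
  # beta | sigma2 ~ N(betahat, sigma2 (X'X)^-1); X'X = R'R
  beta <- betahat + backsolve(R, stats::rnorm(ncol(X_obs))) * sqrt(sigma2)
  drop(X_mis %*% beta) + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

# core chained-equations engine: returns list of m lists of imputed vectors
# (one per incomplete variable) plus a per-cycle convergence log
impute_engine <- function(X0, targets, miss, m, cycles, log = TRUE) {
  vars <- names(targets)
  out <- vector("list", m)
  log_rows <- list()
  for (chain in seq_len(m)) {
    filled <- lapply(vars, function(v) {
      y <- targets[[v]]
      y[miss[[v]]] <- mean(y[!miss[[v]]])
      y
    })
    names(filled) <- vars
    for (cyc in seq_len(cycles)) {
      for (v in vars) {
        if (!any(miss[[v]])) next
        others <- setdiff(vars, v)
        X <- cbind(X0, do.call(cbind, filled[others]))
        y <- targets[[v]]
        obs <- !miss[[v]]
        filled[[v]][!obs] <- draw_imputation(X[obs, , drop = FALSE], y[obs],
                                             X[!obs, , drop = FALSE])
      }
      if (log) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          chain = chain, cycle = cyc,
          t(vapply(vars, function(v) mean(filled[[v]][miss[[v]]]),
                   numeric(1))))
      }
    }
    out[[chain]] <- filled
  }
  list(chains = out,
       log = if (length(log_rows)) do.call(rbind, log_rows) else NULL)
}

#' Multiple imputation by chained equations for paternal anthropometry
#'
#' Imputes missing \code{father_weight_kg} and \code{father_height_cm} by
#' chained Bayesian normal-linear regressions. Predictors are the mother's
#' BMI, the offspring outcome z-scores, offspring age and sex, plus the
#' other paternal variable through the chaining. Runs a fixed number of
#' burn-in cycles per chain and returns m completed tables; with no missing
#' cells the result is m identical copies of the input. Deterministic given
#' \code{seed}.
#'
#' @param table analysis table (see \code{\link{build_analysis_table}});
#'   missingness must be confined to the paternal columns.
#' @param m number of imputations (>= 2).
#' @param seed integer seed; \code{NULL} to use the current RNG state.
#' @param cycles chained-equation burn-in cycles.
#' @return object of class \code{imputation_set}: list with \code{m},
#'   \code{tables} (completed tables with \code{father_bmi} recomputed),
#'   \code{seed}, \code{model_spec}, \code{convergence} (per-cycle means of
#'   imputed values) and \code{original} (the input table).
#' @export
mice_impute <- function(table, m = 10, seed = NULL, cycles = 10) {
  m <- as.integer(m)
  if (m < 2) stop("need m >= 2 imputations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  targets <- list(father_weight_kg = as.numeric(table$father_weight_kg),
                  father_height_cm = as.numeric(table$father_height_cm))
  miss <- lapply(targets, is.na)
  predictors <- default_predictors(table)
  other_na <- setdiff(names(table)[vapply(table, anyNA, logical(1))],
                      c(names(targets), "father_bmi"))
  if (length(other_na)) {
    stop("missingness outside paternal anthropometry: ",
         paste(other_na, collapse = ", "), call. = FALSE)
  }
  n_complete <- sum(!miss$father_weight_kg & !miss$father_height_cm)
  if (any(vapply(miss, any, logical(1))) && n_complete < 30) {
    stop("need at least 30 complete cases to fit the imputation models",
         call. = FALSE)
  }
  model_spec <- list(
    imputed = names(targets),
    predictors = c(predictors, "other paternal variable (chained)"),
    method = "bayesian normal-linear regression", cycles = cycles)

  if (!any(unlist(miss))) {
    tables <- replicate(m, recompute_father_bmi(table), simplify = FALSE)
    res <- list(m = m, tables = tables, seed = seed,
                model_spec = model_spec, convergence = NULL,
                original = table)
    class(res) <- "imputation_set"
    return(res)
  }
  X0 <- predictor_matrix(table, predictors)
  eng <- impute_engine(X0, targets, miss, m, cycles)
  tables <- lapply(eng$chains, function(filled) {
    tb <- table
    tb$father_weight_kg <- filled$father_weight_kg
    tb$father_height_cm <- filled$father_height_cm
    recompute_father_bmi(tb)
  })
  res <- list(m = m, tables = tables, seed = seed, model_spec = model_spec,
              convergence = eng$log, original = table)
  class(res) <- "imputation_set"
  res
}

recompute_father_bmi <- function(table) {
  table$father_bmi <- table$father_weight_kg /
    (table$father_height_cm / 100)^2
  table
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; its
#' variance combines the mean within-imputation variance W and the
#' between-imputation variance B as \eqn{T = W + (1 + 1/m) B}. Confidence
#' intervals use the t distribution with Barnard-Rubin small-sample degrees
#' of freedom (reducing to the classical large-sample formula as
#' \code{dfcom} tends to infinity).
#'
#' @param estimates per-imputation point estimates (length m >= 2).
#' @param variances per-imputation squared standard errors.
#' @param dfcom complete-data residual degrees of freedom.
#' @param conf confidence level.
#' @return list: \code{estimate, within_var, between_var, total_var, df,
#'   ci_low, ci_high}.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf, conf = 0.95) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m) {
    stop("need >= 2 (estimate, variance) pairs", call. = FALSE)
  }
  if (any(variances <= 0)) stop("variances must be positive", call. = FALSE)
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  t_var <- w + (1 + 1 / m) * b
  if (b > 0) {
    lambda <- (1 + 1 / m) * b / t_var
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- dfcom * (dfcom + 1) / (dfcom + 3) * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    } else {
      df <- df_old
    }
  } else {
    df <- if (is.finite(dfcom)) dfcom else Inf
  }
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  list(estimate = qbar, within_var = w, between_var = b, total_var = t_var,
       df = df, ci_low = qbar - tq * sqrt(t_var),
       ci_high = qbar + tq * sqrt(t_var))
}

#' MCAR diagnostics: response t-tests against missingness indicators
#'
#' For every (response, explanatory) pair, compares the response between
#' rows where the explanatory variable is missing and rows where it is
#' observed with a Welch two-sample t-test. Under data missing completely
#' at random the p-values are approximately uniform. Pairs where either
#' group has fewer than 2 rows are flagged not-applicable rather than
#' raising an error; with no missing rows at all the result is empty.
#'
#' @param table analysis table.
#' @param responses response (outcome z-score) column names.
#' @param explanatory explanatory variable column names to scan for
#'   missingness.
#' @return data.frame: \code{response, explanatory, n_missing, n_observed,
#'   p_value, applicable}.
#' @export
mcar_check <- function(table, responses = c("bmi_z", "fmi_z", "lmi_z"),
                       explanatory = c("mother_bmi", "father_bmi")) {
  rows <- list()
  for (ex in explanatory) {
    mis <- is.na(table[[ex]])
    if (!any(mis)) next
    for (resp in responses) {
      y <- table[[resp]]
      n1 <- sum(mis & !is.na(y)); n0 <- sum(!mis & !is.na(y))
      applicable <- n1 >= 2 && n0 >= 2
      p <- if (applicable) {
        stats::t.test(y[mis], y[!mis])$p.value
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, explanatory = ex, n_missing = n1, n_observed = n0,
        p_value = p, applicable = applicable)
    }
  }
  if (!length(rows)) {
    return(data.frame(response = character(0), explanatory = character(0),
                      n_missing = integer(0), n_observed = integer(0),
                      p_value = numeric(0), applicable = logical(0)))
  }
  do.call(rbind, rows)
}
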