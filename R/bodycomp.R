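#' Fat mass from the four-component model
#'
#' Combines body volume (air-displacement plethysmography), total body water
#' (deuterium dilution), bone mineral content (DXA) and body weight into a
#' fat-mass estimate using the four-component (4C) model, the in vivo
#' gold standard for paediatric body composition:
#' \deqn{FM = 2.747 \cdot BV - 0.710 \cdot TBW + 1.460 \cdot BMC - 2.050 \cdot W}
#'
#' The 4C equation can legitimately return a fat mass below zero or above
#' body weight on noisy inputs; such values are flagged with a warning and
#' propagated unchanged. Clamping would bias any downstream regression.
#'
#' @param body_volume body volume in litres.
#' @param total_body_water total body water in kg.
#' @param bone_mineral_content bone mineral content in kg.
#' @param weight body weight in kg.
#' @return Fat mass in kg (vectorised).
#' @export
compute_fat_mass <- function(body_volume, total_body_water,
                             bone_mineral_content, weight) {
  for (nm in c("body_volume", "total_body_water", "bone_mineral_content",
               "weight")) {
    v <- get(nm, inherits = FALSE)
    if (is.null(v) || length(v) == 0L || anyNA(v)) {
      stop("measurement incomplete: missing value in '", nm, "'",
           call. = FALSE)
    }
  }
  fm <- 2.747 * body_volume - 0.710 * total_body_water +
    1.460 * bone_mineral_content - 2.050 * weight
  if (any(fm < 0)) {
    warning(sum(fm < 0), " subject(s) with negative 4C fat mass; ",
            "values propagated unclamped", call. = FALSE)
  }
  if (any(fm > weight)) {
    warning(sum(fm > weight), " subject(s) with 4C fat mass above body ",
            "weight; values propagated unclamped", call. = FALSE)
  }
  fm
}

#' Lean mass as the 4C complement of fat mass
#'
#' @param weight body weight in kg.
#' @param fat_mass fat mass in kg.
#' @return Lean mass in kg, \code{weight - fat_mass}.
#' @export
compute_lean_mass <- function(weight, fat_mass) {
  if (anyNA(weight) || anyNA(fat_mass)) {
    stop("measurement incomplete: weight and fat_mass must be observed",
         call. = FALSE)
  }
  weight - fat_mass
}

#' Body-composition indices (BMI, FMI, LMI)
#'
#' Normalises weight, fat mass and lean mass by squared height (in metres).
#' Because lean mass is the complement of fat mass, the fat mass index and
#' lean mass index sum to BMI by construction.
#'
#' Height is accepted in cm (the storage unit throughout the package) and
#' converted to metres here, at a single point, to avoid unit drift.
#'
#' @param weight kg. @param height cm.
#' @param fat_mass kg. @param lean_mass kg.
#' @param tol relative tolerance for the mass-balance check.
#' @return data.frame with columns \code{bmi}, \code{fmi}, \code{lmi}
#'   (kg/m^2).
#' @export
compute_indices <- function(weight, height, fat_mass, lean_mass,
                            tol = 1e-8) {
  if (any(height <= 0)) stop("height must be positive", call. = FALSE)
  if (any(weight <= 0)) stop("weight must be positive", call. = FALSE)
  imbalance <- abs(fat_mass + lean_mass - weight) / pmax(weight, 1)
  if (any(imbalance > tol)) {
    stop("mass balance violated: fat_mass + lean_mass differs from weight",
         call. = FALSE)
  }
  h2 <- (height / 100)^2
  data.frame(bmi = weight / h2, fmi = fat_mass / h2, lmi = lean_mass / h2)
}

#' LMS z-score
#'
#' Converts a measurement to an age/sex-standardised z-score given the LMS
#' parameters of the reference at that age: skewness (L, Box-Cox power),
#' median (M) and coefficient of variation (S).
#' \deqn{z = ((x/M)^L - 1) / (L S)} with the limit \eqn{z = \ln(x/M)/S}
#' as \eqn{L \to 0} (taken when |L| < 1e-7).
#'
#' @param x measurement, same units as M; must be positive.
#' @param l,m,s LMS parameters (M > 0, S > 0).
#' @return z-score (vectorised).
#' @export
lms_zscore <- function(x, l, m, s) {
  if (any(x <= 0)) stop("LMS z-score needs a positive measurement",
                        call. = FALSE)
  if (any(m <= 0) || any(s <= 0)) {
    stop("LMS parameters need M > 0 and S > 0", call. = FALSE)
  }
  n <- max(length(x), length(l), length(m), length(s))
  x <- rep_len(x, n); l <- rep_len(l, n)
  m <- rep_len(m, n); s <- rep_len(s, n)
  z <- numeric(n)
  log_branch <- abs(l) < 1e-7
  z[log_branch] <- log(x[log_branch] / m[log_branch]) / s[log_branch]
  lb <- l[!log_branch]
  z[!log_branch] <- ((x[!log_branch] / m[!log_branch])^lb - 1) /
    (lb * s[!log_branch])
  z
}

#' Inverse LMS transform
#'
#' Maps a z-score back to measurement units; the exact inverse of
#' \code{\link{lms_zscore}}, used by the synthetic generator to construct
#' raw measurements with a prescribed z-score.
#'
#' @param z z-score. @param l,m,s LMS parameters.
#' @return Measurement in the reference's units; \code{NA} where
#'   \code{1 + L*S*z <= 0} (outside the Box-Cox domain).
#' @export
lms_inverse <- function(z, l, m, s) {
  if (any(m <= 0) || any(s <= 0)) {
    stop("LMS parameters need M > 0 and S > 0", call. = FALSE)
  }
  n <- max(length(z), length(l), length(m), length(s))
  z <- rep_len(z, n); l <- rep_len(l, n)
  m <- rep_len(m, n); s <- rep_len(s, n)
  x <- numeric(n)
  log_branch <- abs(l) < 1e-7
  x[log_branch] <- m[log_branch] * exp(s[log_branch] * z[log_branch])
  base <- 1 + l[!log_branch] * s[!log_branch] * z[!log_branch]
  xn <- rep(NA_real_, sum(!log_branch))
  ok <- base > 0
  xn[ok] <- m[!log_branch][ok] * base[ok]^(1 / l[!log_branch][ok])
  x[!log_branch] <- xn
  x
}

#' Interpolate an LMS reference at a given sex and age
#'
#' Linear interpolation in age, component-wise on (L, M, S), between the
#' bracketing reference rows. An age on a grid point returns that row
#' verbatim. No extrapolation: ages outside the reference span are an
#' error unless \code{cap_age} is set, in which case ages beyond the last
#' grid age are evaluated at the last grid age (the convention of using the
#' oldest reference band for slightly older subjects).
#'
#' @param ref LMS reference data.frame with columns
#'   \code{measure, sex, age_y, L, M, S}.
#' @param measure one of \code{"bmi"}, \code{"fmi"}, \code{"lmi"}.
#' @param sex \code{"M"} or \code{"F"} (vectorised with \code{age}).
#' @param age age in years (vectorised).
#' @param cap_age if TRUE, ages above the oldest reference age are capped
#'   to it instead of erroring. Default FALSE.
#' @return data.frame with columns \code{L}, \code{M}, \code{S}.
#' @export
lookup_lms <- function(ref, measure, sex, age, cap_age = FALSE) {
  stopifnot(all(c("measure", "sex", "age_y", "L", "M", "S") %in% names(ref)))
  n <- max(length(sex), length(age))
  sex <- rep_len(as.character(sex), n)
  age <- rep_len(age, n)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "M", "S")))
  for (sx in unique(sex)) {
    sub <- ref[ref$measure == measure & ref$sex == sx, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no LMS reference rows for measure '", measure, "', sex '",
           sx, "'", call. = FALSE)
    }
    sub <- sub[order(sub$age_y), , drop = FALSE]
    if (is.unsorted(sub$age_y, strictly = TRUE)) {
      stop("LMS reference ages must be strictly increasing within (measure,",
           " sex)", call. = FALSE)
    }
    idx <- which(sex == sx)
    a <- age[idx]
    if (cap_age) a <- pmin(a, max(sub$age_y))
    bad <- a < min(sub$age_y) | a > max(sub$age_y)
    if (any(bad)) {
      stop("age(s) ", paste(signif(age[idx][bad], 4), collapse = ", "),
           " outside LMS reference span [", min(sub$age_y), ", ",
           max(sub$age_y), "] for ", measure, "/", sx, call. = FALSE)
    }
    for (comp in c("L", "M", "S")) {
      out[idx, comp] <- stats::approx(sub$age_y, sub[[comp]], xout = a,
                                      method = "linear", ties = "ordered")$y
    }
  }
  as.data.frame(out)
}

#' Z-score a table of trio measurements
#'
#' Runs the 4C equations and LMS standardisation over a trio table: fat and
#' lean mass from raw inputs, BMI/FMI/LMI, then age- and sex-specific
#' z-scores for all three indices.
#'
#' @param trios trio data.frame in the package CSV dialect (see
#'   \code{\link{read_trios}}); needs \code{subject_id, sex, age_y,
#'   weight_kg, height_cm, bv_l, tbw_kg, bmc_kg}.
#' @param ref LMS reference data.frame covering both sexes and all ages for
#'   the three measures.
#' @param cap_age passed to \code{\link{lookup_lms}}.
#' @return data.frame with \code{subject_id, sex, age_y, fat_mass_kg,
#'   lean_mass_kg, bmi, fmi, lmi, bmi_z, fmi_z, lmi_z}.
#' @export
zscore_table <- function(trios, ref, cap_age = FALSE) {
  need <- c("subject_id", "sex", "age_y", "weight_kg", "height_cm",
            "bv_l", "tbw_kg", "bmc_kg")
  missing_cols <- setdiff(need, names(trios))
  if (length(missing_cols)) {
    stop("trio table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fm <- compute_fat_mass(trios$bv_l, trios$tbw_kg, trios$bmc_kg,
                         trios$weight_kg)
  lm_ <- compute_lean_mass(trios$weight_kg, fm)
  idx <- compute_indices(trios$weight_kg, trios$height_cm, fm, lm_)
  out <- data.frame(subject_id = trios$subject_id, sex = trios$sex,
                    age_y = trios$age_y, fat_mass_kg = fm,
                    lean_mass_kg = lm_, idx)
  failures <- character(0)
  for (measure in c("bmi", "fmi", "lmi")) {
    lms <- tryCatch(
      lookup_lms(ref, measure, trios$sex, trios$age_y, cap_age = cap_age),
      error = function(e) e)
    if (inherits(lms, "error")) {
      failures <- c(failures, paste0(measure, ": ", conditionMessage(lms)))
      next
    }
    x <- out[[measure]]
    if (any(x <= 0)) {
      bad <- trios$subject_id[x <= 0]
      failures <- c(failures, paste0(
        measure, ": non-positive index for subject(s) ",
        paste(utils::head(bad, 5), collapse = ", ")))
      next
    }
    out[[paste0(measure, "_z")]] <- lms_zscore(x, lms$L, lms$M, lms$S)
  }
  if (length(failures)) {
    stop("z-scoring failed:\n  ", paste(failures, collapse = "\n  "),
         call. = FALSE)
  }
  big <- abs(out$bmi_z) >= 8 | abs(out$fmi_z) >= 8 | abs(out$lmi_z) >= 8
  if (any(big)) {
    warning(sum(big), " subject(s) with |z| >= 8; check inputs and ",
            "reference coverage", call. = FALSE)
  }
  out
}

#' Synthetic LMS reference tables
#'
#' Builds a smooth, plausible LMS reference for BMI, FMI and LMI by sex over
#' ages 5-22. This is a synthetic stand-in with the same CSV schema as the
#' real (licensed, non-redistributable) British 1990 BMI and UK
#' body-composition references; to use real tables, write them to the same
#' schema (\code{measure, sex, age_y, L, M, S}) and pass them wherever an
#' LMS reference is accepted. Medians follow logistic growth curves with
#' higher fat-mass medians in girls; LMI medians are the BMI minus FMI
#' medians so that typical realised values sit near the reference centre.
#'
#' @param ages grid of reference ages in years.
#' @return LMS reference data.frame (\code{measure, sex, age_y, L, M, S}).
#' @export
synthetic_lms_reference <- function(ages = seq(5, 22, by = 0.5)) {
  grid <- expand.grid(sex = c("M", "F"), age_y = ages,
                      stringsAsFactors = FALSE)
  a <- grid$age_y
  female <- grid$sex == "F"
  # BMI median rises from ~15.5 to ~22.5 kg/m^2 across childhood
  m_bmi <- 15.2 + 7.4 / (1 + exp(-(a - 13.2) / 3.1)) + 0.25 * female
  l_bmi <- -0.5
  s_bmi <- 0.115 + 0.004 * female
  # FMI: girls carry more fat mass; wide lognormal spread (L = 0)
  m_fmi <- (0.20 + 0.05 * female) * m_bmi
  l_fmi <- 0
  s_fmi <- 0.38 + 0.02 * female
  # LMI median is the BMI-FMI complement so realised values centre well
  m_lmi <- m_bmi - m_fmi
  l_lmi <- 0
  s_lmi <- 0.11
  rbind(
    data.frame(measure = "bmi", sex = grid$sex, age_y = a,
               L = l_bmi, M = m_bmi, S = s_bmi),
    data.frame(measure = "fmi", sex = grid$sex, age_y = a,
               L = l_fmi, M = m_fmi, S = s_fmi),
    data.frame(measure = "lmi", sex = grid$sex, age_y = a,
               L = l_lmi, M = m_lmi, S = s_lmi)
  )
}

#' Read / write an LMS reference CSV
#'
#' @param path CSV file with header \code{measure, sex, age_y, L, M, S}.
#' @return data.frame in the LMS reference schema.
#' @export
read_lms_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measure", "sex", "age_y", "L", "M", "S")
  if (!all(need %in% names(ref))) {
    stop("LMS reference CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    stop("LMS reference needs M > 0 and S > 0", call. = FALSE)
  }
  ref
}

#' @rdname read_lms_reference
#' @param ref LMS reference data.frame.
#' @export
write_lms_reference <- function(ref, path) {
  utils::write.csv(ref, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
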