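#' Build the analysis table from raw trio measurements
#'
#' Runs the body-composition and z-scoring stages and attaches parental BMI
#' (derived from reported weights and heights; NA where paternal data are
#' missing). The result is the table every downstream stage (imputation,
#' regression, sensitivity) operates on.
#'
#' @param trios raw trio table (see \code{\link{read_trios}}).
#' @param ref LMS reference.
#' @param cap_age passed to \code{\link{lookup_lms}}.
#' @return analysis data.frame: z-scored outcomes plus parental columns.
#' @export
build_analysis_table <- function(trios, ref = synthetic_lms_reference(),
                                 cap_age = FALSE) {
  z <- zscore_table(trios, ref, cap_age = cap_age)
  keep <- c("mother_weight_kg", "mother_height_cm", "father_weight_kg",
            "father_height_cm")
  keep <- intersect(keep, names(trios))
  out <- cbind(z, trios[, keep, drop = FALSE],
               weight_kg = trios$weight_kg, height_cm = trios$height_cm)
  add_parent_bmi(out)
}

#' Descriptive statistics table (participant characteristics)
#'
#' Per-sex n, mean, SD, minimum and maximum for offspring age, weight,
#' height, BMI, fat mass, lean mass and the three index z-scores; parental
#' BMI additionally carries quintile boundaries (linear interpolation of
#' order statistics, \code{stats::quantile} type 7).
#'
#' @param analysis analysis table from \code{\link{build_analysis_table}}.
#' @return data.frame: \code{sex, variable, n, mean, sd, min, q20, q40,
#'   q60, q80, max}.
#' @export
make_table1 <- function(analysis) {
  vars <- c(age_y = "age_y", weight_kg = "weight_kg",
            height_cm = "height_cm", bmi = "bmi",
            fat_mass_kg = "fat_mass_kg", lean_mass_kg = "lean_mass_kg",
            bmi_z = "bmi_z", fmi_z = "fmi_z", lmi_z = "lmi_z",
            mother_bmi = "mother_bmi", father_bmi = "father_bmi")
  quintile_vars <- c("mother_bmi", "father_bmi")
  rows <- list()
  for (sx in c("M", "F")) {
    sub <- analysis[analysis$sex == sx, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (v in vars) {
      x <- sub[[v]]
      x <- x[!is.na(x)]
      if (length(x) == 0L) next
      qs <- if (v %in% quintile_vars && length(x) >= 5) {
        stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
      } else rep(NA_real_, 4)
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sx, variable = v, n = length(x), mean = mean(x),
        sd = stats::sd(x), min = min(x), q20 = qs[1], q40 = qs[2],
        q60 = qs[3], q80 = qs[4], max = max(x))
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' simulate -> body composition -> z-scores -> MCAR checks -> multiple
#' imputation -> association grid -> non-paternity sensitivity sweep, with
#' all reports written under \code{out_dir}: \code{trios.csv},
#' \code{truth.csv}, \code{lms_reference.csv}, \code{descriptives.csv}
#' (participant-characteristics shape), \code{mcar_checks.csv},
#' \code{results.csv} (association-grid shape), \code{sens.csv}
#' (sensitivity-table shape) and \code{manifest.json}. Rerunning with the
#' same config yields byte-identical CSV outputs.
#'
#' @param config a \code{\link{trio_config}}.
#' @param out_dir output directory (created if absent).
#' @param m imputations for the main association grid.
#' @param p_grid non-paternity probabilities for the sensitivity sweep.
#' @param B bootstrap replicates per sweep point (0 skips the test).
#' @param m_boot imputations per bootstrap replicate.
#' @param verbose log per-stage lines to stderr.
#' @return invisibly, the run manifest (also written as JSON).
#' @export
run_pipeline <- function(config = trio_config(), out_dir = "pipeline_out",
                         m = 10, p_grid = c(0, 0.01, 0.02, 0.05, 0.10,
                                            0.15, 0.20),
                         B = 0, m_boot = 2, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_all <- list()
  say <- function(stage, t0, extra = "") {
    el <- round(as.numeric(Sys.time()) - t0, 2)
    t_all[[stage]] <<- el
    if (verbose) {
      message(sprintf("[%s] seed=%d n=%d elapsed=%.2fs %s", stage,
                      config$seed, config$n_trios, el, extra))
    }
  }
  paths <- list()
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE, na = "")
    paths[[name]] <<- p
    p
  }

  t0 <- as.numeric(Sys.time())
  sim <- simulate_trios(config)
  wr(sim$trios, "trios.csv")
  write_truth(sim$truth, config, file.path(out_dir, "truth.csv"))
  paths[["truth.csv"]] <- file.path(out_dir, "truth.csv")
  wr(sim$ref, "lms_reference.csv")
  say("simulate", t0)

  t0 <- as.numeric(Sys.time())
  analysis <- build_analysis_table(sim$trios, sim$ref)
  wr(make_table1(analysis), "descriptives.csv")
  say("descriptives", t0)

  t0 <- as.numeric(Sys.time())
  wr(mcar_check(analysis), "mcar_checks.csv")
  say("mcar", t0)

  t0 <- as.numeric(Sys.time())
  imp <- mice_impute(analysis, m = m, seed = config$seed + 1L)
  say("impute", t0, sprintf("m=%d", m))

  t0 <- as.numeric(Sys.time())
  grid <- fit_grid(imp)
  wr(grid, "results.csv")
  say("fit", t0)

  t0 <- as.numeric(Sys.time())
  sens <- sensitivity_sweep(imp, p_grid = p_grid, B = B, m_boot = m_boot,
                            seed = config$seed + 2L)
  wr(sens, "sens.csv")
  say("sensitivity", t0, sprintf("B=%d", B))

  csvs <- unlist(paths)
  manifest <- list(
    package_version = as.character(utils::packageVersion("triocomp")),
    config = Filter(function(x) is.atomic(x), unclass(config)),
    seeds = list(simulate = config$seed, impute = config$seed + 1L,
                 bootstrap = config$seed + 2L),
    quantile_rule = "linear interpolation of order statistics (type 7)",
    outputs = as.list(csvs),
    checksums = as.list(tools::md5sum(csvs)),
    elapsed_s = t_all)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  empty <- csvs[file.size(csvs) == 0]
  if (length(empty)) stop("empty output file(s): ",
                          paste(names(empty), collapse = ", "),
                          call. = FALSE)
  invisible(manifest)
}
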