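## End-to-end analysis pipeline -----------------------------------------------

#' Configuration of a full analysis run
#'
#' Either a simulated cohort (via `cohort`) or existing landmark CSVs
#' (via `landmarks_csv`, optionally with NIfTI airway grids in
#' `grids_dir`, one `<subject_id>.nii.gz` per subject) can be analysed.
#' All randomness derives from the single root `seed`.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Root seed.
#' @param cohort A [cohort_spec()] (used when `landmarks_csv` is NULL).
#' @param landmarks_csv Path to a raw-frame landmark CSV.
#' @param grids_dir Optional directory of NIfTI airway grids.
#' @param sr A [sr_config()] template; its `target` is ignored, both
#'   `Vol` and `CSAmin` experiments are run for targets listed in
#'   `sr_targets`.
#' @param sr_targets Character vector of SR targets (default both).
#' @param repeat_sd Placement SD (mm) for the simulated repeat session
#'   driving the ICC table; `NA` disables it.
#' @param use_grids Measure Vol/CSAmin from voxel grids instead of the
#'   generator's analytic truth (simulated cohorts only; slower).
#' @param plots Write PNG figures.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, cohort = cohort_spec(seed = seed),
                       landmarks_csv = NULL, grids_dir = NULL,
                       sr = sr_config(target = "Vol", seed = seed),
                       sr_targets = c("Vol", "CSAmin"),
                       repeat_sd = 0.5, use_grids = FALSE, plots = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 landmarks_csv = landmarks_csv, grids_dir = grids_dir,
                 sr = sr, sr_targets = sr_targets, repeat_sd = repeat_sd,
                 use_grids = use_grids, plots = plots),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> reorient -> measure -> airway -> statistics ->
#' symbolic regression -> report. Writes, under `config$out_dir`:
#' `measures.csv`, `descriptives.csv`, `icc.csv` (when a repeat session
#' exists), `kendall_tau.csv` / `kendall_p.csv`, `pca_variance.csv` /
#' `pca_coords.csv`, per-target `sr_importance_*.csv` /
#' `sr_sensitivity_*.csv`, a `manifest.json` with seeds and versions, and
#' (optionally) plot PNGs. Stage failures are re-thrown with the stage
#' name; artifacts written before the failure are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results: `measures`,
#'   `descriptives`, `icc`, `kendall`, `pca`, `sr` (per target),
#'   `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  set.seed(config$seed)
  seeds <- list(cohort = config$cohort$seed, repeat_session =
                  sample.int(.Machine$integer.max - 1L, 1),
                sr = config$sr$seed)

  ## --- acquire measurement table -------------------------------------------
  icc <- NULL
  if (is.null(config$landmarks_csv)) {
    cohort <- stage("simulate", generate_cohort(config$cohort))
    meas <- stage("measure",
                  cohort_measure_table(cohort, from_grids = config$use_grids))
    stage("io", write_landmarks(lapply(cohort, `[[`, "landmarks_raw"),
                                out("landmarks_raw.csv")))
    if (!is.na(config$repeat_sd)) {
      icc <- stage("icc", {
        s2 <- lapply(seq_along(cohort), function(i) {
          lms <- generate_repeat_session(cohort[[i]], config$repeat_sd,
                                         seed = seeds$repeat_session + i)
          apply_transform(lms, compute_reorientation(lms))
        })
        t2 <- measure_table(s2)
        shared <- intersect(measure_names(), names(t2))
        icc_table(meas[shared], t2[shared])
      })
    }
  } else {
    raw <- stage("load", read_landmarks(config$landmarks_csv))
    reo <- stage("reorient", lapply(raw, function(l)
      apply_transform(l, compute_reorientation(l))))
    meas <- stage("measure", measure_table(reo, allow_missing = TRUE))
    if (!is.null(config$grids_dir)) {
      meas <- stage("airway", {
        am <- t(vapply(names(reo), function(id) {
          f <- file.path(config$grids_dir, paste0(id, ".nii.gz"))
          if (!file.exists(f))
            f <- file.path(config$grids_dir, paste0(id, ".nii"))
          g <- read_grid_nifti(f)
          airway_metrics(g, reo[[id]])[c("Vol", "CSAmin", "Ap", "Lat")]
        }, numeric(4)))
        cbind(meas, as.data.frame(am))
      })
    }
  }
  dropped <- names(meas)[vapply(meas, function(x)
    is.numeric(x) && anyNA(x), logical(1))]
  if (length(dropped))
    warning("measures with missing values excluded from statistics: ",
            paste(dropped, collapse = ", "))
  utils::write.csv(meas, out("measures.csv"), row.names = FALSE)

  ## --- classical statistics -------------------------------------------------
  stat_cols <- setdiff(names(meas), c("subject_id", "sex", dropped))
  desc <- stage("stats", describe_measures(meas[stat_cols]))
  utils::write.csv(desc, out("descriptives.csv"), row.names = FALSE)
  if (!is.null(icc)) utils::write.csv(icc, out("icc.csv"), row.names = FALSE)

  km <- stage("stats", kendall_matrix(meas[stat_cols]))
  utils::write.csv(km$tau, out("kendall_tau.csv"))
  utils::write.csv(km$p, out("kendall_p.csv"))

  pca <- stage("stats", pca_measures(meas[stat_cols]))
  utils::write.csv(data.frame(dim = seq_along(pca$eigenvalues),
                              eigenvalue = pca$eigenvalues,
                              var_pct = pca$var_pct),
                   out("pca_variance.csv"), row.names = FALSE)
  utils::write.csv(pca$coords, out("pca_coords.csv"))

  ## --- symbolic regression --------------------------------------------------
  sr_results <- list()
  predictors <- setdiff(stat_cols,
                        c("Vol", "CSAmin", "Ap", "Lat", "slice_z", "sex"))
  for (tgt in config$sr_targets) {
    if (!tgt %in% names(meas)) next
    cfg <- config$sr; cfg$target <- tgt
    res <- stage(paste0("symreg_", tgt),
                 run_experiments(meas, cfg, predictors = predictors))
    sr_results[[tgt]] <- res
    utils::write.csv(res$importance,
                     out(sprintf("sr_importance_%s.csv", tgt)),
                     row.names = FALSE)
    utils::write.csv(res$sensitivity,
                     out(sprintf("sr_sensitivity_%s.csv", tgt)),
                     row.names = FALSE)
  }

  ## --- plots ----------------------------------------------------------------
  if (config$plots) {
    stage("plots", {
      save_plot(plot_kendall(km), out("kendall.png"), 7, 6.5)
      save_plot(plot_pca_circle(pca), out("pca_circle.png"), 6, 6)
      for (tgt in names(sr_results))
        save_plot(plot_importance(sr_results[[tgt]]$importance, tgt),
                  out(sprintf("sr_importance_%s.png", tgt)), 6, 4.5)
    })
  }

  manifest <- list(
    package = "airwaymorph",
    version = as.character(utils::packageVersion("airwaymorph")),
    r_version = R.version.string,
    seed = config$seed, derived_seeds = seeds,
    n_subjects = nrow(meas),
    sr_targets = names(sr_results),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(measures = meas, descriptives = desc, icc = icc,
                 kendall = km, pca = pca, sr = sr_results,
                 manifest = manifest))
}

## plotting helpers (plain styling) ------------------------------------------

save_plot <- function(p, path, width, height) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Correlation heatmap of a Kendall matrix
#'
#' @param km A `kendall_matrix`; non-significant cells are crossed.
#' @return A ggplot object.
#' @export
plot_kendall <- function(km) {
  v <- km$variables
  df <- expand.grid(x = v, y = v, stringsAsFactors = FALSE)
  df$tau <- as.vector(km$tau)
  df$sig <- as.vector(km$significant | diag(TRUE, length(v)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[!df$sig, ], shape = 4, size = 1.5) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1),
                                  name = "tau") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' PCA correlation circle (dimensions 1-2)
#'
#' @param pca A `pca_result`.
#' @return A ggplot object.
#' @export
plot_pca_circle <- function(pca) {
  df <- data.frame(variable = rownames(pca$coords),
                   d1 = pca$coords[, 1], d2 = pca$coords[, 2])
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- data.frame(x = cos(th), y = sin(th))
  ggplot2::ggplot(df) +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x, .data$y),
                       colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = .data$d1,
                                       yend = .data$d2),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(x = .data$d1 * 1.07, y = .data$d2 * 1.07,
                                    label = .data$variable), size = 2.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("Dim 1 (%.1f%%)", pca$var_pct[1]),
                  y = sprintf("Dim 2 (%.1f%%)", pca$var_pct[2])) +
    ggplot2::theme_minimal()
}

#' Bar chart of normalized variable importance
#'
#' @param importance Data frame from [variable_importance()].
#' @param target Target name for the title.
#' @param top_n Show at most this many variables.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, target = "", top_n = 15) {
  df <- utils::head(importance, top_n)
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$variable)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "normalized fitness-weighted importance", y = NULL,
                  title = target) +
    ggplot2::theme_minimal()
}
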