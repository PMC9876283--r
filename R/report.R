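# Table rendering, regression-data export, end-to-end pipeline.

#' Render a human-readable performance table
#'
#' Reshapes a [validate_models()] metrics table into the conventional
#' validation-report layout: one row per model, one column block
#' (adjusted R2, RMSE, C1, C2) per subgroup, per sex x modality panel.
#' Values are rounded to `digits` decimals for display only; subgroups
#' below the reliability threshold carry a `'‡'` marker in their header
#' and non-applicable model x sex cells print `n/a`.  The machine-format
#' metrics table, not this rendering, is the full-precision record.
#'
#' @param metrics A [validate_models()] result.
#' @param digits Display rounding (default 2).
#' @param file Optional CSV path to write the rendered table to.
#' @return Data frame of formatted character cells, one row per
#'   model x panel.
#' @export
render_performance_table <- function(metrics, digits = 2, file = NULL) {
  need <- c("model_id", "sex", "modality", "subgroup", "n", "r2_adj",
            "rmse", "c1", "c2", "status")
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols)) {
    .stop("metrics table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  fmt <- function(x) ifelse(is.na(x), "n/a", formatC(x, format = "f", digits = digits))
  panels <- unique(metrics[, c("modality", "sex")])
  subgroups <- unique(metrics$subgroup)
  out <- list()
  for (p in seq_len(nrow(panels))) {
    md <- panels$modality[p]; sx <- panels$sex[p]
    pm <- metrics[metrics$modality == md & metrics$sex == sx, , drop = FALSE]
    # models absent from this modality (either sex) are left out of the
    # panel entirely; sex-inapplicable cells inside the panel print n/a
    panel_models <- unique(metrics$model_id[metrics$modality == md])
    for (mid in panel_models) {
      row <- list(panel = paste(sx, md), model = mid)
      mm <- pm[pm$model_id == mid, , drop = FALSE]
      for (sub in subgroups) {
        cell <- mm[mm$subgroup == sub, , drop = FALSE]
        label <- sub
        if (nrow(cell) == 1) {
          if (!cell$reliable) label <- paste0(sub, "‡")
          label <- paste0(label, " [n=", cell$n, "]")
          vals <- c(fmt(cell$r2_adj), fmt(cell$rmse), fmt(cell$c1), fmt(cell$c2))
        } else {
          vals <- rep("n/a", 4)
        }
        row[paste0(sub, c("_R2", "_RMSE", "_C1", "_C2"))] <- as.list(vals)
        row[[paste0(sub, "_header")]] <- label
      }
      out[[length(out) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  if (!is.null(file)) utils::write.csv(tab, file, row.names = FALSE,
                                       fileEncoding = "UTF-8")
  tab
}

#' Export plot-ready regression data
#'
#' Emits the (predicted, observed) pairs of one model on one subgroup
#' together with the fitted calibration line and the pieces needed to
#' draw its pointwise 95% confidence band externally: residual sigma,
#' n, mean of predicted and its centred sum of squares, and the t
#' critical value.  The band half-width at x is
#' `t_crit * sigma * sqrt(1/n + (x - mean_x)^2 / sxx)`.
#'
#' @param observed,predicted Paired vectors in one unit.
#' @param conf_level Band confidence level (default 0.95).
#' @return List with `pairs` (data frame `predicted`, `observed`,
#'   `fitted`), `line` (`intercept`, `slope`) and `band`
#'   (`sigma`, `n`, `mean_x`, `sxx`, `t_crit`).
#' @export
export_regression_data <- function(observed, predicted, conf_level = 0.95) {
  cal <- fit_calibration(observed, predicted)
  n <- cal$n
  keep <- is.finite(observed) & is.finite(predicted)
  x <- predicted[keep]; y <- observed[keep]
  fitted <- cal$intercept + cal$slope * x
  sigma <- sqrt(sum((y - fitted)^2) / (n - 2))
  list(
    pairs = data.frame(predicted = x, observed = y, fitted = fitted),
    line = c(intercept = cal$intercept, slope = cal$slope),
    band = list(sigma = sigma, n = n, mean_x = mean(x),
                sxx = sum((x - mean(x))^2),
                t_crit = qt(1 - (1 - conf_level) / 2, df = n - 2))
  )
}

#' Run the full validation pipeline
#'
#' generate (or take a cohort) -> eligibility filter -> stratify ->
#' predict -> validate on the requested axes, with a manifest (seed,
#' configuration, stage record counts, package version, averaging-window
#' setting) so a bundle is exactly reproducible.
#'
#' @param config Generator configuration; ignored when `cohort` is given.
#' @param cohort Optional pre-loaded cohort; defaults to
#'   `generate_cohort(config)`.
#' @param models Prediction models (default built-ins).
#' @param axes Stratification axes to validate on.
#' @param contamination Fraction of eligibility violations injected
#'   before filtering (default 0).
#' @param seed Seed for generation/contamination (defaults to
#'   `config$seed`).
#' @param out_dir Optional directory; when given, writes `cohort.csv`,
#'   `included.csv`, `metrics.csv` and `manifest.json` there.
#' @return List of class `vo2val_bundle`: `cohort`, `included`, `ledger`,
#'   `metrics` (all axes row-bound), `manifest`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL,
                         models = builtin_models(),
                         axes = c("endurance", "age", "whole"),
                         contamination = 0, seed = config$seed,
                         out_dir = NULL) {
  axes <- match.arg(axes, c("endurance", "age", "whole"), several.ok = TRUE)
  raw <- cohort %||% generate_cohort(config, seed = seed)
  if (contamination > 0) {
    raw <- contaminate(raw, contamination, seed = seed + 1L)
  }
  incl <- apply_inclusion(raw)
  strat <- stratify(incl$cohort)
  metrics <- do.call(rbind, lapply(axes, function(ax) {
    validate_models(strat, models, axis = ax)
  }))
  rownames(metrics) <- NULL
  manifest <- list(
    package = "vo2val",
    version = as.character(utils::packageVersion("vo2val")),
    seed = seed,
    contamination = contamination,
    vo2_averaging_window_s = 15,
    n_generated = nrow(raw),
    n_included = nrow(incl$cohort),
    axes = axes,
    models = vapply(if (inherits(models, "vo2_registry")) models$models else models,
                    `[[`, "", "model_id"),
    config = if (is.null(cohort)) unclass(config) else NULL
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(raw, file.path(out_dir, "cohort.csv"))
    write_cohort(incl$cohort, file.path(out_dir, "included.csv"))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(cohort = raw, included = strat, ledger = incl$ledger,
                 metrics = metrics, manifest = manifest),
            class = "vo2val_bundle")
}

#' @export
print.vo2val_bundle <- function(x, ...) {
  cat("vo2val pipeline bundle\n")
  cat("  generated:", x$manifest$n_generated,
      "| included:", x$manifest$n_included, "\n")
  cat("  metric rows:", nrow(x$metrics), "across axes:",
      paste(x$manifest$axes, collapse = ", "), "\n")
  invisible(x)
}
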