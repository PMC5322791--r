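# Batch orchestration: images -> measurement CSVs; measurement table ->
# statistics reports. Per-image failures are logged and skipped so a
# heterogeneous batch (herbarium scans vary a lot) never aborts wholesale.

#' Default run configuration
#'
#' All pipeline defaults in one place; `run_measure()`/`run_stats()` take
#' these plus per-call overrides. A key=value config file (see
#' [read_config()]) overrides the built-ins, and direct arguments override
#' both.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(threshold.level = "otsu",
       threshold.polarity = "bright",
       morphology.open_radius = 1,
       morphology.close_radius = 1,
       prune.min_spur = 3,
       prune.adaptive = TRUE,
       angle.probe = "direction",
       angle.probe_factor = 3.5,
       pixel_scale = NA_real_,
       group.column = "group",
       seed = 1)
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are
#' coerced to numeric or logical where possible. Unknown keys are an
#' error, so typos fail loudly.
#'
#' @param path file path.
#' @return named list merged over [default_config()].
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num
    else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
    else val
  }
  cfg
}

#' Measure a batch of images
#'
#' Runs the full pipeline (pre-processing when given raw rasters,
#' skeletonization, graph construction, the six measurements) on every
#' input, writing per-image long-format CSVs, a one-row-per-image summary
#' CSV of the six means, feature/measurement overlay PNGs, loop reports
#' (JSON, whenever loops are found) and a log recording every parameter
#' actually used. Failing images are logged and skipped.
#'
#' @param inputs character vector of PNG/TIFF paths, or a named list of
#'   [binary_image()] objects (already binarized input is used as-is).
#' @param output_dir directory for outputs (created if needed).
#' @param config named list as from [read_config()]; `...` overrides
#'   single keys.
#' @param overlays write overlay PNGs? (default TRUE)
#' @param ... config overrides, e.g. `prune.min_spur = 5`.
#' @return invisibly, the summary data.frame (one row per processed image).
#' @export
run_measure <- function(inputs, output_dir, config = default_config(),
                        overlays = TRUE, ...) {
  config <- utils::modifyList(config, list(...))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(output_dir, "run_measure.log")
  log_lines <- c(sprintf("run_measure: %d input(s)", length(inputs)),
                 paste0("config: ",
                        paste(names(config),
                              vapply(config, format, ""),
                              sep = "=", collapse = " ")))
  nms <- if (is.character(inputs))
    tools::file_path_sans_ext(basename(inputs)) else names(inputs)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- sprintf("image%03d", seq_along(inputs))
  summary_rows <- list()
  readable <- 0L
  for (i in seq_along(inputs)) {
    id <- nms[i]
    res <- tryCatch({
      bin <- if (is.character(inputs)) {
        img <- read_raster(inputs[i])
        readable <- readable + 1L
        lv <- config$threshold.level
        preprocess_image(
          img,
          level = if (identical(lv, "otsu")) NULL else as.numeric(lv),
          polarity = config$threshold.polarity,
          open_radius = config$morphology.open_radius,
          close_radius = config$morphology.close_radius,
          pixel_scale = if (is.na(config$pixel_scale)) NULL
                        else config$pixel_scale)
      } else {
        readable <- readable + 1L
        inputs[[i]]
      }
      ms <- measure_thallus(bin, min_spur = config$prune.min_spur,
                            adaptive_prune = isTRUE(config$prune.adaptive),
                            probe = config$angle.probe,
                            probe_factor = config$angle.probe_factor,
                            on_ring = "error", id = id)
      utils::write.csv(as.data.frame(ms),
                       file.path(output_dir, paste0(id, "_measurements.csv")),
                       row.names = FALSE)
      if (ms$loop_report$count > 0L)
        jsonlite::write_json(
          list(count = ms$loop_report$count,
               cycles = lapply(ms$loop_report$cycles, function(cy)
                 unname(cy - 1L))),
          file.path(output_dir, paste0(id, "_loops.json")),
          auto_unbox = TRUE, digits = NA)
      if (overlays)
        write_measurement_overlay(ms, bin,
                                  file.path(output_dir,
                                            paste0(id, "_overlay.png")))
      lv_used <- ms$provenance$threshold_level
      log_lines <- c(log_lines,
                     sprintf("%s: ok (threshold=%s, prune=%s/%s, scale=%s)",
                             id, if (is.null(lv_used)) "given-mask" else lv_used,
                             config$prune.min_spur, config$prune.adaptive,
                             format(config$pixel_scale)))
      mv <- if (!is.null(ms$means_scaled)) ms$means_scaled else ms$means
      cbind(data.frame(image = id), as.data.frame(as.list(mv)),
            data.frame(loops = ms$loop_report$count))
    }, error = function(e) {
      log_lines <<- c(log_lines, sprintf("%s: SKIPPED (%s)",
                                         id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) summary_rows[[length(summary_rows) + 1L]] <- res
  }
  if (readable == 0L) {
    writeLines(log_lines, logf)
    stop("no readable inputs")
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(image = character(0))
  utils::write.csv(summary, file.path(output_dir, "summary.csv"),
                   row.names = FALSE)
  writeLines(log_lines, logf)
  invisible(summary)
}

#' Run the statistics reports on a measurement table
#'
#' Writes descriptive statistics, per-variable ANOVA with Tukey pairwise
#' comparisons, the Pearson correlation matrix, the MANOVA (Wilks) test
#' and the canonical discriminant analysis with its resubstitution
#' classification matrix, as CSV/JSON reports.
#'
#' @param table data.frame of per-specimen measurements, or path to a CSV
#'   with a header.
#' @param output_dir directory for the report files.
#' @param group name of the grouping column.
#' @param variables measurement columns (default: all numeric columns).
#' @return invisibly, a list with the in-memory results.
#' @export
run_stats <- function(table, output_dir, group = "group", variables = NULL) {
  if (is.character(table)) table <- utils::read.csv(table)
  if (!group %in% names(table)) stop("no grouping column '", group, "'")
  if (length(unique(table[[group]])) < 2L)
    stop("need at least two groups for the statistics reports")
  if (is.null(variables))
    variables <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                         group)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  desc <- descriptives(table, variables, group)
  utils::write.csv(desc, file.path(output_dir, "descriptives.csv"),
                   row.names = FALSE)
  pw <- do.call(rbind, lapply(variables, function(v) {
    a <- anova_pairwise(table, v, group)
    cbind(variable = v, a$pairwise)
  }))
  utils::write.csv(pw, file.path(output_dir, "anova_pairwise.csv"),
                   row.names = FALSE)
  cm <- correlation_matrix(table, variables)
  utils::write.csv(as.data.frame(cm$r),
                   file.path(output_dir, "correlation.csv"))
  mw <- manova_wilks(table, variables, group)
  jsonlite::write_json(list(wilks_lambda = mw$lambda, F = mw$F,
                            df1 = mw$df1, df2 = mw$df2, p_value = mw$p.value),
                       file.path(output_dir, "manova.json"),
                       auto_unbox = TRUE, digits = NA)
  fml <- stats::as.formula(paste(group, "~", paste(variables, collapse = "+")))
  fit <- cda(fml, table)
  cls <- cda_classify(fit)
  jsonlite::write_json(
    list(eigenvalues = fit$eigenvalues,
         canonical_correlation = fit$canonical_correlation,
         wilks_lambda = fit$wilks, proportion = fit$proportion,
         F = fit$F, num_df = fit$df1, p_value = fit$p.value,
         coefficients = as.data.frame(fit$coef),
         coefficients_standardized = as.data.frame(fit$coef_std),
         group_means = as.data.frame(fit$group_means),
         correct_rate = cls$correct_rate),
    file.path(output_dir, "cda.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame.matrix(cls$matrix),
                   file.path(output_dir, "classification_matrix.csv"))
  invisible(list(descriptives = desc, anova_pairwise = pw, correlation = cm,
                 manova = mw, cda = fit, classification = cls))
}
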