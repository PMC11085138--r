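# File formats and the end-to-end pipeline.  All tabular files are plain
# delimited text with documented headers; time is always hours since
# inoculation (no datetime parsing).  The JSON report is versioned and
# records the seed and thresholds so a rerun is reproducible.

REPORT_SCHEMA_VERSION <- "1.0"

#' Read a long-format multicultivator OD log
#'
#' Expects header columns `channel, time_h, od` (additional columns are
#' ignored). Returns one sensor-space [od_series()] per channel.
#' Malformed rows — missing columns, non-numeric cells, duplicated or
#' non-increasing timestamps within a channel — raise a parse error naming
#' the offending line (1-based, counting the header as line 1).
#'
#' @param path Path to the log file.
#' @param sep Field separator (default comma).
#' @param space Space of the logged values (default `"sensor"`).
#' @return Named list of [od_series()], one per channel.
#' @export
read_od_log <- function(path, sep = ",", space = "sensor") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("channel", "time_h", "od")
  if (nrow(raw) == 0L)
    stop(sprintf("parse error in '%s': no data rows", path), call. = FALSE)
  if (!all(need %in% names(raw)))
    stop(sprintf("parse error in '%s': missing columns %s", path,
                 paste(setdiff(need, names(raw)), collapse = ", ")),
         call. = FALSE)
  time_h <- suppressWarnings(as.numeric(raw$time_h))
  od <- suppressWarnings(as.numeric(raw$od))
  bad <- which(is.na(time_h) | is.na(od))
  if (length(bad))
    stop(sprintf("parse error in '%s': non-numeric value at line %d", path,
                 bad[1] + 1L), call. = FALSE)
  df <- data.frame(channel = raw$channel, time_h = time_h, od = od,
                   line = seq_len(nrow(raw)) + 1L)
  out <- list()
  for (ch in unique(df$channel)) {
    sub <- df[df$channel == ch, ]
    ord <- order(sub$time_h)
    sub <- sub[ord, ]
    dup <- which(diff(sub$time_h) <= 0)
    if (length(dup))
      stop(sprintf(
        "parse error in '%s': duplicated or non-increasing time at line %d (channel %s)",
        path, sub$line[dup[1] + 1L], ch), call. = FALSE)
    out[[ch]] <- od_series(sub$time_h, sub$od, space = space, channel = ch)
  }
  out
}

#' Write OD series to a long-format log file
#'
#' @param series A single [od_series()] or a list of them.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_od_log <- function(series, path, sep = ",") {
  if (inherits(series, "od_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(channel = s$channel, time_h = s$times, od = s$values)))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a full synthetic dataset to a directory
#'
#' Emits the sensor logs, the clean corrected log, the substrate table
#' (heterotrophic batches), and a `truth.json` with every generating
#' parameter and derived ground truth — the layout the analysis scripts
#' consume.
#'
#' @param batch A `simulated_batch` (after [apply_sensor_model()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_batch_dataset <- function(batch, dir) {
  stopifnot(inherits(batch, "simulated_batch"))
  if (is.null(batch$od_sensor))
    stop("apply_sensor_model() first: no sensor series present", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_od_log(batch$od_sensor, file.path(dir, "sensor_log.csv"))
  write_od_log(batch$od_corrected, file.path(dir, "corrected_log.csv"))
  if (!is.null(batch$substrate)) {
    utils::write.table(
      data.frame(time_h = batch$substrate$times,
                 conc_g_per_L = batch$substrate$concentration),
      file.path(dir, "substrate.csv"), sep = ",", row.names = FALSE,
      quote = FALSE)
  }
  spec <- batch$spec
  spec_out <- spec[setdiff(names(spec), "calibration")]
  spec_out$calibration <- list(a = spec$calibration$a, b = spec$calibration$b)
  jsonlite::write_json(list(spec = spec_out, truth = batch$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on one batch dataset
#'
#' Stage order: calibrate (or load a calibration) -> correct the sensor
#' logs -> segment phases -> estimate mu, doubling time, and V_max ->
#' substrate yields (when substrate data are present) -> pigment
#' contrasts (when pigment data are present). A stage failure aborts with
#' the stage name and cause. The report is returned as a list and, when
#' `config$outdir` is set, written to `report.json` (plus CSV tables).
#'
#' @param config Named list:
#'   * `od_log` — path to a sensor log, or a list of [od_series()];
#'   * `calibration` — a [calibration_model()], a path to a pairs file,
#'     or a data frame of pairs (fitted on the fly);
#'   * `conversion_k` — g biomass per corrected-OD unit;
#'   * `x_initial`, `s_initial` — endpoint-yield inputs (optional);
#'   * `substrate` — path or data frame of the substrate series (optional);
#'   * `pigments` — path or [pigment_records()] table (optional);
#'   * `lag_skip`, `min_exp_hours`, `r2_threshold`, `vmax_window_hours` —
#'     segmentation/productivity thresholds (optional, defaults as in
#'     [segment_phases()] / [estimate_vmax()]);
#'   * `contrast_design`, `alpha` — pigment-stage options (optional);
#'   * `outdir` — output directory (optional);
#'   * `seed` — recorded in the report.
#' @return The report, a nested list with `schema_version`, `seed`,
#'   `calibration`, `growth` (per channel), `yield`, and
#'   `pigment_contrasts` sections.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  report <- list(schema_version = REPORT_SCHEMA_VERSION,
                 seed = if (is.null(config$seed)) NA else config$seed,
                 thresholds = list(
                   lag_skip = config$lag_skip %||% 2,
                   min_exp_hours = config$min_exp_hours %||% 5,
                   r2_threshold = config$r2_threshold %||% 0.9996,
                   vmax_window_hours = config$vmax_window_hours %||% 12))

  model <- .stage("sensor_calibration", {
    cal <- config$calibration
    if (inherits(cal, "calibration_model")) cal
    else if (is.character(cal)) fit_calibration(read_calibration_pairs(cal))
    else if (is.data.frame(cal)) fit_calibration(cal)
    else stop("no usable calibration source in config")
  })
  report$calibration <- list(a = model$a, b = model$b,
                             n_pairs = model$n_pairs,
                             r_squared = model$r_squared)

  series <- .stage("io", {
    sl <- config$od_log
    if (is.character(sl)) read_od_log(sl)
    else if (inherits(sl, "od_series")) list(sl)
    else if (is.list(sl)) sl
    else stop("no usable OD log in config")
  })

  conv <- .stage("growth_analysis", {
    if (is.null(config$conversion_k))
      stop("conversion_k missing from config")
    biomass_conversion(config$conversion_k)
  })

  corrected <- .stage("sensor_calibration", lapply(series, function(s)
    if (s$space == "sensor") correct_series(s, model) else s))

  growth <- .stage("growth_analysis", lapply(corrected, function(s) {
    g <- analyze_growth(s, conv,
                        lag_skip = report$thresholds$lag_skip,
                        min_exp_hours = report$thresholds$min_exp_hours,
                        r2_threshold = report$thresholds$r2_threshold,
                        vmax_window_hours = report$thresholds$vmax_window_hours)
    list(channel = s$channel, mu = g$mu, mu_r_squared = g$mu_r_squared,
         doubling_time = g$doubling_time, vmax = g$vmax,
         exp_window = c(g$segmentation$exp_start, g$segmentation$exp_end),
         vmax_window = g$vmax_window)
  }))
  report$growth <- growth
  report$growth_summary <- list(
    mu_mean = mean(vapply(growth, `[[`, numeric(1), "mu")),
    vmax_mean = mean(vapply(growth, `[[`, numeric(1), "vmax")))

  if (!is.null(config$s_initial)) {
    report$yield <- .stage("substrate_yield", {
      x0 <- config$x_initial %||% 0
      finals <- vapply(corrected, function(s)
        od_to_biomass(s$values[length(s$values)], conv), numeric(1))
      est <- yield_endpoint(mean(finals), x0, config$s_initial)
      out <- list(endpoint = est$y)
      if (!is.null(config$substrate)) {
        ss <- if (is.character(config$substrate))
          read_substrate_table(config$substrate) else config$substrate
        bm <- data.frame(
          time_h = corrected[[1]]$times,
          biomass_g_per_L = od_to_biomass(
            rowMeans(vapply(corrected, `[[`, numeric(length(corrected[[1]]$times)),
                            "values")), conv))
        cons <- yield_consumption(bm, ss)
        out$consumption <- cons$y
        out$consumption_r_squared <- cons$diagnostics$r_squared
      }
      out
    })
  }

  if (!is.null(config$pigments)) {
    report$pigment_contrasts <- .stage("pigment_stats", {
      tab <- if (is.character(config$pigments))
        read_pigment_table(config$pigments) else config$pigments
      et <- effect_table(tab,
                         design = config$contrast_design %||%
                           c("light", "phase", "weaklight", "substrate"),
                         alpha = config$alpha %||% 0.05)
      et
    })
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report[setdiff(names(report), "pigment_contrasts")],
      file.path(config$outdir, "report.json"), auto_unbox = TRUE,
      digits = NA)
    if (!is.null(report$pigment_contrasts))
      utils::write.table(report$pigment_contrasts,
                         file.path(config$outdir, "pigment_contrasts.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
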