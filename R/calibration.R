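# Turbidity sensors in multicultivators report an apparent optical density
# (od_sensor, measured at 720 nm) that falls below the true optical density
# (od_reference, 750 nm in a bench spectrophotometer) as cultures densify.
# The ratio od_reference/od_sensor is well described by a * exp(b * od_sensor)
# with species- and condition-dependent constants a and b, so the corrected
# value is od_sensor * a * exp(b * od_sensor).

#' Construct a sensor calibration model
#'
#' Holds the constants of the exponential optical-density correction
#' `od_corrected = od_sensor * a * exp(b * od_sensor)` together with fit
#' diagnostics.
#'
#' @param a Dimensionless multiplier; the low-density correction factor
#'   (`od_corrected / od_sensor -> a` as `od_sensor -> 0`). Must be positive.
#' @param b Exponent, per apparent-OD unit. May be negative; typically
#'   positive for dense algal cultures.
#' @param label Species/condition tag carried through to reports.
#' @param n_pairs Number of calibration pairs used in the fit.
#' @param r_squared Coefficient of determination of the fit in the
#'   linearised space `ln(od_reference/od_sensor) ~ od_sensor`.
#' @return An object of class `calibration_model`.
#' @seealso [fit_calibration()], [correct_od()], [invert_od()]
#' @export
calibration_model <- function(a, b, label = "", n_pairs = NA_integer_,
                              r_squared = NA_real_) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (a <= 0) stop("calibration constant 'a' must be positive", call. = FALSE)
  if (!is.na(n_pairs) && n_pairs < 2L)
    stop("a fitted calibration needs at least 2 pairs", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("'r_squared' must lie in [0, 1]", call. = FALSE)
  structure(list(a = a, b = b, label = label,
                 n_pairs = as.integer(n_pairs), r_squared = r_squared),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Sensor calibration%s: a = %.4g, b = %.4g per OD unit\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$a, x$b))
  if (!is.na(x$n_pairs))
    cat(sprintf("  fitted on %d dilution pairs, R^2 (linearised) = %.4f\n",
                x$n_pairs, x$r_squared))
  invisible(x)
}

#' Correct apparent optical density
#'
#' Applies the exponential sensor correction: the corrected OD is
#' `od_sensor * a * exp(b * od_sensor)`. Strictly increasing and convex in
#' `od_sensor` for positive `a` and `b`.
#'
#' @param od_sensor Apparent OD from the turbidity sensor (vectorised,
#'   non-negative).
#' @param model A [calibration_model()].
#' @return Corrected OD, same length as `od_sensor`.
#' @export
correct_od <- function(od_sensor, model) {
  stopifnot(inherits(model, "calibration_model"), is.numeric(od_sensor))
  if (any(od_sensor < 0, na.rm = TRUE))
    stop("apparent OD must be non-negative", call. = FALSE)
  od_sensor * model$a * exp(model$b * od_sensor)
}

#' Invert the sensor correction
#'
#' Returns the apparent OD `x` satisfying `correct_od(x, model) ==
#' od_corrected`. For `b != 0` the closed form uses the principal Lambert-W
#' branch, `x = W0(b * od_corrected / a) / b`; for `b == 0`, `x =
#' od_corrected / a`. Used by the simulator to emit sensor-space logs.
#'
#' @param od_corrected Corrected (true) OD, non-negative, vectorised.
#' @param model A [calibration_model()].
#' @return Apparent OD, same length as `od_corrected`.
#' @export
invert_od <- function(od_corrected, model) {
  stopifnot(inherits(model, "calibration_model"), is.numeric(od_corrected))
  if (any(od_corrected < 0, na.rm = TRUE))
    stop("corrected OD must be non-negative", call. = FALSE)
  if (model$b == 0) return(od_corrected / model$a)
  arg <- model$b * od_corrected / model$a
  if (any(arg < -exp(-1), na.rm = TRUE))
    stop("corrected OD outside the invertible range for b < 0", call. = FALSE)
  vapply(arg, function(z) {
    if (is.na(z)) return(NA_real_)
    pracma::lambertWp(z)
  }, numeric(1)) / model$b
}

#' Fit the sensor calibration from dilution pairs
#'
#' Fits the exponential correction in its linearised space:
#' `ln(od_reference/od_sensor) = ln(a) + b * od_sensor`, by ordinary least
#' squares; `a = exp(intercept)`. The linearisation is exact, so noiseless
#' model-consistent pairs recover the generating constants to machine
#' precision, and the fit is deterministic with no starting-value
#' sensitivity. Pairs with `od_sensor` below `min_od_sensor` are excluded:
#' the ratio amplifies noise near zero.
#'
#' @param pairs Data frame with numeric columns `od_sensor` (apparent OD)
#'   and `od_reference` (spectrophotometer OD at 750 nm), one row per
#'   dilution.
#' @param min_od_sensor Exclusion floor on apparent OD (default 0.01).
#' @param label Species/condition tag stored in the model.
#' @return A [calibration_model()] with `n_pairs` and `r_squared` filled in.
#' @examples
#' pairs <- simulate_dilution_series(calibration_model(1.795, 0.934))
#' fit_calibration(pairs)
#' @export
fit_calibration <- function(pairs, min_od_sensor = 0.01, label = "") {
  pairs <- as.data.frame(pairs)
  need <- c("od_sensor", "od_reference")
  if (!all(need %in% names(pairs)))
    stop("'pairs' needs columns od_sensor and od_reference", call. = FALSE)
  ok <- is.finite(pairs$od_sensor) & is.finite(pairs$od_reference) &
    pairs$od_sensor >= min_od_sensor
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 2L)
    stop("insufficient data: need at least 2 usable calibration pairs",
         call. = FALSE)
  ratio <- pairs$od_reference / pairs$od_sensor
  if (any(ratio <= 0))
    stop("non-positive od_reference/od_sensor ratio: cannot linearise",
         call. = FALSE)
  fit <- stats::lm(log(ratio) ~ od_sensor, data = pairs)
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("degenerate calibration pairs (constant od_sensor?)", call. = FALSE)
  # noiseless model-consistent pairs fit perfectly; that is expected here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  calibration_model(a = exp(unname(co[1])), b = unname(co[2]), label = label,
                    n_pairs = nrow(pairs),
                    r_squared = min(max(r2, 0), 1))
}

#' Compare two calibration fits (e.g. exponential vs deceleration phase)
#'
#' Fits a common linearised model with a group term and its interaction
#' with `od_sensor`, so the reported p-values test whether `ln(a)` and `b`
#' differ between the two sets of dilution pairs. Useful to confirm that
#' one model per species/condition suffices across growth phases.
#'
#' @param pairs_a,pairs_b Data frames of calibration pairs (see
#'   [fit_calibration()]).
#' @param labels Character vector of length 2 naming the groups.
#' @param min_od_sensor Exclusion floor on apparent OD.
#' @return Data frame with one row per constant (`ln_a`, `b`): the estimate
#'   in each group, the difference, and its p-value.
#' @export
compare_calibrations <- function(pairs_a, pairs_b,
                                 labels = c("group_a", "group_b"),
                                 min_od_sensor = 0.01) {
  fa <- fit_calibration(pairs_a, min_od_sensor, labels[1])
  fb <- fit_calibration(pairs_b, min_od_sensor, labels[2])
  build <- function(p, g) {
    p <- as.data.frame(p)
    p <- p[is.finite(p$od_sensor) & p$od_sensor >= min_od_sensor, ]
    data.frame(od_sensor = p$od_sensor,
               y = log(p$od_reference / p$od_sensor), group = g)
  }
  dat <- rbind(build(pairs_a, labels[1]), build(pairs_b, labels[2]))
  dat$group <- factor(dat$group, levels = labels)
  fit <- stats::lm(y ~ od_sensor * group, data = dat)
  sm <- stats::coef(summary(fit))
  grp_rows <- grep("group", rownames(sm))
  data.frame(
    constant = c("ln_a", "b"),
    estimate_a = c(log(fa$a), fa$b),
    estimate_b = c(log(fb$a), fb$b),
    difference = sm[grp_rows, "Estimate"],
    p_value = sm[grp_rows, "Pr(>|t|)"],
    row.names = NULL
  )
}

#' Generate a synthetic dilution series from a calibration model
#'
#' Emits `(od_sensor, od_reference)` pairs exactly consistent with the
#' exponential correction, optionally with multiplicative Gaussian noise on
#' the reference reading — the shape of a real dilution-series measurement.
#'
#' @param model A [calibration_model()] supplying the generating constants.
#' @param od_sensor Apparent-OD grid (default 0.1 to 2.0 in steps of 0.1,
#'   the range a dense-culture dilution series spans).
#' @param noise_sd Relative standard deviation of multiplicative Gaussian
#'   noise on `od_reference` (0 = noiseless).
#' @param seed Optional integer seed; only consulted when `noise_sd > 0`.
#' @return Data frame with columns `od_sensor`, `od_reference`.
#' @export
simulate_dilution_series <- function(model, od_sensor = seq(0.1, 2, by = 0.1),
                                     noise_sd = 0, seed = NULL) {
  ref <- correct_od(od_sensor, model)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ref <- ref * (1 + stats::rnorm(length(ref), 0, noise_sd))
  }
  data.frame(od_sensor = od_sensor, od_reference = ref)
}

#' Read calibration pairs from a delimited text file
#'
#' Expects a header with columns `od_sensor` and `od_reference`, decimal
#' point, UTF-8.
#'
#' @param path Path to the file.
#' @param sep Field separator (default comma).
#' @return Data frame of calibration pairs.
#' @export
read_calibration_pairs <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("od_sensor", "od_reference")
  if (!all(need %in% names(df)))
    stop(sprintf("calibration file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!all(vapply(df[need], is.numeric, logical(1))))
    stop(sprintf("non-numeric values in calibration file '%s'", path),
         call. = FALSE)
  if (any(df$od_sensor < 0 | df$od_reference < 0))
    stop("calibration pairs must be non-negative", call. = FALSE)
  df
}
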