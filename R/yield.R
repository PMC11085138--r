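# Biomass yield on carbon substrate (Y_X/S, g dry weight per g substrate).
# Two estimators: the endpoint method divides the biomass gained by the
# initial substrate concentration (assuming complete consumption), and the
# consumption method regresses cumulative biomass increments on cumulative
# substrate consumed, through the origin.

#' Construct a substrate concentration series
#'
#' @param times Hours since inoculation, strictly increasing.
#' @param concentration Substrate concentration, g L^-1, non-negative;
#'   expected non-increasing up to measurement noise.
#' @param substrate Substrate name (e.g. `"glucose"`, `"acetate"`).
#' @return An object of class `substrate_series`.
#' @export
substrate_series <- function(times, concentration, substrate = "substrate") {
  stopifnot(is.numeric(times), is.numeric(concentration),
            length(times) == length(concentration))
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(concentration < 0))
    stop("substrate concentration must be non-negative", call. = FALSE)
  structure(list(times = as.numeric(times),
                 concentration = as.numeric(concentration),
                 substrate = substrate),
            class = "substrate_series")
}

#' Yield estimate container
#'
#' @param y Yield, g dry weight per g substrate, non-negative.
#' @param method `"endpoint"` or `"consumption"`.
#' @param diagnostics Named list (e.g. `r_squared` for the consumption
#'   regression).
#' @return An object of class `yield_estimate`.
#' @export
yield_estimate <- function(y, method = c("endpoint", "consumption"),
                           diagnostics = list()) {
  method <- match.arg(method)
  if (y < 0) stop("yield must be non-negative", call. = FALSE)
  structure(list(y = y, method = method, diagnostics = diagnostics),
            class = "yield_estimate")
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat(sprintf("Y_X/S = %.3f g(DW) g^-1 [%s method]\n", x$y, x$method))
  if (!is.null(x$diagnostics$r_squared))
    cat(sprintf("  consumption regression R^2 = %.4f\n",
                x$diagnostics$r_squared))
  invisible(x)
}

#' Endpoint biomass yield on substrate
#'
#' Divides the biomass density gained over the batch by the initial
#' substrate concentration. Valid under the assumption that the substrate
#' is exhausted when growth stops; if a final substrate concentration is
#' supplied and exceeds 5% of the initial one, a warning is raised because
#' that assumption fails.
#'
#' @param x_final Final biomass density, g L^-1.
#' @param x_initial Initial biomass density, g L^-1.
#' @param s_initial Initial substrate concentration, g L^-1, positive.
#' @param s_final Optional final substrate concentration, g L^-1.
#' @return A [yield_estimate()] with method `"endpoint"`.
#' @examples
#' yield_endpoint(7.75, 0.10, 15)  # ~0.51 g/g
#' @export
yield_endpoint <- function(x_final, x_initial, s_initial, s_final = NULL) {
  if (s_initial <= 0)
    stop("initial substrate concentration must be positive", call. = FALSE)
  if (x_final < x_initial)
    stop("negative growth: x_final < x_initial", call. = FALSE)
  if (!is.null(s_final) && s_final > 0.05 * s_initial)
    warning(sprintf(
      "final substrate (%.3g g/L) exceeds 5%% of initial: endpoint yield assumes complete consumption",
      s_final), call. = FALSE)
  yield_estimate((x_final - x_initial) / s_initial, "endpoint",
                 diagnostics = list(x_final = x_final, x_initial = x_initial,
                                    s_initial = s_initial))
}

#' Consumption-regression biomass yield on substrate
#'
#' Regresses cumulative biomass increments `X(t) - X(t0)` on cumulative
#' substrate consumed `S(t0) - S(t)`, through the origin (the mass-balance
#' line passes through (0, 0) by definition). The substrate series is
#' linearly interpolated to the biomass sampling times when the grids
#' differ.
#'
#' @param biomass Data frame with columns `time_h` and `biomass_g_per_L`,
#'   or an [od_series()] already converted to biomass units.
#' @param substrate A [substrate_series()] or data frame with columns
#'   `time_h` and `conc_g_per_L`.
#' @return A [yield_estimate()] with method `"consumption"` and an
#'   `r_squared` diagnostic.
#' @export
yield_consumption <- function(biomass, substrate) {
  if (inherits(biomass, "od_series"))
    biomass <- data.frame(time_h = biomass$times,
                          biomass_g_per_L = biomass$values)
  if (inherits(substrate, "substrate_series"))
    substrate <- data.frame(time_h = substrate$times,
                            conc_g_per_L = substrate$concentration)
  stopifnot(all(c("time_h", "biomass_g_per_L") %in% names(biomass)),
            all(c("time_h", "conc_g_per_L") %in% names(substrate)))
  tmin <- max(min(biomass$time_h), min(substrate$time_h))
  tmax <- min(max(biomass$time_h), max(substrate$time_h))
  bm <- biomass[biomass$time_h >= tmin & biomass$time_h <= tmax, ]
  if (nrow(bm) < 3L)
    stop("need at least 3 paired time points", call. = FALSE)
  s_at <- stats::approx(substrate$time_h, substrate$conc_g_per_L,
                        xout = bm$time_h)$y
  ds <- s_at[1] - s_at       # substrate consumed since first point
  dx <- bm$biomass_g_per_L - bm$biomass_g_per_L[1]
  if (max(ds) <= 0)
    stop("substrate never decreases: no consumption to regress on",
         call. = FALSE)
  fit <- stats::lm(dx ~ 0 + ds)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum(dx^2)
  yield_estimate(max(unname(stats::coef(fit)[1]), 0), "consumption",
                 diagnostics = list(
                   r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                   n = nrow(bm)))
}

#' Read a substrate concentration table
#'
#' Delimited text with header columns `time_h`, `conc_g_per_L`.
#'
#' @param path Path to the file.
#' @param substrate Substrate name stored in the series.
#' @param sep Field separator (default comma).
#' @return A [substrate_series()].
#' @export
read_substrate_table <- function(path, substrate = "substrate", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("time_h", "conc_g_per_L")
  if (!all(need %in% names(df)))
    stop(sprintf("substrate file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  substrate_series(df$time_h, df$conc_g_per_L, substrate)
}
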