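## Curve models. The thermal-unfolding model is the Boltzmann sigmoidal
##   Y = Bottom + (Top - Bottom) / (1 + exp((V50 - X)/Slope)),
## which *rises* with X; the folded fraction falls with temperature, so when
## fitting folded-fraction data with Top/Bottom fixed to 1/0 the model is
## applied to the unfolded fraction (1 - f), equivalently
##   f(X) = 1 / (1 + exp((X - V50)/Slope)).
## V50 (the Tm) and Slope are reported unchanged either way.

boltzmann_y <- function(X, Bottom, Top, V50, Slope) {
  Bottom + (Top - Bottom) / (1 + exp((V50 - X) / Slope))
}

folded_fraction_y <- function(X, V50, Slope) {
  1 / (1 + exp((X - V50) / Slope))
}

#' Fit a Boltzmann sigmoidal thermal unfolding curve
#'
#' Nonlinear least squares (Levenberg-Marquardt via [minpack.lm::nlsLM()])
#' of the Boltzmann sigmoidal to a melt curve. With
#' `fix_normalization = TRUE` the input must be folded fraction and the
#' normalization constants are held at Top = 1, Bottom = 0 (the model then
#' fits the unfolded fraction `1 - Y`); otherwise Top and Bottom are free.
#' Initialization is deterministic: V50 at the half-range crossing
#' temperature, Slope = range(X)/10.
#'
#' @param temperature Temperatures (degrees C), strictly increasing.
#' @param y Ellipticity or folded fraction at each temperature.
#' @param fix_normalization Hold Top = 1, Bottom = 0 (input must be folded
#'   fraction).
#' @param min_signal_to_noise A transition is required: the data range must
#'   exceed this multiple of the local noise estimate (default 5).
#' @return A `melt_fit`: list with `V50`, `Slope`, `Top`, `Bottom`,
#'   standard errors (`se`), `converged`, and the fitted model.
#' @export
fit_boltzmann <- function(temperature, y, fix_normalization = TRUE,
                          min_signal_to_noise = 5) {
  stopifnot(length(temperature) == length(y), length(y) >= 8L)
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  # local noise: SD of successive differences of the residual signal
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  if (diff(range(y)) <= min_signal_to_noise * max(noise, 1e-12))
    stop("no-transition error: curve is flat relative to its noise")
  v50_init <- init_half_crossing(temperature, y)
  slope_init <- diff(range(temperature)) / 10
  df <- data.frame(X = temperature, Y = y)
  fit <- if (fix_normalization) {
    if (min(y) < -0.2 || max(y) > 1.2)
      stop("fix_normalization requires folded-fraction input in [0, 1]; ",
           "see normalize_to_folded_fraction()")
    minpack.lm::nlsLM(Y ~ folded_fraction_y(X, V50, Slope), data = df,
                      start = list(V50 = v50_init, Slope = slope_init),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    # the model tends to Bottom below the transition and Top above it, so a
    # falling curve simply fits with Top < Bottom. Y is rescaled to unit
    # range for the optimizer (raw millidegree scales otherwise produce a
    # numerically singular initial gradient) and mapped back afterwards.
    y_off <- min(y); y_rng <- diff(range(y))
    df$Yn <- (y - y_off) / y_rng
    n10 <- max(2L, ceiling(length(y) / 10))
    minpack.lm::nlsLM(Yn ~ boltzmann_y(X, Bottom, Top, V50, Slope), data = df,
                      start = list(Bottom = mean(utils::head(df$Yn, n10)),
                                   Top = mean(utils::tail(df$Yn, n10)),
                                   V50 = v50_init, Slope = slope_init),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  if (fix_normalization) {
    res <- list(V50 = unname(cf["V50"]), Slope = unname(cf["Slope"]),
                Top = 1, Bottom = 0,
                se = c(V50 = unname(se["V50"]), Slope = unname(se["Slope"]),
                       Top = 0, Bottom = 0))
  } else {
    y_off <- min(y); y_rng <- diff(range(y))
    res <- list(V50 = unname(cf["V50"]), Slope = unname(cf["Slope"]),
                Top = y_off + y_rng * unname(cf["Top"]),
                Bottom = y_off + y_rng * unname(cf["Bottom"]),
                se = c(V50 = unname(se["V50"]), Slope = unname(se["Slope"]),
                       Top = y_rng * unname(se["Top"]),
                       Bottom = y_rng * unname(se["Bottom"])))
  }
  if (res$V50 < min(temperature) || res$V50 > max(temperature))
    stop("fit failure: V50 = ", signif(res$V50, 4),
         " lies outside the measured temperature range [",
         min(temperature), ", ", max(temperature), "]")
  res$converged <- fit$convInfo$isConv %||% TRUE
  res$fit <- fit
  class(res) <- "melt_fit"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Temperature at which y crosses the midpoint of its range (linear
## interpolation between the bracketing points).
init_half_crossing <- function(x, y) {
  mid <- (max(y) + min(y)) / 2
  s <- sign(y - mid)
  i <- which(s[-1] * s[-length(s)] <= 0)[1]
  if (is.na(i)) return(stats::median(x))
  x[i] + (mid - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("melt_fit: Tm (V50) = %.2f +/- %.2f C, Slope = %.2f C\n",
              x$V50, x$se["V50"], x$Slope))
  invisible(x)
}

#' Normalize a melt curve to folded fraction
#'
#' An unconstrained Boltzmann pre-fit supplies the pre- and post-transition
#' plateaus; the curve is then mapped linearly so the pre-transition plateau
#' becomes 1 (fully folded) and the post-transition plateau 0. Idempotent on
#' already-normalized curves.
#'
#' @param temperature Temperatures (degrees C).
#' @param y Raw ellipticity (or any monotone-transition signal).
#' @return Numeric vector of folded fractions.
#' @export
normalize_to_folded_fraction <- function(temperature, y) {
  pre <- fit_boltzmann(temperature, y, fix_normalization = FALSE)
  # fitted asymptotes: the model tends to Bottom on the low-temperature side
  # and Top on the high-temperature side (for Slope > 0)
  lo <- if (pre$Slope > 0) pre$Bottom else pre$Top
  hi <- if (pre$Slope > 0) pre$Top else pre$Bottom
  if (abs(lo - hi) < 1e-12)
    stop("normalization error: indistinguishable plateaus")
  (y - hi) / (lo - hi)
}

#' Aggregate replicate melt fits
#'
#' Arithmetic mean and sample SD of the replicate V50 (Tm) values; refuses if
#' any replicate failed to converge.
#'
#' @param fits List of `melt_fit` objects (>= 2).
#' @return List with `mean_tm`, `sd_tm`, `n`.
#' @export
aggregate_tm <- function(fits) {
  stopifnot(length(fits) >= 2L)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv))
    stop("aggregation refused: replicate(s) ",
         paste(which(!conv), collapse = ", "), " did not converge")
  tms <- vapply(fits, `[[`, numeric(1), "V50")
  list(mean_tm = mean(tms), sd_tm = stats::sd(tms), n = length(tms))
}

#' Melting-temperature difference between two states
#'
#' `delta = Tm_a - Tm_b`, with the replicate SDs combined in quadrature.
#'
#' @param agg_a,agg_b Aggregates from [aggregate_tm()].
#' @return List with `delta_tm` and `sd`.
#' @export
delta_tm <- function(agg_a, agg_b) {
  list(delta_tm = agg_a$mean_tm - agg_b$mean_tm,
       sd = sqrt(agg_a$sd_tm^2 + agg_b$sd_tm^2))
}

#' Fit a one-phase association time course
#'
#' Least squares of `Y(x) = Y0 + (Plateau - Y0) (1 - exp(-k x))`, the standard
#' model for nucleotide-exchange tryptophan-fluorescence enhancement. `k` is
#' the rate constant in reciprocal x-axis time units. Initialization is
#' deterministic: `Plateau` from the tail mean, `Y0` from the first point,
#' `k` from a log-linear fit of `log(Plateau_est - Y)`.
#'
#' @param time Time axis (any unit), >= 20 points.
#' @param y Fluorescence intensities.
#' @return A `kinetics_fit`: list with `Y0`, `Plateau`, `k`, standard errors
#'   (`se`), `converged`, and a `window_warning` flag set when the fitted
#'   `1/k` exceeds a third of the observation window (weak identifiability).
#' @export
fit_one_phase <- function(time, y) {
  stopifnot(length(time) == length(y), length(y) >= 20L)
  plateau_init <- mean(y[time >= stats::quantile(time, 0.9)])
  y0_init <- y[1]
  dy <- plateau_init - y
  pos <- dy > 0 & time > min(time)
  k_init <- if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(dy[pos]) ~ time[pos]))[2]
    max(-unname(sl), 1e-6)
  } else 1 / diff(range(time))
  df <- data.frame(x = time, Y = y)
  fit <- minpack.lm::nlsLM(
    Y ~ Y0 + (Plateau - Y0) * (1 - exp(-k * x)), data = df,
    start = list(Y0 = y0_init, Plateau = plateau_init, k = k_init),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (cf["k"] <= 0)
    stop("no-association error: fitted rate constant is not positive")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3), names(cf)))
  window_warning <- (1 / cf["k"]) > diff(range(time)) / 3
  if (window_warning)
    warning("fitted time constant 1/k exceeds a third of the observation ",
            "window; k is weakly identified")
  structure(list(Y0 = unname(cf["Y0"]), Plateau = unname(cf["Plateau"]),
                 k = unname(cf["k"]),
                 se = c(Y0 = unname(se["Y0"]), Plateau = unname(se["Plateau"]),
                        k = unname(se["k"])),
                 converged = fit$convInfo$isConv %||% TRUE,
                 window_warning = unname(window_warning), fit = fit),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("kinetics_fit: k = %.4g +/- %.2g, Y0 = %.4g, Plateau = %.4g\n",
              x$k, x$se["k"], x$Y0, x$Plateau))
  invisible(x)
}

#' Read a melt-curve CSV
#'
#' Columns `temperature`, `ellipticity` and optionally `replicate`.
#'
#' @param path CSV path.
#' @return Data frame (replicate defaults to 1 when absent).
#' @export
read_melt_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("temperature", "ellipticity") %in% names(tab)))
    stop("melt CSV must have columns temperature, ellipticity")
  if (is.null(tab$replicate)) tab$replicate <- 1L
  tab
}

#' Fit replicate melt curves and aggregate the Tm
#'
#' Each replicate is normalized to folded fraction and fitted with fixed
#' normalization; replicate Tm values are aggregated as mean and SD.
#'
#' @param melt Data frame from [read_melt_csv()].
#' @return List with `fits` (per replicate), `aggregate` (mean/SD/n).
#' @export
fit_melt_replicates <- function(melt) {
  reps <- split(melt, melt$replicate)
  fits <- lapply(reps, function(d) {
    f <- normalize_to_folded_fraction(d$temperature, d$ellipticity)
    fit_boltzmann(d$temperature, f, fix_normalization = TRUE)
  })
  agg <- if (length(fits) >= 2L) aggregate_tm(fits) else
    list(mean_tm = fits[[1]]$V50, sd_tm = NA_real_, n = 1L)
  list(fits = fits, aggregate = agg)
}
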