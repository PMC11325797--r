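#' Construct a 1D NMR spectrum
#'
#' @param ppm Chemical-shift axis (ppm), strictly monotone (conventionally
#'   descending).
#' @param intensity Intensities (arbitrary units), same length as `ppm`.
#' @param meta Optional metadata list (saturation time, irradiation offsets,
#'   spectrometer frequency in MHz, ...).
#' @return A `spectrum1d` object.
#' @export
spectrum1d <- function(ppm, intensity, meta = list()) {
  if (length(ppm) != length(intensity))
    stop("ppm axis and intensities differ in length")
  dd <- diff(ppm)
  if (!(all(dd > 0) || all(dd < 0)))
    stop("ppm axis must be strictly monotone")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 meta = meta), class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat("spectrum1d:", length(x$ppm), "points,",
      sprintf("%.3f to %.3f ppm\n", x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' STD difference spectrum
#'
#' `off - on`, minus an optional background spectrum (a matched protein-only
#' STD spectrum, processed identically). Axes must agree exactly; no silent
#' interpolation is performed.
#'
#' @param off,on `spectrum1d` objects on identical axes.
#' @param background Optional `spectrum1d` to subtract after differencing.
#' @param tol Axis agreement tolerance (ppm).
#' @return A `spectrum1d`.
#' @export
difference_spectrum <- function(off, on, background = NULL, tol = 1e-9) {
  check_axis <- function(a, b, what) {
    if (length(a$ppm) != length(b$ppm) || any(abs(a$ppm - b$ppm) > tol))
      stop("alignment error: ", what, " axes differ (no silent interpolation)")
  }
  check_axis(off, on, "on/off")
  d <- off$intensity - on$intensity
  if (!is.null(background)) {
    check_axis(off, background, "background")
    d <- d - background$intensity
  }
  spectrum1d(off$ppm, d, off$meta)
}

#' Integrate a spectral window
#'
#' Sign-preserving trapezoidal integral over a ppm window, in
#' intensity * ppm. The window is `[lo, hi]` in ppm regardless of axis
#' direction; the integral is taken over ascending ppm.
#'
#' @param spec A `spectrum1d`.
#' @param window Numeric length-2 ppm interval.
#' @return Scalar integral.
#' @export
integrate_peak <- function(spec, window) {
  lo <- min(window); hi <- max(window)
  sel <- spec$ppm >= lo & spec$ppm <= hi
  if (sum(sel) < 2L)
    stop("window error: window [", lo, ", ", hi, "] ppm does not overlap axis")
  x <- spec$ppm[sel]; y <- spec$intensity[sel]
  if (x[1] > x[length(x)]) { x <- rev(x); y <- rev(y) }
  pracma::trapz(x, y)
}

#' STD amplification factor
#'
#' `ASTD = (Idiff / I0) * (L / P)` where `Idiff` is the signal integral in the
#' difference spectrum, `I0` the integral of the same signal in the reference
#' (off-resonance) spectrum, and `L`, `P` the ligand and protein
#' concentrations (any shared unit). Expressed with the on-resonance integral
#' `Isat`, `Idiff = I0 - Isat`; both conventions are exposed via `Isat`.
#'
#' @param I0 Reference integral (> 0).
#' @param Idiff Difference-spectrum integral. Supply either `Idiff` or `Isat`.
#' @param L,P Ligand and protein concentrations (same units; `P > 0`).
#' @param Isat Optional on-resonance integral; used as `Idiff = I0 - Isat`.
#' @return Scalar amplification factor.
#' @export
compute_std_af <- function(I0, Idiff = NULL, L, P, Isat = NULL) {
  if (!is.null(Isat)) {
    if (!is.null(Idiff)) stop("supply Idiff or Isat, not both")
    Idiff <- I0 - Isat
  }
  if (is.null(Idiff)) stop("supply Idiff or Isat")
  if (I0 <= 0) stop("domain error: I0 must be > 0")
  if (P <= 0) stop("domain error: protein concentration must be > 0")
  (Idiff / I0) * (L / P)
}

#' Amplification-factor uncertainty from the difference-spectrum SNR
#'
#' `sigma = ASTD / SNRdiff`.
#'
#' @param ASTD Amplification factor.
#' @param SNRdiff Signal-to-noise ratio of the signal in the difference
#'   spectrum (> 0).
#' @return Scalar sigma (same units as ASTD).
#' @export
compute_af_error <- function(ASTD, SNRdiff) {
  if (any(SNRdiff <= 0)) stop("domain error: SNRdiff must be > 0")
  ASTD / SNRdiff
}

#' Normalize amplification factors to a reference proton
#'
#' Each proton's ASTD is expressed as a percentage of the reference proton's
#' (conventionally proton "a" of the guanine base, whose local environment is
#' the most invariant). Uncertainties propagate in quadrature on relative
#' errors: `sigma_norm/norm = sqrt((sigma/ASTD)^2 + (sigma_ref/ASTD_ref)^2)`;
#' the reference proton is reported at 100% carrying its own relative error.
#'
#' @param af Data frame with columns `proton`, `ASTD` and optionally `sigma`.
#' @param reference Reference proton label (default `"a"`).
#' @return An `std_af_result`: the input with `normalized_pct`, `sigma_pct`
#'   and `bin` columns appended.
#' @export
normalize_af <- function(af, reference = "a") {
  stopifnot(all(c("proton", "ASTD") %in% names(af)))
  if (!reference %in% af$proton)
    stop("reference proton '", reference, "' not present")
  ref <- af[af$proton == reference, , drop = FALSE][1, ]
  if (ref$ASTD <= 0)
    stop("normalization error: reference ASTD must be > 0")
  if (is.null(af$sigma)) af$sigma <- 0
  af$normalized_pct <- 100 * af$ASTD / ref$ASTD
  rel <- ifelse(af$ASTD > 0, af$sigma / af$ASTD, 0)
  rel_ref <- ref$sigma / ref$ASTD
  rel_norm <- sqrt(rel^2 + rel_ref^2)
  rel_norm[af$proton == reference] <- rel_ref
  af$sigma_pct <- af$normalized_pct * rel_norm
  af$bin <- vapply(af$normalized_pct, bin_interaction, character(1))
  structure(af, class = c("std_af_result", "data.frame"),
            reference = reference)
}

#' Interaction bin of a normalized amplification factor
#'
#' Bins relative to the reference proton (100%): `<= 50` weak, `(50, 100)`
#' weak-moderate, `[100, 150]` moderate (closed at 100, where the reference
#' itself sits), `> 150` strong. A total function on `[0, Inf)`.
#'
#' @param pct Normalized amplification factor (percent, >= 0).
#' @return One of `"weak"`, `"weak-moderate"`, `"moderate"`, `"strong"`.
#' @export
bin_interaction <- function(pct) {
  if (is.na(pct) || pct < 0) stop("domain error: pct must be >= 0")
  if (pct <= 50) "weak"
  else if (pct < 100) "weak-moderate"
  else if (pct <= 150) "moderate"
  else "strong"
}

#' Signal-to-noise ratio in a spectrum
#'
#' `SNR = max |intensity in signal window| / (divisor * RMS of the noise
#' window after mean removal)`, mirroring common spectrometer "sino" output
#' (divisor 2 by default).
#'
#' @param spec A `spectrum1d`.
#' @param signal_window,noise_window Disjoint ppm intervals; the noise window
#'   must be signal-free by declaration.
#' @param divisor Noise multiplier in the denominator (default 2).
#' @return Scalar SNR.
#' @export
estimate_snr <- function(spec, signal_window, noise_window, divisor = 2) {
  if (max(min(signal_window), min(noise_window)) <
      min(max(signal_window), max(noise_window)))
    stop("signal and noise windows must be disjoint")
  s_sel <- spec$ppm >= min(signal_window) & spec$ppm <= max(signal_window)
  n_sel <- spec$ppm >= min(noise_window) & spec$ppm <= max(noise_window)
  if (!any(s_sel) || sum(n_sel) < 2L) stop("window error: empty window")
  noise <- spec$intensity[n_sel]
  rms <- sqrt(mean((noise - mean(noise))^2))
  if (rms <= 0) stop("degenerate-noise error: noise window has zero variance")
  max(abs(spec$intensity[s_sel])) / (divisor * rms)
}

#' Process a free-induction decay into a spectrum
#'
#' Exponential apodization `exp(-pi * LB * t)`, zero-filling, discrete Fourier
#' transform (real part), and optional polynomial (degree <= 2) baseline
#' correction fitted on declared signal-free regions.
#'
#' @param fid Complex (or numeric) time-domain array, length >= 2.
#' @param sweep_width_hz Spectral width (Hz).
#' @param frequency_mhz Spectrometer frequency (MHz), to express the axis in
#'   ppm.
#' @param center_ppm Carrier position (ppm) at the centre of the spectrum.
#' @param line_broadening_hz Exponential line broadening (Hz, default 3).
#' @param zero_fill Target number of points (>= length of `fid`).
#' @param baseline_regions Optional list of ppm intervals declared
#'   signal-free; a degree-2 polynomial fitted there is subtracted.
#' @return A `spectrum1d` with a descending ppm axis.
#' @export
process_fid <- function(fid, sweep_width_hz, frequency_mhz, center_ppm = 4.7,
                        line_broadening_hz = 3, zero_fill = length(fid),
                        baseline_regions = NULL) {
  n <- length(fid)
  if (n < 2L) stop("fid must have length >= 2")
  if (zero_fill < n)
    stop("config error: zero_fill (", zero_fill,
         ") smaller than fid length (", n, ")")
  t <- (seq_len(n) - 1) / sweep_width_hz
  apod <- fid * exp(-pi * line_broadening_hz * t)
  padded <- c(apod, rep(0 + 0i, zero_fill - n))
  spec <- stats::fft(padded)
  # DFT bin k holds frequency k*SW/N for k < N/2, aliased negative above
  k <- 0:(zero_fill - 1)
  half <- ceiling(zero_fill / 2)
  freq <- ifelse(k < half, k, k - zero_fill) * sweep_width_hz / zero_fill
  ppm <- center_ppm + freq / frequency_mhz
  ord <- order(ppm, decreasing = TRUE)
  out <- spectrum1d(ppm[ord], Re(spec)[ord],
                    meta = list(sweep_width_hz = sweep_width_hz,
                                frequency_mhz = frequency_mhz,
                                line_broadening_hz = line_broadening_hz))
  if (!is.null(baseline_regions)) {
    sel <- Reduce(`|`, lapply(baseline_regions, function(w)
      out$ppm >= min(w) & out$ppm <= max(w)))
    if (sum(sel) < 3L) stop("baseline regions cover too few points")
    fitdat <- data.frame(x = out$ppm[sel], y = out$intensity[sel])
    bl <- stats::lm(y ~ stats::poly(x, 2, raw = TRUE), data = fitdat)
    pred <- stats::predict(bl, newdata = data.frame(x = out$ppm))
    out$intensity <- out$intensity - as.numeric(pred)
  }
  out
}

#' Amplification factors measured from on/off-resonance spectra
#'
#' Full spectral path: difference spectrum, per-proton window integration of
#' the reference (off-resonance) and difference spectra, SNR estimation in
#' the difference spectrum, and the amplification factor with its
#' uncertainty.
#'
#' @param off,on `spectrum1d` objects on identical axes.
#' @param windows Named list of ppm integration windows, one per proton.
#' @param noise_window Signal-free ppm interval for noise estimation.
#' @param L,P Ligand and protein concentrations (same units).
#' @param background Optional background `spectrum1d`, subtracted from the
#'   reference spectrum before integration (the difference spectrum is
#'   computed from `off - on` and is background-free when the background is
#'   common to both).
#' @return Data frame with `proton`, `I0`, `Idiff`, `SNR`, `ASTD`, `sigma`.
#' @export
std_af_from_spectra <- function(off, on, windows, noise_window, L, P,
                                background = NULL) {
  dsp <- difference_spectrum(off, on)
  ref <- if (is.null(background)) off
         else spectrum1d(off$ppm, off$intensity - background$intensity,
                         off$meta)
  rows <- lapply(names(windows), function(lab) {
    w <- windows[[lab]]
    I0 <- integrate_peak(ref, w)
    Idiff <- integrate_peak(dsp, w)
    snr <- estimate_snr(dsp, w, noise_window)
    astd <- compute_std_af(I0 = I0, Idiff = Idiff, L = L, P = P)
    data.frame(proton = lab, I0 = I0, Idiff = Idiff, SNR = snr,
               ASTD = astd, sigma = compute_af_error(astd, snr))
  })
  do.call(rbind, rows)
}

#' Read an STD peak table
#'
#' Instrument-agnostic CSV with one row per proton signal: columns `proton`,
#' `window_lo_ppm`, `window_hi_ppm`, `I0`, `Idiff`, `SNR`.
#'
#' @param path CSV path.
#' @return Data frame validated for the required columns.
#' @export
read_peak_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("proton", "window_lo_ppm", "window_hi_ppm", "I0", "Idiff", "SNR")
  if (!all(need %in% names(tab)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$I0 <= 0)) stop("I0 must be > 0 for every proton")
  if (any(!is.na(tab$SNR) & tab$SNR <= 0)) stop("SNR must be > 0 when provided")
  tab
}

#' Amplification factors from a peak table
#'
#' Convenience wrapper: per-proton ASTD, sigma, normalization and binning
#' from a [read_peak_table()] data frame and the sample concentrations.
#'
#' @param peaks Peak table data frame.
#' @param L,P Ligand and protein concentrations (same units).
#' @param reference Reference proton label (default `"a"`).
#' @return An `std_af_result` data frame.
#' @export
std_af_from_peaks <- function(peaks, L, P, reference = "a") {
  af <- data.frame(proton = peaks$proton,
                   ASTD = mapply(function(i0, idiff)
                     compute_std_af(I0 = i0, Idiff = idiff, L = L, P = P),
                     peaks$I0, peaks$Idiff))
  af$sigma <- 0
  ok <- !is.na(peaks$SNR)
  af$sigma[ok] <- compute_af_error(af$ASTD[ok], peaks$SNR[ok])
  normalize_af(af, reference = reference)
}
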