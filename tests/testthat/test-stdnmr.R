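flat_spec <- function(vals, n = length(vals), lo = 0, hi = 10) {
  spectrum1d(seq(hi, lo, length.out = n), vals)
}

test_that("difference spectrum subtracts and refuses mismatched axes", {
  ppm <- seq(10, 0, length.out = 101)
  off <- spectrum1d(ppm, rep(2, 101))
  on <- spectrum1d(ppm, rep(2, 101))
  expect_equal(difference_spectrum(off, on)$intensity, rep(0, 101))

  peak <- exp(-(ppm - 5)^2 * 50)
  off2 <- spectrum1d(ppm, 2 + 0.3 * peak)
  d <- difference_spectrum(off2, on)
  expect_equal(d$intensity, 0.3 * peak, tolerance = 1e-12)

  bg <- spectrum1d(ppm, 0.5 * exp(-(ppm - 2)^2))
  off3 <- spectrum1d(ppm, off2$intensity + bg$intensity)
  d2 <- difference_spectrum(off3, on, background = bg)
  expect_equal(d2$intensity, 0.3 * peak, tolerance = 1e-12)

  other <- spectrum1d(seq(10, 0.1, length.out = 101), rep(2, 101))
  expect_error(difference_spectrum(off, other), "alignment error")
})

test_that("peak integration is a sign-preserving trapezoid", {
  # rectangle of height 1 over 0.1 ppm
  ppm <- seq(1, 0, by = -0.001)
  y <- as.numeric(ppm >= 0.45 & ppm <= 0.55)
  s <- spectrum1d(ppm, y)
  expect_equal(integrate_peak(s, c(0.44, 0.56)), 0.1, tolerance = 0.02)
  expect_equal(integrate_peak(spectrum1d(ppm, -y), c(0.44, 0.56)), -0.1,
               tolerance = 0.02)
  expect_error(integrate_peak(s, c(5, 6)), "window error")
})

test_that("a unit-area Lorentzian integrates to ~1 over +-50 half-widths", {
  gamma <- 0.004
  ppm <- seq(12, 0, length.out = 2^15)
  x0 <- 6
  y <- (1 / pi) * gamma / ((ppm - x0)^2 + gamma^2)
  s <- spectrum1d(ppm, y)
  int <- integrate_peak(s, x0 + c(-50, 50) * gamma)
  # closed form: (2/pi) atan(50) = 0.98727
  expect_gt(int, 0.985)
  expect_lt(int, 1.0)
})

test_that("the amplification factor and its error follow the defining formulas", {
  expect_equal(compute_std_af(I0 = 1000, Idiff = 20, L = 2000, P = 40), 1.0)
  expect_equal(compute_std_af(I0 = 500, Idiff = 0, L = 2000, P = 40), 0)
  expect_equal(compute_std_af(I0 = 100, Idiff = 10, L = 2000, P = 40), 5.0)
  # Isat convention: Idiff = I0 - Isat
  expect_equal(compute_std_af(I0 = 1000, Isat = 980, L = 2000, P = 40), 1.0)
  expect_error(compute_std_af(I0 = 0, Idiff = 1, L = 1, P = 1), "domain error")
  expect_error(compute_std_af(I0 = 1, Idiff = 1, L = 1, P = 0), "domain error")

  expect_equal(compute_af_error(1.0, 20), 0.05)
  expect_equal(compute_af_error(5.0, 10), 0.5)
  expect_lt(compute_af_error(1.0, 1e9), 1e-8)
  expect_error(compute_af_error(1.0, 0), "domain error")
})

test_that("normalization sets the reference to 100% and propagates errors in quadrature", {
  af <- data.frame(proton = c("a", "b", "c"),
                   ASTD = c(1.0, 1.5, 0.4),
                   sigma = c(0.04, 0.045, 0.02))
  out <- normalize_af(af, reference = "a")
  expect_equal(out$normalized_pct[out$proton == "a"], 100)
  expect_equal(out$normalized_pct[out$proton == "b"], 150)
  # 3-4-5 quadrature: rel errors 0.03 and 0.04 combine to 0.05
  af2 <- data.frame(proton = c("a", "b"), ASTD = c(1, 2),
                    sigma = c(0.04, 0.03 * 2))
  out2 <- normalize_af(af2, "a")
  expect_equal(out2$sigma_pct[out2$proton == "b"] /
               out2$normalized_pct[out2$proton == "b"], 0.05)
  # zero errors propagate to zero
  af3 <- data.frame(proton = c("a", "b"), ASTD = c(1, 1.5), sigma = c(0, 0))
  out3 <- normalize_af(af3, "a")
  expect_equal(out3$normalized_pct[2], 150)
  expect_equal(out3$sigma_pct[2], 0)
  expect_error(normalize_af(data.frame(proton = "a", ASTD = 0, sigma = 0)),
               "normalization error")
})

test_that("interaction binning covers [0, Inf) with the documented boundaries", {
  expect_equal(bin_interaction(45), "weak")
  expect_equal(bin_interaction(50), "weak")          # boundary: <= 50
  expect_equal(bin_interaction(50.1), "weak-moderate")
  expect_equal(bin_interaction(99.9), "weak-moderate")
  expect_equal(bin_interaction(100), "moderate")     # reference sits here
  expect_equal(bin_interaction(120), "moderate")
  expect_equal(bin_interaction(150), "moderate")
  expect_equal(bin_interaction(160), "strong")
  expect_equal(bin_interaction(0), "weak")
  expect_error(bin_interaction(-1), "domain error")
  # total function on a grid
  for (p in seq(0, 400, by = 7))
    expect_true(bin_interaction(p) %in%
                c("weak", "weak-moderate", "moderate", "strong"))
})

test_that("SNR estimation follows the peak over twice-RMS-noise convention", {
  ppm <- seq(10, 0, length.out = 1001)
  y <- rep(0, 1001)
  y[ppm >= 4.9 & ppm <= 5.1] <- 1.0
  # deterministic 'noise': alternating +-0.025 has RMS 0.025
  noise_sel <- ppm >= 8 & ppm <= 9
  y[noise_sel] <- rep(c(0.025, -0.025), length.out = sum(noise_sel))
  s <- spectrum1d(ppm, y)
  expect_equal(estimate_snr(s, c(4.8, 5.2), c(8, 9)), 20, tolerance = 1e-3)
  flat <- spectrum1d(ppm, rep(1, 1001))
  expect_error(estimate_snr(flat, c(4.8, 5.2), c(8, 9)), "degenerate-noise")
  expect_error(estimate_snr(s, c(4.8, 5.2), c(5.0, 6)), "disjoint")
})

test_that("FID processing puts the peak at the planted frequency with ~LB broadening", {
  sw <- 4800; mhz <- 800; n <- 4096
  t <- (0:(n - 1)) / sw
  f0 <- 800   # Hz offset from carrier => +1 ppm at 800 MHz
  r2 <- 10    # natural linewidth f0/pi ~ 3.18 Hz
  fid <- exp(2i * pi * f0 * t) * exp(-r2 * t)
  sp <- process_fid(fid, sweep_width_hz = sw, frequency_mhz = mhz,
                    center_ppm = 4.7, line_broadening_hz = 3,
                    zero_fill = 65536)
  pk <- sp$ppm[which.max(sp$intensity)]
  expect_equal(pk, 4.7 + 1, tolerance = 0.005)
  # FWHM: natural r2/pi plus LB, in Hz
  half <- max(sp$intensity) / 2
  above <- range(sp$ppm[sp$intensity > half])
  fwhm_hz <- diff(above) * mhz
  expect_equal(fwhm_hz, r2 / pi + 3, tolerance = 0.4)

  expect_equal(max(abs(process_fid(rep(0 + 0i, 64), sw, mhz)$intensity)), 0)
  expect_error(process_fid(fid, sw, mhz, zero_fill = n / 2), "config error")
})

test_that("ASTD is linear in L/P and in Idiff/I0", {
  base <- compute_std_af(I0 = 1000, Idiff = 20, L = 2000, P = 40)
  expect_equal(compute_std_af(I0 = 1000, Idiff = 40, L = 2000, P = 40),
               2 * base)
  expect_equal(compute_std_af(I0 = 1000, Idiff = 20, L = 4000, P = 40),
               2 * base)
})

test_that("peak tables round-trip through CSV and drive the AF pipeline", {
  tab <- data.frame(proton = c("a", "b"),
                    window_lo_ppm = c(8.0, 5.8), window_hi_ppm = c(8.2, 6.0),
                    I0 = c(1000, 1000), Idiff = c(20, 18), SNR = c(30, 25))
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  peaks <- read_peak_table(f)
  res <- std_af_from_peaks(peaks, L = 2000, P = 40)
  expect_equal(res$ASTD, c(1.0, 0.9))
  expect_equal(res$normalized_pct, c(100, 90))
  expect_equal(res$bin, c("moderate", "weak-moderate"))
  bad <- tab; bad$I0[1] <- -1
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_peak_table(f), "I0")
})
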