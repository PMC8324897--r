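#' Convert reconstructed refractive-index values to mass density
#'
#' Phase-contrast nanotomography reconstructions provide values
#' `omega = -(2 pi / lambda) * delta_dec` (in 1/cm) of the refractive index
#' decrement. Under the Guinier approximation with a mass-to-charge ratio
#' M/Z of 2, `delta_dec = 1.3e-6 * rho * lambda^2` (lambda in Angstrom), so
#' the local mass density is
#' `rho = -(1 / (2 pi)) * omega / (1.3 * lambda) * 1e-2` g/cm^3. Local
#' tomography truncation shifts all grey values by a constant; the global
#' `offset` (estimated from a background region) is subtracted from `omega`
#' before conversion, so pure background maps to zero density.
#'
#' @param omega reconstruction grey value(s) in 1/cm.
#' @param wavelength X-ray wavelength in Angstrom (0.73 for a 17.05 keV
#'   beam).
#' @param offset background grey value in 1/cm (default 0).
#' @return Mass density in g/cm^3 (vectorised).
#' @seealso [omega_from_density()] for the forward model.
#' @export
#' @examples
#' omega <- omega_from_density(1.64, 0.73)
#' density_from_omega(omega, 0.73) # exactly 1.64
density_from_omega <- function(omega, wavelength, offset = 0) {
  stopifnot(wavelength > 0)
  -(omega - offset) / (2 * pi * 1.3 * wavelength) * 1e-2
}

#' Forward Guinier model: density to reconstruction grey value
#'
#' @param rho mass density in g/cm^3.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param offset background grey value in 1/cm added to the result.
#' @return Grey value omega in 1/cm (negative for positive density).
#' @export
omega_from_density <- function(rho, wavelength, offset = 0) {
  stopifnot(wavelength > 0)
  -rho * 2 * pi * 1.3 * wavelength * 1e2 + offset
}

#' Gaussian fit of a grey-value histogram
#'
#' Locates the histogram peak, fits a Gaussian by Levenberg-Marquardt least
#' squares (initialised from the peak position, a moment estimate of the
#' width and the peak height) and reports mean, FWHM and the standard
#' deviation
#' `sigma = FWHM / (2 sqrt(2 log 2))`.
#'
#' @param hist a data frame with columns `centre` (strictly increasing bin
#'   centres) and `count` (non-negative).
#' @return List with `mean`, `fwhm`, `sigma`, `height` and the `fit` object.
#' @export
fit_histogram_gaussian <- function(hist) {
  stopifnot(all(c("centre", "count") %in% names(hist)),
            all(diff(hist$centre) > 0), all(hist$count >= 0))
  x <- hist$centre; y <- hist$count
  k <- which.max(y)
  if (y[k] <= 0) stop("no peak found in histogram")
  mu0 <- x[k]
  s0 <- sqrt(sum(y * (x - mu0)^2) / sum(y))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 10
  h0 <- y[k]
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(h = h0, m = mu0, s = s0),
      fn = function(p) y - p$h * exp(-(x - p$m)^2 / (2 * p$s^2)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit failed: ", conditionMessage(e)))
  if (!fit$info %in% 1:3)
    stop("Gaussian fit failed: ", fit$message)
  cf <- fit$par
  sigma <- abs(cf$s)
  list(mean = cf$m, fwhm = sigma * 2 * sqrt(2 * log(2)),
       sigma = sigma, height = cf$h, fit = fit)
}

#' Fibril diameter from grey-value line profiles
#'
#' Estimates the fibril diameter (fibril plus its share of extrafibrillar
#' matrix, i.e. the lateral period of the fibril packing) from 1D line
#' profiles taken perpendicular to the fibril axis. Two estimators per
#' profile:
#' * FFT: dominant non-DC peak of the amplitude spectrum of the de-meaned
#'   profile, sharpened by parabolic interpolation of the log-amplitudes of
#'   the three bins around the peak (profiles contain few periods, so raw
#'   bin resolution is insufficient); returns the corresponding period.
#'   Profiles whose dominant peak does not rise above the spectral noise
#'   floor (median amplitude times `snr_min`) yield `NA`.
#' * Local minima: spacings between consecutive local minima of the profile
#'   (darker extrafibrillar matrix between fibrils), one width per fibril.
#'
#' Per-method mean and standard deviation are combined as their plain
#' average with the error propagated through the variances,
#' `sqrt((sd_fft^2 + sd_minima^2) / 2)`.
#'
#' @param profiles a single data frame or a list of data frames with columns
#'   `position` (uniformly spaced, in nm) and `value`.
#' @param snr_min required ratio of the dominant FFT peak to the median
#'   spectral amplitude (default 3).
#' @return List with `d_combined`, `error`, `d_fft`, `sd_fft`, `d_minima`,
#'   `sd_minima`, and the per-profile FFT estimates and minima widths.
#' @export
fibril_diameter <- function(profiles, snr_min = 3) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  fft_est <- vapply(profiles, profile_period_fft, numeric(1),
                    snr_min = snr_min)
  widths <- unlist(lapply(profiles, profile_minima_widths))
  d_fft <- mean(fft_est, na.rm = TRUE)
  sd_fft <- stats::sd(fft_est[!is.na(fft_est)])
  d_min <- mean(widths)
  sd_min <- stats::sd(widths)
  if (is.na(sd_fft)) sd_fft <- 0
  if (is.na(sd_min)) sd_min <- 0
  list(d_combined = mean(c(d_fft, d_min)),
       error = sqrt((sd_fft^2 + sd_min^2) / 2),
       d_fft = d_fft, sd_fft = sd_fft,
       d_minima = d_min, sd_minima = sd_min,
       fft_estimates = fft_est, minima_widths = widths)
}

# dominant period of one profile by FFT with parabolic peak interpolation
profile_period_fft <- function(profile, snr_min = 3) {
  x <- profile$position; y <- profile$value
  stopifnot(length(x) >= 8)
  dx <- diff(x)
  if (diff(range(dx)) > 1e-6 * mean(dx))
    stop("line profile must be uniformly spaced")
  dx <- mean(dx)
  n <- length(y)
  amp <- Mod(stats::fft(y - mean(y)))[seq_len(floor(n / 2))]
  amp[1] <- 0 # DC residual
  k <- which.max(amp)
  if (k <= 1L || amp[k] < snr_min * stats::median(amp[amp > 0]))
    return(NA_real_)
  # parabolic interpolation on log-amplitude around the peak bin
  kk <- k
  if (k > 2L && k < length(amp)) {
    la <- log(pmax(amp[(k - 1):(k + 1)], .Machine$double.xmin))
    den <- la[1] - 2 * la[2] + la[3]
    if (is.finite(den) && den < 0)
      kk <- k + 0.5 * (la[1] - la[3]) / den
  }
  freq <- (kk - 1) / (n * dx)
  1 / freq
}

# widths between consecutive local minima of one profile; only minima
# separated by an excursion above the profile midline count, which makes the
# detection robust to noise in the flat inter-fibril valleys
profile_minima_widths <- function(profile) {
  y <- profile$value; x <- profile$position
  midline <- (max(y) + min(y)) / 2
  above <- y > midline
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peak_runs <- which(r$values)
  if (length(peak_runs) < 2L) return(numeric(0))
  # deepest point between consecutive fibril cores
  mins <- vapply(seq_len(length(peak_runs) - 1L), function(i) {
    lo <- ends[peak_runs[i]]
    hi <- starts[peak_runs[i + 1L]]
    seg <- lo:hi
    x[seg[which.min(y[seg])]]
  }, numeric(1))
  if (length(mins) < 2L) return(numeric(0))
  diff(mins)
}

#' Fit the recruitment sigmoid to contact-area fractions
#'
#' Non-linear least-squares fit of
#' `xi(eps) = 1 / (1 + exp(-(eps - mu) / beta))` to a series of contact-area
#' fractions versus apparent strain. Start values: `mu` from linear
#' interpolation of the strain at fraction 0.5, `beta` as a quarter of the
#' 0.25-0.75 rise width. For degenerate, step-like series `beta` collapses
#' towards zero; the fit is then flagged in the goodness report rather than
#' failed.
#'
#' @param series data frame with columns `strain` and `fraction` (in
#'   `[0, 1]`, non-decreasing); at least 4 points spanning the rise.
#' @return List with `mu`, `beta`, `residual_sd`, `converged`, and
#'   `degenerate` (`TRUE` when the fitted rise width is below the strain
#'   grid spacing).
#' @export
#' @examples
#' s <- make_area_series(0.0215, 0.00635, n_points = 30)
#' fit_recruitment(s)$mu
fit_recruitment <- function(series) {
  stopifnot(all(c("strain", "fraction") %in% names(series)))
  series <- series[order(series$strain), , drop = FALSE]
  if (nrow(series) < 4L)
    stop("need at least 4 points spanning the sigmoid rise")
  eps <- series$strain; fr <- series$fraction
  q <- function(p) {
    i <- which(fr >= p)[1]
    if (is.na(i)) return(max(eps))
    if (i == 1L) return(eps[1])
    stats::approx(fr[(i - 1):i], eps[(i - 1):i], xout = p, ties = "ordered")$y
  }
  mu0 <- q(0.5)
  beta0 <- max((q(0.75) - q(0.25)) / 4, diff(range(eps)) / (4 * length(eps)))
  beta_min <- min(diff(eps)) / 1e4  # lower bound keeps the step limit finite
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(mu = mu0, beta = beta0),
      fn = function(p) fr - 1 / (1 + exp(-(eps - p$mu) / p$beta)),
      lower = c(-Inf, beta_min),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:3)
    stop("recruitment fit did not converge; residual sd at start values: ",
         signif(stats::sd(fr - 1 / (1 + exp(-(eps - mu0) / beta0))), 3))
  beta_hat <- abs(fit$par$beta)
  list(mu = fit$par$mu, beta = beta_hat,
       residual_sd = stats::sd(fit$fvec),
       converged = fit$info %in% 1:3,
       degenerate = beta_hat < min(diff(eps)) / 4,
       fit = fit)
}
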