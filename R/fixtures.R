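#' Synthetic grey-value line profiles
#'
#' Generates quasi-periodic 1D line profiles emulating sagittal nanotomography
#' sections across a fibril bundle: one Gaussian intensity bump per fibril at
#' spacing `period`, sampled at the instrument voxel size, plus additive
#' Gaussian noise.
#'
#' @param period fibril spacing in nm.
#' @param n_profiles number of profiles.
#' @param noise_cov noise standard deviation as a fraction of the bump
#'   amplitude (default 0).
#' @param n_periods fibril count per profile (default 6).
#' @param pixel_nm sampling step in nm (default 20, the isotropic voxel
#'   size).
#' @param seed optional integer seed.
#' @return A list of data frames with columns `position` (nm) and `value`.
#' @export
#' @examples
#' pr <- make_line_profiles(224, n_profiles = 1)
#' fibril_diameter(pr)$d_combined
make_line_profiles <- function(period, n_profiles = 1, noise_cov = 0,
                               n_periods = 6, pixel_nm = 20, seed = NULL) {
  stopifnot(period > 2 * pixel_nm, n_profiles >= 1, n_periods >= 3)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_profiles), function(i) {
    len <- (n_periods + 1) * period
    pos <- seq(0, len, by = pixel_nm)
    centres <- period / 2 + period * (0:n_periods)
    val <- rowSums(vapply(centres,
                          function(c0) exp(-(pos - c0)^2 / (2 * (period / 5)^2)),
                          numeric(length(pos))))
    if (noise_cov > 0) val <- val + stats::rnorm(length(val), 0, noise_cov)
    data.frame(position = pos, value = val)
  })
}

#' Synthetic contact-area-fraction series
#'
#' Evaluates the recruitment sigmoid on a strain grid, optionally with
#' multiplicative noise, emulating the contact-area fractions extracted from
#' cross-sectional tomography slices.
#'
#' @param mu,beta sigmoid midpoint and shape parameter.
#' @param n_points number of strain values (at least 4).
#' @param noise multiplicative noise coefficient of variation (default 0).
#' @param strain_max largest strain of the grid (default `mu + 6 * beta`,
#'   covering the full rise).
#' @param seed optional integer seed.
#' @return Data frame with columns `strain` and `fraction`.
#' @export
make_area_series <- function(mu, beta, n_points = 30, noise = 0,
                             strain_max = mu + 6 * beta, seed = NULL) {
  stopifnot(beta > 0, n_points >= 4)
  if (!is.null(seed)) set.seed(seed)
  eps <- seq(0, strain_max, length.out = n_points)
  fr <- recruitment_fraction(eps, mu, beta)
  if (noise > 0) fr <- pmin(pmax(fr * (1 + stats::rnorm(n_points, 0, noise)), 0), 1)
  data.frame(strain = eps, fraction = fr)
}

#' Synthetic grey-value histogram
#'
#' Builds a binned grey-value histogram in reconstruction units (1/cm) whose
#' implied density distribution is Gaussian with the requested mean and
#' standard deviation, for exercising the histogram and density-calibration
#' analysis without tomography data.
#'
#' @param mean_density,sd_density density distribution in g/cm^3.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param offset background grey value in 1/cm.
#' @param n_samples number of voxel samples drawn (default 20000).
#' @param n_bins number of histogram bins (default 80).
#' @param seed optional integer seed.
#' @return Data frame with columns `centre` (omega, 1/cm) and `count`.
#' @export
make_grey_histogram <- function(mean_density, sd_density, wavelength = 0.73,
                                offset = 0, n_samples = 20000, n_bins = 80,
                                seed = NULL) {
  stopifnot(sd_density >= 0, n_bins >= 10)
  if (!is.null(seed)) set.seed(seed)
  rho <- stats::rnorm(n_samples, mean_density, sd_density)
  omega <- omega_from_density(rho, wavelength, offset)
  h <- graphics::hist(omega, breaks = n_bins, plot = FALSE)
  data.frame(centre = h$mids, count = h$counts)
}
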