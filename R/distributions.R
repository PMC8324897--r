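#' Statistical distribution of a material parameter
#'
#' Describes how a material parameter varies between the fibrils of the
#' bundle. Variation is specified by the coefficient of variation
#' `cov = sd / mean`; the base case for the tissue is `cov = 0.15`, and the
#' sensitivity analysis spans 0.01 to 0.30. Families:
#' `"normal"` (the default), `"skew-normal"` (Azzalini shape parameter
#' `skew`; location and scale are chosen so that mean and standard deviation
#' match the requested `mean` and `cov * mean`), and `"degenerate"`
#' (`cov = 0`, every element identical).
#'
#' Sampled values must respect the truncation policy: draws at or below
#' `truncate_at` times the mean are rejected and redrawn (moduli and strains
#' must stay strictly positive). More than 1000 consecutive rejections raise
#' an error, since then the distribution is incompatible with its bounds.
#'
#' @param family `"normal"`, `"skew-normal"` or `"degenerate"`.
#' @param cov coefficient of variation (non-negative; 0 forces the
#'   degenerate family).
#' @param skew shape parameter of the skew-normal family (0 recovers the
#'   normal).
#' @param truncate_at lower bound for valid draws, as a fraction of the
#'   mean. Default 0 (strictly positive draws).
#' @return An object of class `"distribution_spec"`.
#' @export
distribution_spec <- function(family = c("normal", "skew-normal", "degenerate"),
                              cov = 0.15, skew = 0, truncate_at = 0) {
  family <- match.arg(family)
  stopifnot(cov >= 0, truncate_at >= 0, truncate_at < 1)
  if (cov == 0) family <- "degenerate"
  if (family == "degenerate" && cov != 0)
    stop("degenerate family requires cov = 0")
  structure(list(family = family, cov = cov, skew = skew,
                 truncate_at = truncate_at),
            class = "distribution_spec")
}

# one batch of draws around `mean` according to the spec (no truncation here)
draw_values <- function(n, mean, spec) {
  sd <- spec$cov * abs(mean)
  switch(spec$family,
    degenerate = rep(mean, n),
    normal = stats::rnorm(n, mean, sd),
    `skew-normal` = {
      # Azzalini skew-normal via the conditioning representation, re-centred
      # and re-scaled to the requested mean and sd
      a <- spec$skew
      delta <- a / sqrt(1 + a^2)
      z0 <- abs(stats::rnorm(n))
      z1 <- stats::rnorm(n)
      z <- delta * z0 + sqrt(1 - delta^2) * z1
      mz <- delta * sqrt(2 / pi)
      sz <- sqrt(1 - mz^2)
      mean + sd * (z - mz) / sz
    })
}

# truncated sampling by rejection, per the distribution's truncation policy
sample_parameter <- function(n, mean, spec) {
  lower <- spec$truncate_at * mean
  valid <- function(v) is.finite(v) & v > lower
  x <- draw_values(n, mean, spec)
  bad <- which(!valid(x))
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > 1000L)
      stop("more than 1000 consecutive rejected draws: distribution ",
           "(mean = ", mean, ", cov = ", spec$cov,
           ") is incompatible with its lower bound ", lower)
    x[bad] <- draw_values(length(bad), mean, spec)
    bad <- bad[!valid(x[bad])]
  }
  x
}

#' Sample the per-element material properties of a fibril bundle
#'
#' Draws the statistically varied parameters of `n` rheological elements
#' independently per element and per parameter. Two modes:
#' * `"nested"` (default): the constituent parameters (`E_min`, `mu_col`,
#'   `mu_ef`) are sampled and each element's fibril and apparent moduli are
#'   computed through the two nested shear-lag formulas from its own draws.
#' * `"direct"`: the fibril modulus `E_mc` is sampled around its tabulated
#'   mean and the apparent modulus follows from the fibre-level shear lag
#'   with the element's sampled `mu_ef`.
#'
#' Yield strains, hardening moduli and ultimate strains are always sampled
#' directly around their means.
#'
#' @param params a [fibre_params()] object holding the mean values.
#' @param n number of elements.
#' @param spec a [distribution_spec()] applied to every varied parameter.
#' @return A data frame with one row per element: sampled constituent
#'   parameters, derived moduli `E_mc` and `E_app`, and the plasticity
#'   parameters. Means over elements converge to the base values.
#' @export
sample_elements <- function(params, n, spec = params$dist) {
  stopifnot(n >= 1)
  sl <- params$shear_lag
  pl <- params$plasticity
  el <- data.frame(
    E_min  = sample_parameter(n, sl$E_min, spec),
    mu_col = sample_parameter(n, sl$mu_col, spec),
    mu_ef  = sample_parameter(n, sl$mu_ef, spec),
    eps_y_mc = sample_parameter(n, pl$eps_y_mc, spec),
    eps_y_ef = sample_parameter(n, pl$eps_y_ef, spec),
    chi_mc = sample_parameter(n, pl$chi_mc, spec),
    chi_ef = sample_parameter(n, pl$chi_ef, spec),
    eps_ult_mc = sample_parameter(n, pl$eps_ult_mc, spec),
    eps_ult_ef = sample_parameter(n, pl$eps_ult_ef, spec)
  )
  if (identical(params$sampling, "direct")) {
    E_mc_base <- params$E_mc %||% fibril_modulus(sl)
    el$E_mc <- sample_parameter(n, E_mc_base, spec)
  } else {
    el$E_mc <- shear_lag_modulus(sl$phi_min_intra, el$E_min, sl$gamma_min,
                                 el$mu_col)
  }
  el$E_app <- shear_lag_modulus(sl$phi_mc, el$E_mc, sl$gamma_mc, el$mu_ef)
  el
}
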