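#' Elastic parameters of the two nested shear-lag composites
#'
#' Collects the constituent elastic constants entering the nested shear-lag
#' description of a mineralised collagen fibre: a fibril is a staggered
#' composite of stiff mineral platelets in a compliant collagen matrix, and
#' the fibre is a composite of stiff fibrils in a compliant extrafibrillar
#' matrix. Load is transferred to the stiff phase by interfacial shear only.
#'
#' The intrafibrillar mineral fraction `phi_min_intra` is the mineral volume
#' fraction referred to the fibril volume. By default it is derived from the
#' tissue-level fraction as `phi_min / phi_mc`, i.e. all mineral is assumed
#' intrafibrillar; this convention reproduces the canonical fibril modulus of
#' about 20.4 GPa to about 1 percent. Set `mineral_intrafibrillar = FALSE`
#' to use the tissue-level fraction directly.
#'
#' @param E_min mineral Young's modulus in GPa (default 114).
#' @param gamma_min mineral platelet aspect ratio (default 25).
#' @param mu_col collagen shear modulus in GPa (default 1.58).
#' @param gamma_mc fibril aspect ratio (default 200).
#' @param mu_ef extrafibrillar-matrix shear modulus in GPa (default 0.003).
#' @param comp a [composition()] object (default `composition(0.29)`).
#' @param mineral_intrafibrillar logical; if `TRUE` (default) evaluate the
#'   fibril-level shear lag with `phi_min / phi_mc`.
#' @return An object of class `"shear_lag_params"`.
#' @export
#' @examples
#' p <- shear_lag_params()
#' fibril_modulus(p) # about 20.2 GPa
#' fibre_modulus(p)  # about 15.6 GPa
shear_lag_params <- function(E_min = 114, gamma_min = 25, mu_col = 1.58,
                             gamma_mc = 200, mu_ef = 0.003,
                             comp = composition(0.29),
                             mineral_intrafibrillar = TRUE) {
  stopifnot(E_min > 0, mu_col > 0, mu_ef > 0, gamma_min > 1, gamma_mc > 1)
  phi_min_intra <- if (mineral_intrafibrillar) comp$phi_min / comp$phi_mc
                   else comp$phi_min
  if (phi_min_intra <= 0 || phi_min_intra >= 1)
    stop("intrafibrillar mineral fraction must lie in (0, 1); got ",
         signif(phi_min_intra, 4))
  p <- structure(list(E_min = E_min, gamma_min = gamma_min, mu_col = mu_col,
                      gamma_mc = gamma_mc, mu_ef = mu_ef,
                      phi_min_intra = phi_min_intra, phi_mc = comp$phi_mc),
                 class = "shear_lag_params")
  if (E_min < 10 * mu_col)
    warning("stiff/compliant shear-lag assumption strained: E_min < 10 * mu_col")
  E_mc <- fibril_modulus(p)
  if (E_mc < 10 * mu_ef)
    warning("stiff/compliant shear-lag assumption strained: E_mc < 10 * mu_ef")
  p
}

#' @export
print.shear_lag_params <- function(x, ...) {
  cat("Nested shear-lag parameters\n")
  cat(sprintf("  mineral:  E = %g GPa, aspect ratio %g, phi (intrafibrillar) = %.4f\n",
              x$E_min, x$gamma_min, x$phi_min_intra))
  cat(sprintf("  collagen: mu = %g GPa\n", x$mu_col))
  cat(sprintf("  fibril:   aspect ratio %g, phi = %.3f -> E = %.3f GPa\n",
              x$gamma_mc, x$phi_mc, fibril_modulus(x)))
  cat(sprintf("  EFM:      mu = %g GPa -> fibre E = %.3f GPa\n",
              x$mu_ef, fibre_modulus(x)))
  invisible(x)
}

# shared kernel of the two shear-lag levels: series compliance of axial
# stretching of the stiff phase and shear transfer through the matrix
shear_lag_modulus <- function(phi, E_stiff, gamma, mu_matrix) {
  if (any(phi <= 0) || any(phi >= 1))
    stop("volume fraction must lie in (0, 1)")
  if (any(E_stiff <= 0) || any(mu_matrix <= 0))
    stop("moduli must be positive")
  1 / (1 / (phi * E_stiff) + 4 * (1 - phi) / (phi^2 * gamma^2 * mu_matrix))
}

#' Apparent Young's modulus of the mineralised collagen fibril
#'
#' Shear-lag estimate for mineral platelets of aspect ratio `gamma_min` in a
#' collagen matrix:
#' `E_mc = (1 / (phi * E_min) + 4 (1 - phi) / (phi^2 gamma_min^2 mu_col))^-1`
#' with `phi` the intrafibrillar mineral fraction. The first compliance term
#' is axial stretching of the mineral, the second shear transfer through the
#' collagen.
#'
#' @param p a [shear_lag_params()] object.
#' @return Modulus in GPa (vectorised over vector-valued parameter fields).
#' @export
fibril_modulus <- function(p) {
  shear_lag_modulus(p$phi_min_intra, p$E_min, p$gamma_min, p$mu_col)
}

#' Apparent Young's modulus of the mineralised collagen fibre
#'
#' Second shear-lag level: fibrils of modulus `E_mc` and aspect ratio
#' `gamma_mc` embedded in the extrafibrillar matrix,
#' `E = (1 / (phi_mc E_mc) + 4 (1 - phi_mc) / (phi_mc^2 gamma_mc^2 mu_ef))^-1`.
#'
#' @param p a [shear_lag_params()] object.
#' @param E_mc fibril modulus in GPa; defaults to `fibril_modulus(p)`. Pass
#'   the canonical tabulated value explicitly to pin it.
#' @return Modulus in GPa.
#' @export
fibre_modulus <- function(p, E_mc = fibril_modulus(p)) {
  if (any(E_mc <= 0)) stop("E_mc must be positive")
  shear_lag_modulus(p$phi_mc, E_mc, p$gamma_mc, p$mu_ef)
}

#' Strain of the intrafibrillar mineral
#'
#' The axial stress in the fibril is carried by the mineral platelets, so the
#' elastic mineral strain is `sigma_mc / (phi_min_intra * E_min)` for a given
#' fibril stress `sigma_mc`.
#'
#' @param sigma_mc axial fibril stress in GPa.
#' @param phi_min_intra intrafibrillar mineral volume fraction.
#' @param E_min mineral Young's modulus in GPa.
#' @return Dimensionless strain.
#' @export
mineral_strain <- function(sigma_mc, phi_min_intra, E_min) {
  den <- phi_min_intra * E_min
  if (any(den <= 0)) stop("phi_min_intra * E_min must be positive")
  sigma_mc / den
}

#' Fibril-to-fibre strain ratio
#'
#' Ratio between the apparent fibril strain (elastic part from the shear lag
#' plus the intrafibrillar plastic strain) and the total applied strain:
#' `(sigma / (phi_mc * E_mc) + eps_p_mc) / eps_total`. This is the quantity
#' measured by in-situ small-angle X-ray scattering.
#'
#' @param sigma axial stress in GPa (fibre-level stress; use `phi_mc = 1`
#'   when `sigma` is the stress carried by a single fibril-matrix element in
#'   series, see the methods vignette).
#' @param eps_total total applied strain (non-zero).
#' @param phi_mc fibril volume fraction.
#' @param E_mc fibril Young's modulus in GPa.
#' @param eps_p_mc intrafibrillar plastic strain.
#' @return Dimensionless strain ratio.
#' @export
fibril_strain_ratio <- function(sigma, eps_total, phi_mc, E_mc,
                                eps_p_mc = 0) {
  if (any(eps_total == 0)) stop("strain ratio undefined at eps_total = 0")
  (sigma / (phi_mc * E_mc) + eps_p_mc) / eps_total
}

#' Mineral-to-fibre strain ratio
#'
#' Elastic mineral strain relative to the total applied strain,
#' `sigma / (eps_total * phi_mc * phi_min_intra * E_min)`; the quantity
#' measured by in-situ X-ray diffraction on the mineral lattice.
#'
#' @inheritParams fibril_strain_ratio
#' @param phi_min_intra intrafibrillar mineral volume fraction.
#' @param E_min mineral Young's modulus in GPa.
#' @return Dimensionless strain ratio.
#' @export
mineral_strain_ratio <- function(sigma, eps_total, phi_mc, phi_min_intra,
                                 E_min) {
  if (any(eps_total == 0)) stop("strain ratio undefined at eps_total = 0")
  sigma / (eps_total * phi_mc * phi_min_intra * E_min)
}
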