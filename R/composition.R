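#' Tissue composition of a mineralised collagen fibre
#'
#' Builds the volume-fraction description of the fibre used by the nested
#' shear-lag models. At the fibre level the tissue is divided into mineralised
#' collagen fibrils (volume fraction `phi_mc`) and extrafibrillar matrix
#' (`phi_ef = 1 - phi_mc`); at the constituent level into mineral (`phi_min`),
#' collagen (`phi_col`) and non-collagenous proteins including bound water
#' (`phi_ncp`). The tissue mineral density is the volume-fraction weighted sum
#' of the constituent densities,
#' `rho = phi_min * rho_min + phi_col * rho_col + phi_ncp * rho_ncp`.
#'
#' @param phi_min mineral volume fraction.
#' @param phi_ncp non-collagenous-protein volume fraction (includes bound
#'   water). Default 0.14.
#' @param phi_mc fibril volume fraction within the fibre. Default 0.86.
#' @param rho_min,rho_col,rho_ncp constituent mass densities in g/cm^3.
#'   Defaults 2.90 for mineral and 1.13 for both organic constituents.
#' @return An object of class `"composition"`: a list with the volume
#'   fractions, the constituent densities and the implied tissue mineral
#'   density `rho` (g/cm^3).
#' @seealso [fractions_from_density()] to obtain `phi_min` from a measured
#'   tissue mineral density, [fibril_count()] for the size of the fibril
#'   bundle.
#' @export
#' @examples
#' comp <- composition(phi_min = 0.29)
#' comp$rho # about 1.64 g/cm^3
composition <- function(phi_min, phi_ncp = 0.14, phi_mc = 0.86,
                        rho_min = 2.90, rho_col = 1.13, rho_ncp = 1.13) {
  stopifnot(is.numeric(phi_min), length(phi_min) == 1L, is.finite(phi_min))
  phi_col <- 1 - phi_min - phi_ncp
  fr <- c(phi_min = phi_min, phi_col = phi_col, phi_ncp = phi_ncp,
          phi_mc = phi_mc, phi_ef = 1 - phi_mc)
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12))
    stop("volume fractions must lie in [0, 1]; got ",
         paste(sprintf("%s = %.4f", names(fr), fr), collapse = ", "))
  rho <- phi_min * rho_min + phi_col * rho_col + phi_ncp * rho_ncp
  structure(list(phi_min = phi_min, phi_col = phi_col, phi_ncp = phi_ncp,
                 phi_mc = phi_mc, phi_ef = 1 - phi_mc,
                 rho = rho, rho_min = rho_min, rho_col = rho_col,
                 rho_ncp = rho_ncp),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("Fibre composition\n")
  cat(sprintf("  fibril / extrafibrillar fraction: %.3f / %.3f\n",
              x$phi_mc, x$phi_ef))
  cat(sprintf("  mineral / collagen / ncp fraction: %.3f / %.3f / %.3f\n",
              x$phi_min, x$phi_col, x$phi_ncp))
  cat(sprintf("  tissue mineral density: %.3f g/cm^3\n", x$rho))
  invisible(x)
}

#' Volume fractions from tissue mineral density
#'
#' Inverts the density mixture rule for the mineral volume fraction. With the
#' non-collagenous fraction `phi_ncp` fixed (it is taken from independent
#' literature data, the mixture rule alone cannot determine two unknowns),
#' `rho = phi_min * rho_min + phi_col * rho_col + phi_ncp * rho_ncp` is a
#' linear equation in `phi_min` once `phi_col = 1 - phi_min - phi_ncp` is
#' substituted. No rounding is applied to the solution.
#'
#' @param rho tissue mineral density in g/cm^3.
#' @inheritParams composition
#' @return A [composition()] object whose `rho` reproduces the input.
#' @export
#' @examples
#' fractions_from_density(1.64)$phi_min # about 0.288
fractions_from_density <- function(rho, phi_ncp = 0.14, phi_mc = 0.86,
                                   rho_min = 2.90, rho_col = 1.13,
                                   rho_ncp = 1.13) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (phi_ncp < 0 || phi_ncp >= 1)
    stop("phi_ncp must lie in [0, 1)")
  # attainable density range for phi_min in [0, 1 - phi_ncp]
  rho_lo <- (1 - phi_ncp) * rho_col + phi_ncp * rho_ncp
  rho_hi <- (1 - phi_ncp) * rho_min + phi_ncp * rho_ncp
  if (rho < min(rho_lo, rho_hi) - 1e-12 || rho > max(rho_lo, rho_hi) + 1e-12)
    stop(sprintf(
      "rho = %.4f g/cm^3 is outside the attainable interval [%.4f, %.4f] for phi_ncp = %.3f",
      rho, rho_lo, rho_hi, phi_ncp))
  phi_min <- (rho - phi_ncp * rho_ncp - (1 - phi_ncp) * rho_col) /
    (rho_min - rho_col)
  composition(phi_min = phi_min, phi_ncp = phi_ncp, phi_mc = phi_mc,
              rho_min = rho_min, rho_col = rho_col, rho_ncp = rho_ncp)
}

#' Number of fibrils in a fibre cross-section
#'
#' Area-ratio estimate of how many fibrils of diameter `fibril_diameter` fit
#' into a fibre of diameter `fibre_diameter` at a given packing density:
#' `round(packing_density * (fibre_diameter / fibril_diameter)^2)`. The
#' packing density is an input constant (0.86 for a closest packing of circles
#' in a circle); deriving it from a packing optimisation is out of scope.
#'
#' @param fibre_diameter fibre (micropillar) diameter in micrometres.
#' @param fibril_diameter fibril diameter in nanometres.
#' @param packing_density areal packing density in (0, 1]. Default 0.86.
#' @return Integer fibril count.
#' @export
#' @examples
#' fibril_count(6.08, 224) # 634 by the area-ratio formula
fibril_count <- function(fibre_diameter, fibril_diameter,
                         packing_density = 0.86) {
  stopifnot(fibre_diameter > 0, fibril_diameter > 0,
            packing_density > 0, packing_density <= 1)
  d_nm <- fibre_diameter * 1e3
  if (fibril_diameter > d_nm)
    stop("fibril diameter (", fibril_diameter,
         " nm) must be smaller than the fibre diameter (", d_nm, " nm)")
  as.integer(round(packing_density * (d_nm / fibril_diameter)^2))
}
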