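#' @export
print.fibre_sim <- function(x, ...) {
  sc <- x$scalars
  cat("Simulated mineralised collagen fibre\n")
  cat(sprintf("  %d elements, seed %s, %d protocol points\n",
              x$params$n_elements,
              if (is.null(x$seed)) "<none>" else x$seed, length(x$strain)))
  cat(sprintf("  shear-lag fibre modulus: %.3f GPa\n", sc$modulus_shear_lag))
  if (is.finite(sc$yield_strain))
    cat(sprintf("  yield point: %.4f strain, %.4f GPa\n",
                sc$yield_strain, sc$yield_stress))
  else cat("  yield point: not reached\n")
  cat(sprintf("  compressive strength: %.4f GPa at %.4f strain\n",
              sc$strength, sc$strength_strain))
  if (!is.null(x$first_failure))
    cat(sprintf("  first fibril failure at %.4f strain (alpha_ef = %.4f)\n",
                x$first_failure$strain, x$first_failure$alpha_ef))
  invisible(x)
}

#' Summary of a fibre simulation
#'
#' @param object a [simulate_fibre()] result.
#' @param ... unused.
#' @return A named list of the derived scalar quantities (invisibly printed).
#' @export
summary.fibre_sim <- function(object, ...) {
  sc <- object$scalars
  out <- c(unlist(sc),
           n_failed = sum(!object$final_state$active),
           dissipated = NA_real_)
  class(out) <- "summary.fibre_sim"
  out
}

#' @export
print.summary.fibre_sim <- function(x, ...) {
  y <- unclass(x)
  y <- y[!is.na(y)]
  for (nm in names(y)) cat(sprintf("  %-24s %s\n", nm, format(signif(y[[nm]], 5))))
  invisible(x)
}

#' Derived scalar coefficients of a simulation
#'
#' @param object a [simulate_fibre()] result.
#' @param ... unused.
#' @return Named numeric vector with apparent modulus, yield point,
#'   strength, first-failure quantities and yield-point strain-ratio means.
#' @export
coef.fibre_sim <- function(object, ...) {
  unlist(object$scalars)
}

#' Plot a fibre simulation
#'
#' Base-graphics display: the apparent stress-strain trace with the loading
#' envelope, yield point and first-failure marker, and (if the per-element
#' matrices were kept) histograms of the fibril-to-fibre and
#' mineral-to-fibre strain ratios at the yield strain.
#'
#' @param x a [simulate_fibre()] result.
#' @param which subset of panels, 1 = stress-strain, 2 = strain-ratio
#'   histograms.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fibre_sim <- function(x, which = if (is.null(x$env_sigma)) 1 else 1:2,
                           ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  sc <- x$scalars
  if (1 %in% which) {
    graphics::plot(x$strain, x$stress, type = "l", col = "grey50",
                   xlab = "apparent strain", ylab = "apparent stress (GPa)",
                   ...)
    graphics::lines(x$envelope$strain, x$envelope$stress, lwd = 2)
    if (is.finite(sc$yield_strain))
      graphics::points(sc$yield_strain, sc$yield_stress, pch = 19,
                       col = "red3")
    if (!is.null(x$first_failure))
      graphics::abline(v = x$first_failure$strain, lty = 3)
  }
  if (2 %in% which && !is.null(x$env_sigma) && is.finite(sc$yield_strain)) {
    r <- strain_ratios(x, sc$yield_strain)
    graphics::hist(r$fibril, breaks = 30, col = "grey80",
                   main = "strain ratios at yield", xlab = "ratio")
    graphics::hist(r$mineral, breaks = 30, col = grDevices::adjustcolor("red3", 0.5),
                   add = TRUE)
    graphics::legend("topright", fill = c("grey80", "red3"),
                     legend = c("fibril / fibre", "mineral / fibre"),
                     bty = "n")
  }
  invisible(x)
}
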