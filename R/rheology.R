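#' Properties of one elasto-plastic rheological element
#'
#' A rheological element represents one mineralised collagen fibril embedded
#' in extrafibrillar matrix: an elastic spring of modulus `E_app` in series
#' with two rate-independent plastic sliders, one for the intrafibrillar
#' mineral-collagen interface (`mc`) and one for the extrafibrillar
#' fibril-matrix interface (`ef`). Both sliders carry the same stress (series
#' chain). Slider `i` yields when
#' `|sigma| > E_app * eps_y_i + chi_i * alpha_i` (linear isotropic hardening
#' on the accumulated plastic strain `alpha_i`), and is deactivated -- the
#' fibril fails and the element stress drops to zero -- once its plastic
#' strain magnitude exceeds `eps_ult_i`.
#'
#' @param E_app apparent element Young's modulus in GPa (the spring).
#' @param eps_y_mc,eps_y_ef yield strains of the intrafibrillar and
#'   extrafibrillar sliders.
#' @param chi_mc,chi_ef linear hardening moduli in GPa (non-negative).
#' @param eps_ult_mc,eps_ult_ef ultimate plastic strains at which the
#'   respective slider, and with it the whole element, is deactivated.
#' @return An object of class `"element_properties"`.
#' @export
#' @examples
#' pr <- element_properties(E_app = 15.8)
#' st <- element_step(element_state(), pr, 0.02)
#' st$sigma
element_properties <- function(E_app,
                               eps_y_mc = 0.028, eps_y_ef = 0.012,
                               chi_mc = 0.020, chi_ef = 0.03e-4,
                               eps_ult_mc = 9.0, eps_ult_ef = 0.09) {
  stopifnot(E_app > 0, eps_y_mc > 0, eps_y_ef > 0,
            chi_mc >= 0, chi_ef >= 0, eps_ult_mc > 0, eps_ult_ef > 0)
  structure(list(E_app = E_app, eps_y_mc = eps_y_mc, eps_y_ef = eps_y_ef,
                 chi_mc = chi_mc, chi_ef = chi_ef,
                 eps_ult_mc = eps_ult_mc, eps_ult_ef = eps_ult_ef),
            class = "element_properties")
}

#' Internal state of a rheological element
#'
#' @param eps_p_mc,eps_p_ef plastic strains of the two sliders.
#' @param alpha_mc,alpha_ef accumulated plastic strains (non-negative, never
#'   decreasing).
#' @param active logical; `FALSE` once either slider has passed its ultimate
#'   strain. An inactive element returns zero stress forever.
#' @return An object of class `"element_state"`.
#' @export
element_state <- function(eps_p_mc = 0, eps_p_ef = 0,
                          alpha_mc = 0, alpha_ef = 0, active = TRUE) {
  stopifnot(alpha_mc >= abs(eps_p_mc) - 1e-12,
            alpha_ef >= abs(eps_p_ef) - 1e-12)
  structure(list(eps_p_mc = eps_p_mc, eps_p_ef = eps_p_ef,
                 alpha_mc = alpha_mc, alpha_ef = alpha_ef,
                 active = isTRUE(active)),
            class = "element_state")
}

#' Strain-driven update of one rheological element
#'
#' Implicit return-mapping update from the current state to the prescribed
#' total element strain `eps_n`. The elastic trial stress is
#' `E_app * (eps_n - eps_p_mc - eps_p_ef)`; both yield functions are
#' evaluated on it and the violated set is corrected in closed form. Because
#' the sliders share one stress, simultaneous activation with linear
#' hardening reduces to a 2x2 linear system in the two plastic multipliers;
#' a negative multiplier drops that surface and the other slider is
#' return-mapped alone. Plastic strain increments carry the sign of the
#' (trial) stress, so the dissipation increment is non-negative and the
#' Karush-Kuhn-Tucker conditions hold after every step. If either plastic
#' strain magnitude exceeds its ultimate value after the corrector, the
#' element is deactivated and reports zero stress for the whole step.
#'
#' The update is exact for any step size within a monotone strain segment
#' (linear hardening); no sub-stepping is needed.
#'
#' @param state an [element_state()].
#' @param props an [element_properties()].
#' @param eps_n total element strain at the end of the step.
#' @return A list with the updated `state`, the end-of-step stress `sigma`
#'   (GPa), and `dissipation`, the energy dissipated in the step per unit
#'   volume (GPa, i.e. stress times plastic strain increment; trapezoidal in
#'   the stress so that work, stored energy and dissipation balance exactly).
#' @export
element_step <- function(state, props, eps_n) {
  if (!is.finite(eps_n)) stop("element strain must be finite")
  E <- props$E_app
  if (!state$active)
    return(list(state = state, sigma = 0, dissipation = 0))

  eps_p_mc <- state$eps_p_mc; eps_p_ef <- state$eps_p_ef
  alpha_mc <- state$alpha_mc; alpha_ef <- state$alpha_ef

  sig_tr <- E * (eps_n - eps_p_mc - eps_p_ef)
  s <- sign(sig_tr)
  f_mc <- abs(sig_tr) - (E * props$eps_y_mc + props$chi_mc * alpha_mc)
  f_ef <- abs(sig_tr) - (E * props$eps_y_ef + props$chi_ef * alpha_ef)

  dl_mc <- 0; dl_ef <- 0
  if (f_mc > 0 && f_ef > 0) {
    det <- (E + props$chi_mc) * (E + props$chi_ef) - E * E
    dl_mc <- (f_mc * (E + props$chi_ef) - E * f_ef) / det
    dl_ef <- (f_ef * (E + props$chi_mc) - E * f_mc) / det
    if (dl_mc < 0) { dl_mc <- 0; dl_ef <- f_ef / (E + props$chi_ef) }
    if (dl_ef < 0) { dl_ef <- 0; dl_mc <- f_mc / (E + props$chi_mc) }
  } else if (f_mc > 0) {
    dl_mc <- f_mc / (E + props$chi_mc)
  } else if (f_ef > 0) {
    dl_ef <- f_ef / (E + props$chi_ef)
  }

  eps_p_mc <- eps_p_mc + s * dl_mc
  eps_p_ef <- eps_p_ef + s * dl_ef
  alpha_mc <- alpha_mc + dl_mc
  alpha_ef <- alpha_ef + dl_ef
  sigma <- sig_tr - E * s * (dl_mc + dl_ef)

  # dissipation over the step: trapezoid in stress times plastic increment;
  # the start-of-step strain is carried in the "eps_prev" attribute (set by
  # element_path()); a lone call falls back to the virgin strain 0
  eps_prev <- attr(state, "eps_prev") %||% 0
  sigma0 <- E * (eps_prev - state$eps_p_mc - state$eps_p_ef)
  diss <- 0.5 * (sigma0 + sigma) * s * (dl_mc + dl_ef)

  active <- abs(eps_p_mc) <= props$eps_ult_mc &&
            abs(eps_p_ef) <= props$eps_ult_ef
  if (!active) sigma <- 0

  new_state <- element_state(eps_p_mc, eps_p_ef, alpha_mc, alpha_ef, active)
  list(state = new_state, sigma = sigma, dissipation = diss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drive one element along a strain path
#'
#' Convenience wrapper applying [element_step()] to an ordered sequence of
#' total strains, starting from a virgin state.
#'
#' @param props an [element_properties()].
#' @param path numeric vector of total element strains.
#' @param state starting [element_state()].
#' @return A data frame trace with columns `eps`, `sigma`, `eps_p_mc`,
#'   `eps_p_ef`, `alpha_mc`, `alpha_ef`, `active`, `dissipation` (the
#'   per-step increment).
#' @export
element_path <- function(props, path, state = element_state()) {
  n <- length(path)
  out <- data.frame(eps = path, sigma = numeric(n),
                    eps_p_mc = numeric(n), eps_p_ef = numeric(n),
                    alpha_mc = numeric(n), alpha_ef = numeric(n),
                    active = logical(n), dissipation = numeric(n))
  eps_prev <- 0
  for (k in seq_len(n)) {
    attr(state, "eps_prev") <- eps_prev
    st <- element_step(state, props, path[k])
    state <- st$state
    eps_prev <- path[k]
    out$sigma[k] <- st$sigma
    out$eps_p_mc[k] <- state$eps_p_mc
    out$eps_p_ef[k] <- state$eps_p_ef
    out$alpha_mc[k] <- state$alpha_mc
    out$alpha_ef[k] <- state$alpha_ef
    out$active[k] <- state$active
    out$dissipation[k] <- st$dissipation
  }
  out
}

#' Total dissipation along a recorded trace
#'
#' Sums `sigma * d(eps_p)` over both sliders along a trace as returned by
#' [element_path()], using the trapezoidal stress between consecutive points.
#' By construction this equals the work input minus the change of stored
#' elastic energy (exactly, as long as no element is deactivated on the
#' path), and it is non-negative for any admissible path.
#'
#' @param trace a data frame with columns `eps`, `sigma`, `eps_p_mc`,
#'   `eps_p_ef`, starting from the virgin state (the initial point before
#'   `trace[1, ]` is taken as unstrained and stress-free).
#' @return Total dissipated energy per unit volume (GPa).
#' @export
dissipation_of_path <- function(trace) {
  sig <- c(0, trace$sigma)
  ep <- c(0, trace$eps_p_mc + trace$eps_p_ef)
  sum(0.5 * (sig[-1] + sig[-length(sig)]) * diff(ep))
}
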