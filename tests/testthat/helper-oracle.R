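# Independent brute-force integrator for the two-slider element.
#
# Each macro strain step is subdivided into micro steps of at most `substep`.
# Within a micro step the corrected stress is found without the closed-form
# two-surface return map of the implementation: single-surface violations are
# projected directly, and the simultaneous case is solved by scalar root
# finding on the stress magnitude (uniroot), using the hardening laws to
# express each plastic multiplier as a function of the final stress. This
# shares no algebra with element_step() and serves as the independent oracle.
oracle_element_path <- function(props, path, substep = 1e-6) {
  E <- props$E_app
  chi1 <- props$chi_mc; chi2 <- props$chi_ef
  ep_mc <- 0; ep_ef <- 0; a_mc <- 0; a_ef <- 0; active <- TRUE
  n <- length(path)
  out <- data.frame(eps = path, sigma = numeric(n),
                    eps_p_mc = numeric(n), eps_p_ef = numeric(n),
                    alpha_mc = numeric(n), alpha_ef = numeric(n),
                    active = logical(n))
  eps_cur <- 0
  for (k in seq_len(n)) {
    target <- path[k]
    n_sub <- max(1L, ceiling(abs(target - eps_cur) / substep))
    grid <- seq(eps_cur, target, length.out = n_sub + 1L)[-1L]
    for (eps in grid) {
      if (!active) break
      sig_tr <- E * (eps - ep_mc - ep_ef)
      s_tr <- abs(sig_tr); sgn <- sign(sig_tr)
      h1 <- E * props$eps_y_mc + chi1 * a_mc
      h2 <- E * props$eps_y_ef + chi2 * a_ef
      dl1 <- 0; dl2 <- 0
      if (s_tr > h1 || s_tr > h2) {
        # candidates: project one violated surface alone and check that the
        # corrected stress does not violate the other surface
        try1 <- if (s_tr > h1) (s_tr - h1) / (E + chi1) else 0
        try2 <- if (s_tr > h2) (s_tr - h2) / (E + chi2) else 0
        if (try1 > 0 && s_tr - E * try1 <= h2 + 1e-15) {
          dl1 <- try1
        } else if (try2 > 0 && s_tr - E * try2 <= h1 + 1e-15) {
          dl2 <- try2
        } else {
          # simultaneous flow: find the final stress magnitude s solving
          # (s_tr - s)/E = dl1(s) + dl2(s) with dli(s) = max(0, (s - hi)/chii)
          g <- function(s)
            (s_tr - s) / E - max(0, (s - h1) / max(chi1, 1e-12)) -
              max(0, (s - h2) / max(chi2, 1e-12))
          root <- stats::uniroot(g, c(min(h1, h2), s_tr), tol = 1e-14)$root
          total <- (s_tr - root) / E
          # allocate the better-conditioned multiplier from the hardening
          # law, the other as the remainder
          if (chi1 >= chi2) {
            dl1 <- min(total, max(0, (root - h1) / max(chi1, 1e-12)))
            dl2 <- total - dl1
          } else {
            dl2 <- min(total, max(0, (root - h2) / max(chi2, 1e-12)))
            dl1 <- total - dl2
          }
        }
        ep_mc <- ep_mc + sgn * dl1; a_mc <- a_mc + dl1
        ep_ef <- ep_ef + sgn * dl2; a_ef <- a_ef + dl2
      }
      if (abs(ep_mc) > props$eps_ult_mc || abs(ep_ef) > props$eps_ult_ef)
        active <- FALSE
    }
    eps_cur <- target
    out$sigma[k] <- if (active) E * (target - ep_mc - ep_ef) else 0
    out$eps_p_mc[k] <- ep_mc; out$eps_p_ef[k] <- ep_ef
    out$alpha_mc[k] <- a_mc; out$alpha_ef[k] <- a_ef
    out$active[k] <- active
  }
  out
}

# random element properties on a reduced strain scale so that short random
# paths still traverse both yield surfaces and occasionally the ultimate
# strains
random_props <- function() {
  element_properties(
    E_app = runif(1, 5, 25),
    eps_y_mc = runif(1, 2e-4, 2e-3),
    eps_y_ef = runif(1, 2e-4, 2e-3),
    chi_mc = runif(1, 0, 0.5),
    chi_ef = runif(1, 0, 0.5),
    eps_ult_mc = runif(1, 2e-3, 2e-2),
    eps_ult_ef = runif(1, 2e-3, 2e-2))
}

# random cyclic strain path (direction reversals, both signs)
random_path <- function(n_steps = 10, amp = 6e-4) {
  cumsum(runif(n_steps, -amp, amp))
}

table2_element <- function() element_properties(E_app = 15.803)
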