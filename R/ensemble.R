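#' Parameter set of the statistical fibre model
#'
#' Bundles everything needed for a simulation run: the composition, the
#' nested shear-lag elasticity, the plasticity parameters of the rheological
#' element, the statistical distribution of the varied parameters, the
#' recruitment model (or `NULL` to disable it, i.e. zero surface roughness)
#' and the loading protocol. Defaults are the tabulated values for
#' mineralised turkey leg tendon; see [scenario_preset()] for variants.
#'
#' @param comp a [composition()] object.
#' @param shear_lag a [shear_lag_params()] object (built from `comp` if
#'   missing).
#' @param plasticity named list with `eps_y_mc`, `eps_y_ef`, `chi_mc`,
#'   `chi_ef`, `eps_ult_mc`, `eps_ult_ef` (defaults: yield strains 0.028 and
#'   0.012, hardening 0.020 and 0.03e-4 GPa, ultimate plastic strains 9.0
#'   and 0.09; the intrafibrillar ultimate strain is one hundred times the
#'   extrafibrillar one, failure is assumed extrafibrillar).
#' @param dist a [distribution_spec()] (default normal, cov 0.15).
#' @param recruitment a [recruitment_offsets()] model, or `NULL` for no
#'   recruitment.
#' @param protocol a [make_protocol()] object.
#' @param n_elements number of rheological elements (default 618, the
#'   canonical fibril count of the tested micropillars; [fibril_count()]
#'   gives the area-ratio estimate).
#' @param sampling `"nested"` (element moduli computed through the shear
#'   lags from sampled constituent parameters) or `"direct"` (fibril modulus
#'   sampled around its tabulated mean), see [sample_elements()].
#' @param E_mc optional pinned fibril modulus in GPa overriding the computed
#'   shear-lag value (used by `"direct"` sampling and reporting).
#' @return An object of class `"fibre_params"`.
#' @export
#' @examples
#' p <- fibre_params()
#' p$n_elements
fibre_params <- function(comp = composition(0.29),
                         shear_lag = shear_lag_params(comp = comp),
                         plasticity = list(),
                         dist = distribution_spec("normal", cov = 0.15),
                         recruitment = NULL,
                         protocol = make_protocol(),
                         n_elements = 618,
                         sampling = c("nested", "direct"),
                         E_mc = NULL) {
  sampling <- match.arg(sampling)
  pl_def <- list(eps_y_mc = 0.028, eps_y_ef = 0.012,
                 chi_mc = 0.020, chi_ef = 0.03e-4,
                 eps_ult_mc = 9.0, eps_ult_ef = 0.09)
  unknown <- setdiff(names(plasticity), names(pl_def))
  if (length(unknown))
    stop("unknown plasticity parameter(s): ", paste(unknown, collapse = ", "))
  pl <- utils::modifyList(pl_def, plasticity)
  if (pl$eps_ult_mc <= pl$eps_ult_ef)
    warning("intrafibrillar ultimate strain not larger than extrafibrillar ",
            "one; the extrafibrillar-failure-first assumption is violated")
  if (!is.null(recruitment) && recruitment$n_elements != n_elements)
    stop("recruitment model was built for ", recruitment$n_elements,
         " elements, but n_elements = ", n_elements)
  stopifnot(n_elements >= 1)
  structure(list(comp = comp, shear_lag = shear_lag, plasticity = pl,
                 dist = dist, recruitment = recruitment, protocol = protocol,
                 n_elements = as.integer(n_elements), sampling = sampling,
                 E_mc = E_mc),
            class = "fibre_params")
}

#' @export
print.fibre_params <- function(x, ...) {
  cat("Statistical fibre model parameters\n")
  cat(sprintf("  elements: %d, sampling: %s, distribution: %s (cov = %g)\n",
              x$n_elements, x$sampling, x$dist$family, x$dist$cov))
  cat(sprintf("  moduli: fibril %.2f GPa, fibre %.2f GPa\n",
              x$E_mc %||% fibril_modulus(x$shear_lag),
              fibre_modulus(x$shear_lag, x$E_mc %||% fibril_modulus(x$shear_lag))))
  pl <- x$plasticity
  cat(sprintf("  yield strains: mc %.3f, ef %.3f; ultimate: mc %.2f, ef %.3f\n",
              pl$eps_y_mc, pl$eps_y_ef, pl$eps_ult_mc, pl$eps_ult_ef))
  if (is.null(x$recruitment)) cat("  recruitment: none (zero roughness)\n")
  else cat(sprintf("  recruitment: mu = %g, beta = %g\n",
                   x$recruitment$mu, x$recruitment$beta))
  invisible(x)
}

#' Simulate the fibre as a parallel bundle of rheological elements
#'
#' Samples `n_elements` element property sets, assigns the recruitment
#' offsets (in element order), and drives the bundle through the loading
#' protocol. At every protocol point each recruited element sees the strain
#' `eps - eps_0n` (an element is loaded only once the apparent strain
#' exceeds its offset) and is updated by the closed-form return mapping of
#' the two-slider element; contact with the punch is unilateral, so an
#' element whose corrected strain falls below its residual plastic strain
#' separates from the punch and carries zero stress instead of going into
#' tension. The apparent stress is the arithmetic mean of the element
#' stresses (each element represents an equal share of the cross-section).
#'
#' Along the loading envelope (points where the apparent strain reaches a
#' new maximum) per-element stresses and intrafibrillar plastic strains are
#' recorded so that strain-ratio distributions can be evaluated at any
#' envelope strain after the fact.
#'
#' @param params a [fibre_params()] object.
#' @param seed integer seed; every source of randomness in the run derives
#'   from it. `NULL` leaves the RNG state alone.
#' @param keep_elements logical; keep the per-element envelope matrices in
#'   the result (needed for strain-ratio distributions; default `TRUE`).
#' @return An object of class `"fibre_sim"`; see Details.
#' @details The result contains
#' * `strain`, `stress`: the apparent trace over the whole protocol (GPa);
#' * `envelope`: data frame with the loading envelope (`strain`, `stress`,
#'   `n_recruited`, `n_active`);
#' * `elements`: the sampled element properties;
#' * `env_sigma`, `env_eps_p_mc`: element-by-envelope matrices (if kept);
#' * `first_failure`: list with apparent strain, element index and its
#'   accumulated plastic strains at the first deactivation (or `NULL`);
#' * `scalars`: derived quantities (apparent modulus, yield point by the
#'   default criterion, strength, strain-ratio means at yield);
#' * `seed`, `params`.
#' @export
#' @examples
#' p <- fibre_params(n_elements = 40,
#'                   protocol = make_protocol(peaks = c(0.02, 0.04),
#'                                            resolution = 1e-3))
#' s <- simulate_fibre(p, seed = 1)
#' s$scalars$strength
simulate_fibre <- function(params, seed = NULL, keep_elements = TRUE) {
  if (!inherits(params, "fibre_params")) stop("params must be fibre_params")
  if (!is.null(seed)) set.seed(seed)
  N <- params$n_elements
  el <- sample_elements(params, N)
  path <- params$protocol$path
  if (length(path) == 0) stop("loading protocol is empty")

  off <- if (is.null(params$recruitment)) numeric(N)
         else params$recruitment$offsets_applied

  E <- el$E_app
  eyc <- el$eps_y_mc; eye <- el$eps_y_ef
  chc <- el$chi_mc;  che <- el$chi_ef
  ultc <- el$eps_ult_mc; ulte <- el$eps_ult_ef
  det2 <- (E + chc) * (E + che) - E * E

  ep_mc <- numeric(N); ep_ef <- numeric(N)
  a_mc <- numeric(N); a_ef <- numeric(N)
  active <- rep(TRUE, N)

  n_steps <- length(path)
  stress <- numeric(n_steps)

  res <- params$protocol$resolution
  env_strain <- seq(res, max(path), by = res)
  n_env <- length(env_strain)
  env_sigma <- if (keep_elements) matrix(NA_real_, N, n_env) else NULL
  env_ep_mc <- if (keep_elements) matrix(NA_real_, N, n_env) else NULL
  env_stress <- rep(NA_real_, n_env)
  env_recr <- integer(n_env)
  env_act <- integer(n_env)

  first_failure <- NULL
  eps_max <- 0

  for (k in seq_len(n_steps)) {
    eps <- path[k]
    eps_n <- eps - off
    contact <- active & (eps_n > ep_mc + ep_ef)
    sig <- numeric(N)
    if (any(contact)) {
      sig_tr <- E * (eps_n - ep_mc - ep_ef)
      sig_tr[!contact] <- 0
      f_mc <- abs(sig_tr) - (E * eyc + chc * a_mc)
      f_ef <- abs(sig_tr) - (E * eye + che * a_ef)
      f_mc[!contact] <- -1; f_ef[!contact] <- -1
      dl_mc <- numeric(N); dl_ef <- numeric(N)
      both <- f_mc > 0 & f_ef > 0
      if (any(both)) {
        d1 <- (f_mc * (E + che) - E * f_ef) / det2
        d2 <- (f_ef * (E + chc) - E * f_mc) / det2
        neg1 <- both & d1 < 0
        neg2 <- both & d2 < 0
        d1[neg1] <- 0; d2[neg1] <- f_ef[neg1] / (E[neg1] + che[neg1])
        d2[neg2] <- 0; d1[neg2] <- f_mc[neg2] / (E[neg2] + chc[neg2])
        dl_mc[both] <- d1[both]; dl_ef[both] <- d2[both]
      }
      only_mc <- f_mc > 0 & !both
      only_ef <- f_ef > 0 & !both
      dl_mc[only_mc] <- f_mc[only_mc] / (E[only_mc] + chc[only_mc])
      dl_ef[only_ef] <- f_ef[only_ef] / (E[only_ef] + che[only_ef])
      s <- sign(sig_tr)
      ep_mc <- ep_mc + s * dl_mc
      ep_ef <- ep_ef + s * dl_ef
      a_mc <- a_mc + dl_mc
      a_ef <- a_ef + dl_ef
      sig <- sig_tr - E * s * (dl_mc + dl_ef)
      failed <- active & (abs(ep_mc) > ultc | abs(ep_ef) > ulte)
      if (any(failed)) {
        if (is.null(first_failure)) {
          i <- which(failed)[which.max(pmax(abs(ep_mc[failed]) / ultc[failed],
                                            abs(ep_ef[failed]) / ulte[failed]))]
          first_failure <- list(strain = eps, element = i,
                                alpha_mc = a_mc[i], alpha_ef = a_ef[i],
                                eps_p_ef = ep_ef[i])
        }
        active[failed] <- FALSE
        sig[failed] <- 0
      }
      sig[!contact] <- 0
    }
    stress[k] <- mean(sig)
    if (eps > eps_max + res / 2) {
      j <- as.integer(round(eps / res))
      if (j >= 1 && j <= n_env) {
        if (keep_elements) {
          env_sigma[, j] <- sig
          env_ep_mc[, j] <- ep_mc
        }
        env_stress[j] <- stress[k]
        env_recr[j] <- sum(eps >= off)
        env_act[j] <- sum(active)
      }
      eps_max <- eps
    }
  }

  envelope <- data.frame(strain = env_strain, stress = env_stress,
                         n_recruited = env_recr, n_active = env_act)
  envelope <- envelope[!is.na(envelope$stress), , drop = FALSE]

  sim <- structure(list(strain = path, stress = stress, envelope = envelope,
                        elements = el, env_sigma = env_sigma,
                        env_eps_p_mc = env_ep_mc,
                        first_failure = first_failure,
                        final_state = data.frame(eps_p_mc = ep_mc,
                                                 eps_p_ef = ep_ef,
                                                 alpha_mc = a_mc,
                                                 alpha_ef = a_ef,
                                                 active = active),
                        seed = seed, params = params),
                   class = "fibre_sim")
  sim$scalars <- derive_scalars(sim)
  sim
}

# scalar summaries of a finished run
derive_scalars <- function(sim) {
  env <- sim$envelope
  yp <- yield_point(env)
  sc <- list(
    modulus_shear_lag = fibre_modulus(sim$params$shear_lag,
                                      sim$params$E_mc %||%
                                        fibril_modulus(sim$params$shear_lag)),
    modulus_apparent = envelope_modulus(env),
    yield_strain = yp$eps_y, yield_stress = yp$sigma_y,
    strength = max(env$stress),
    strength_strain = env$strain[which.max(env$stress)],
    first_failure_strain = sim$first_failure$strain %||% NA_real_,
    first_failure_alpha_ef = sim$first_failure$alpha_ef %||% NA_real_,
    first_failure_alpha_mc = sim$first_failure$alpha_mc %||% NA_real_
  )
  if (!is.null(sim$env_sigma) && is.finite(yp$eps_y)) {
    r <- strain_ratios(sim, yp$eps_y)
    sc$ratio_fibril_fibre <- mean(r$fibril)
    sc$ratio_mineral_fibre <- mean(r$mineral)
  } else {
    sc$ratio_fibril_fibre <- NA_real_
    sc$ratio_mineral_fibre <- NA_real_
  }
  sc
}

# apparent modulus as the maximum smoothed slope of the loading envelope
envelope_modulus <- function(env, window = 10L) {
  n <- nrow(env)
  if (n < window + 1L) window <- max(1L, n - 1L)
  i <- seq_len(n - window)
  slopes <- (env$stress[i + window] - env$stress[i]) /
            (env$strain[i + window] - env$strain[i])
  max(slopes)
}

#' Per-element strain-ratio distributions at an envelope strain
#'
#' Evaluates the fibril-to-fibre and mineral-to-fibre strain ratios for
#' every element at the envelope point closest to `eps`. The element stress
#' passes through fibril and matrix in series, so within an element the
#' fibril carries the full element stress: the elastic fibril strain is
#' `sigma_n / E_mc_n` and the mineral strain
#' `sigma_n / (phi_min_intra * E_min_n)`. Ratios are taken against the total
#' applied strain; elements not in contact contribute zero.
#'
#' @param sim a [simulate_fibre()] result with element matrices kept.
#' @param eps apparent strain at which to evaluate (snapped to the envelope
#'   grid).
#' @return A data frame with columns `fibril`, `mineral`, and
#'   `mineral_fibril` (mineral-to-fibril ratio), one row per element.
#' @export
strain_ratios <- function(sim, eps) {
  if (is.null(sim$env_sigma))
    stop("run simulate_fibre() with keep_elements = TRUE")
  env <- sim$envelope
  j <- which.min(abs(env$strain - eps))
  jj <- as.integer(round(env$strain[j] / sim$params$protocol$resolution))
  sig <- sim$env_sigma[, jj]
  ep_mc <- sim$env_eps_p_mc[, jj]
  el <- sim$elements
  phi_i <- sim$params$shear_lag$phi_min_intra
  fib <- fibril_strain_ratio(sig, env$strain[j], phi_mc = 1,
                             E_mc = el$E_mc, eps_p_mc = ep_mc)
  mine <- mineral_strain_ratio(sig, env$strain[j], phi_mc = 1,
                               phi_min_intra = phi_i, E_min = el$E_min)
  data.frame(fibril = fib, mineral = mine,
             mineral_fibril = ifelse(fib != 0, mine / fib, 0))
}

#' Yield point of a stress-strain envelope
#'
#' Extracts a "numerical yield point" from the monotone loading envelope.
#' Two criteria are available:
#' * `"offset"` (default): 0.2 percent plastic-offset construction; the
#'   reference line has the maximum (smoothed) envelope slope and is
#'   anchored at its toe intercept, so that curves with a recruitment toe
#'   (which never attain the elastic modulus as a loading slope) are
#'   handled the same way as toe-free curves; the line shifted by `offset`
#'   strain is intersected with the envelope.
#' * `"intersect"`: bilinear construction; the tangent at the point of
#'   maximum slope is intersected with the horizontal line through the
#'   maximum stress, and the yield point is the envelope at that strain.
#'
#' @param env either a `fibre_sim` object or a data frame with columns
#'   `strain` and `stress` forming a monotone envelope.
#' @param criterion `"intersect"` or `"offset"`.
#' @param offset plastic strain offset used by the `"offset"` criterion
#'   (default 0.002).
#' @param window smoothing window (points) for the slope estimate.
#' @return List with `eps_y` and `sigma_y`; both `NA` if the curve never
#'   yields under the chosen criterion (not-yielded sentinel).
#' @export
#' @examples
#' env <- data.frame(strain = seq(0, 0.03, 1e-4))
#' env$stress <- pmin(16 * env$strain, 0.16) # bilinear, kink at 0.01
#' yield_point(env)$eps_y # just above 0.012
#' yield_point(env, criterion = "intersect")$eps_y
yield_point <- function(env, criterion = c("offset", "intersect"),
                        offset = 0.002, window = 10L) {
  criterion <- match.arg(criterion)
  if (inherits(env, "fibre_sim")) env <- env$envelope
  stopifnot(all(c("strain", "stress") %in% names(env)))
  env <- env[order(env$strain), , drop = FALSE]
  n <- nrow(env)
  if (n < 3L) return(list(eps_y = NA_real_, sigma_y = NA_real_))
  w <- min(window, n - 1L)
  i <- seq_len(n - w)
  slopes <- (env$stress[i + w] - env$stress[i]) / (env$strain[i + w] - env$strain[i])
  k <- which.max(slopes)
  m <- slopes[k]
  # tangent anchored at the centre of the max-slope window
  x0 <- (env$strain[k] + env$strain[k + w]) / 2
  y0 <- (env$stress[k] + env$stress[k + w]) / 2
  if (criterion == "intersect") {
    sig_max <- max(env$stress)
    eps_knee <- x0 + (sig_max - y0) / m
    if (eps_knee >= 0.98 * max(env$strain))
      return(list(eps_y = NA_real_, sigma_y = NA_real_))
    j <- which.min(abs(env$strain - eps_knee))
    list(eps_y = env$strain[j], sigma_y = env$stress[j])
  } else {
    # toe-corrected offset line: slope m through (toe intercept + offset)
    eps_int <- x0 - y0 / m
    line <- m * (env$strain - eps_int - offset)
    above <- which(env$strain > x0 & line >= env$stress)
    if (length(above) == 0L)
      return(list(eps_y = NA_real_, sigma_y = NA_real_))
    j <- above[1L]
    list(eps_y = env$strain[j], sigma_y = env$stress[j])
  }
}

#' Sensitivity of the fibre response to heterogeneity and ultimate strain
#'
#' Runs one seeded simulation per scenario, varying the coefficient of
#' variation of the parameter distributions and/or scaling the mean ultimate
#' strains, and tabulates the derived scalars together with two softening
#' measures of the post-peak envelope: the total stress drop from the peak
#' to the end of the envelope, and the largest single-step drop (a measure
#' of abruptness of failure).
#'
#' @param params base [fibre_params()].
#' @param covs coefficients of variation to scan (default the published
#'   scan, 0.01 to 0.30).
#' @param ult_scales multiplicative factors on both ultimate strains
#'   (default 1).
#' @param seed integer; scenario `i` runs with `seed + i - 1`.
#' @return Data frame, one row per scenario (all `covs` crossed with all
#'   `ult_scales`).
#' @export
sensitivity_scan <- function(params, covs = c(0.01, 0.08, 0.15, 0.30),
                             ult_scales = 1, seed = 1) {
  stopifnot(length(covs) >= 1, length(ult_scales) >= 1)
  grid <- expand.grid(cov = covs, ult_scale = ult_scales)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$dist <- distribution_spec(
      if (grid$cov[i] == 0) "degenerate" else params$dist$family,
      cov = grid$cov[i], skew = params$dist$skew,
      truncate_at = params$dist$truncate_at)
    p$plasticity$eps_ult_mc <- params$plasticity$eps_ult_mc * grid$ult_scale[i]
    p$plasticity$eps_ult_ef <- params$plasticity$eps_ult_ef * grid$ult_scale[i]
    s <- simulate_fibre(p, seed = seed + i - 1, keep_elements = FALSE)
    env <- s$envelope
    peak <- which.max(env$stress)
    post <- env$stress[peak:nrow(env)]
    rows[[i]] <- data.frame(
      cov = grid$cov[i], ult_scale = grid$ult_scale[i],
      modulus = s$scalars$modulus_apparent,
      yield_strain = s$scalars$yield_strain,
      yield_stress = s$scalars$yield_stress,
      strength = s$scalars$strength,
      first_failure_strain = s$scalars$first_failure_strain,
      first_failure_alpha_ef = s$scalars$first_failure_alpha_ef,
      softening_drop = max(env$stress) - post[length(post)],
      softening_max_step = if (length(post) > 1) max(-diff(post)) else 0)
  }
  do.call(rbind, rows)
}

#' Named parameter presets
#'
#' Ready-made configurations:
#' * `"mtlt_base"`: the tabulated mineralised turkey leg tendon values with
#'   sigmoid recruitment (`mu = 0.0215`, `beta = 0.00635`).
#' * `"mtlt_no_recruitment"`: as above with surface roughness set to zero.
#' * `"bone_density"`: composition recomputed from the cortical-bone tissue
#'   mineral density of 1.90 g/cm^3.
#' * `"bone_density_diameter"`: additionally a 1.8-fold smaller fibril
#'   diameter entering the fibre-level shear lag through the fibril aspect
#'   ratio.
#' * `"bone_interaction"`: additionally hardening moduli and extrafibrillar
#'   yield strain scaled by 1.81 (the fibril surface-to-volume ratio factor)
#'   to emulate the stronger fibril-matrix interaction of bone.
#' All bone presets use a 75 percent lower surface roughness
#' (`mu` and `beta` scaled by 0.25).
#'
#' @param name preset name.
#' @param n_elements bundle size (default 618).
#' @return A [fibre_params()] object.
#' @export
scenario_preset <- function(name = c("mtlt_base", "mtlt_no_recruitment",
                                     "bone_density", "bone_density_diameter",
                                     "bone_interaction"),
                            n_elements = 618) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown preset; available: mtlt_base, ",
                          "mtlt_no_recruitment, bone_density, ",
                          "bone_density_diameter, bone_interaction",
                          call. = FALSE))
  recr <- function(scale = 1)
    recruitment_offsets(0.0215 * scale, 0.00635 * scale, n_elements)
  if (name == "mtlt_base")
    return(fibre_params(recruitment = recr(), n_elements = n_elements))
  if (name == "mtlt_no_recruitment")
    return(fibre_params(recruitment = NULL, n_elements = n_elements))
  comp <- fractions_from_density(1.90)
  gamma_mc <- if (name == "bone_density") 200 else 200 * 1.8
  sl <- shear_lag_params(gamma_mc = gamma_mc, comp = comp)
  pl <- list()
  if (name == "bone_interaction")
    pl <- list(eps_y_ef = 0.012 * 1.81, chi_mc = 0.020 * 1.81,
               chi_ef = 0.03e-4 * 1.81)
  fibre_params(comp = comp, shear_lag = sl, plasticity = pl,
               recruitment = recr(0.25), n_elements = n_elements)
}
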