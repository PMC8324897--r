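small_params <- function(n = 24, recruitment = NULL, cov = 0.15,
                         peaks = c(0.02, 0.04), res = 5e-4, ...) {
  fibre_params(dist = distribution_spec(if (cov == 0) "degenerate" else "normal",
                                        cov = cov),
               recruitment = recruitment,
               protocol = make_protocol(peaks = peaks, resolution = res),
               n_elements = n, ...)
}

test_that("sampled parameters match their base values in distribution", {
  p <- fibre_params()
  set.seed(123)
  el <- sample_elements(p, 618)
  means <- c(E_min = 114, mu_col = 1.58, mu_ef = 0.003,
             eps_y_mc = 0.028, eps_y_ef = 0.012,
             eps_ult_ef = 0.09)
  for (nm in names(means)) {
    se <- 0.15 * means[[nm]] / sqrt(618)
    expect_lt(abs(mean(el[[nm]]) - means[[nm]]), 3 * se)
    expect_equal(sd(el[[nm]]) / means[[nm]], 0.15, tolerance = 0.2)
  }
  expect_true(all(el$E_app > 0 & el$E_mc > 0))
})

test_that("degenerate sampling reproduces the base values exactly", {
  p <- small_params(cov = 0)
  el <- sample_elements(p, 10)
  expect_true(all(el$E_min == 114))
  expect_equal(unique(el$E_app), fibre_modulus(p$shear_lag), tolerance = 1e-12)
})

test_that("skew-normal sampling honours mean, sd and skew sign", {
  spec <- distribution_spec("skew-normal", cov = 0.1, skew = 5)
  set.seed(77)
  x <- mcfibre:::sample_parameter(20000, 10, spec)
  expect_equal(mean(x), 10, tolerance = 0.01)
  expect_equal(sd(x), 1, tolerance = 0.05)
  m3 <- mean((x - mean(x))^3) / sd(x)^3
  expect_gt(m3, 0.3) # right-skewed
})

test_that("incompatible truncation raises a configuration error", {
  spec <- distribution_spec("normal", cov = 0.01, truncate_at = 0.9)
  set.seed(1)
  expect_error(mcfibre:::sample_parameter(10, -5, spec),
               "1000 consecutive rejected draws")
})

test_that("recruitment offsets follow the inverted sigmoid", {
  rm <- recruitment_offsets(0.0215, 0.00635, 618)
  expect_identical(rm$n_instantaneous, 20L)
  # median element sits at the sigmoid midpoint
  expect_equal(rm$offsets[309], -0.00635 * log(618 / 309 - 1) + 0.0215,
               tolerance = 1e-12)
  expect_true(all(diff(rm$offsets) > 0))           # monotone in element index
  expect_true(all(rm$offsets_applied >= 0))
  expect_true(all(is.finite(rm$offsets)))          # incl. the n = N endpoint
  # vanishing roughness: step recruitment, all offsets collapse to zero
  rm0 <- recruitment_offsets(0, 1e-9, 100)
  expect_lt(max(abs(rm0$offsets)), 1e-6)
  # the sigmoid itself is a strictly increasing fraction
  xi <- recruitment_fraction(seq(0, 0.1, 1e-3), 0.0215, 0.00635)
  expect_true(all(diff(xi) > 0) && all(xi > 0 & xi < 1))
})

test_that("a bundle of one identical element reproduces the element trace", {
  # peaks small enough that the free-standing element would not reverse-yield
  # at full unload, so the unilateral-contact bundle and the symmetric element
  # differ only by the tensile floor
  p <- small_params(n = 1, cov = 0, peaks = c(0.015, 0.02), res = 1e-4)
  s <- simulate_fibre(p, seed = 1)
  pr <- element_properties(E_app = fibre_modulus(p$shear_lag))
  tr <- element_path(pr, p$protocol$path)
  expect_equal(s$stress, pmax(tr$sigma, 0), tolerance = 1e-9)
})

test_that("cov -> 0 ensemble converges to the single-element response", {
  s_many <- simulate_fibre(small_params(n = 24, cov = 0), seed = 1)
  s_one <- simulate_fibre(small_params(n = 1, cov = 0), seed = 1)
  expect_equal(s_many$stress, s_one$stress, tolerance = 1e-12)
})

test_that("apparent stress is the mean of element stresses and activity never recovers", {
  p <- small_params(n = 40, peaks = c(0.04, 0.08, 0.12), res = 2e-4)
  s <- simulate_fibre(p, seed = 3)
  j <- which(!is.na(s$envelope$stress))
  jj <- round(s$envelope$strain / p$protocol$resolution)
  expect_equal(colMeans(s$env_sigma[, jj]), s$envelope$stress,
               tolerance = 1e-12)
  expect_true(all(diff(s$envelope$n_active) <= 0))
  expect_true(all(diff(s$envelope$n_recruited) >= 0))
  expect_true(all(s$stress >= 0))  # compressive protocol, unilateral contact
})

test_that("seeded runs are bit-reproducible", {
  p <- small_params(n = 16)
  a <- simulate_fibre(p, seed = 42)
  b <- simulate_fibre(p, seed = 42)
  expect_identical(a$stress, b$stress)
  expect_identical(a$elements, b$elements)
  c <- simulate_fibre(p, seed = 43)
  expect_false(identical(a$stress, c$stress))
})

test_that("unloading modulus equals the mean elastic modulus of loaded elements", {
  p <- fibre_params(n_elements = 100,
                    protocol = make_protocol(peaks = 0.03, resolution = 1e-4))
  s <- simulate_fibre(p, seed = 2)
  n_up <- which.max(s$strain)
  seg <- (n_up + 1):(n_up + 5) # just after the peak, all elements in contact
  slope <- mean(diff(s$stress[c(n_up, seg)]) / diff(s$strain[c(n_up, seg)]))
  expect_equal(slope, mean(s$elements$E_app), tolerance = 0.01)
})

test_that("strain-ratio distributions narrow as recruitment completes", {
  p <- fibre_params(n_elements = 200,
                    recruitment = recruitment_offsets(0.0215, 0.00635, 200),
                    protocol = make_protocol(peaks = c(0.02, 0.06),
                                             resolution = 2e-4))
  s <- simulate_fibre(p, seed = 8)
  early <- strain_ratios(s, 0.02)
  late <- strain_ratios(s, 0.055)
  expect_lt(var(late$fibril), var(early$fibril))
})

test_that("yield_point criteria behave on an analytic bilinear curve", {
  env <- data.frame(strain = seq(0, 0.03, 1e-4))
  env$stress <- pmin(16 * env$strain, 0.16)
  yo <- yield_point(env, criterion = "offset")
  expect_gte(yo$eps_y, 0.0119)
  expect_lte(yo$eps_y, 0.0125)
  expect_equal(yo$sigma_y, 0.16, tolerance = 1e-9)
  yi <- yield_point(env, criterion = "intersect")
  expect_equal(yi$eps_y, 0.01, tolerance = 0.1)
  # perfectly elastic curve: not-yielded sentinel under both criteria
  lin <- data.frame(strain = seq(0, 0.02, 1e-4))
  lin$stress <- 16 * lin$strain
  expect_true(is.na(yield_point(lin, criterion = "offset")$eps_y))
  expect_true(is.na(yield_point(lin, criterion = "intersect")$eps_y))
})

test_that("the vectorised bundle update agrees with the scalar element", {
  p <- small_params(n = 12, peaks = c(0.03, 0.05), res = 5e-4,
                    recruitment = recruitment_offsets(0.01, 0.004, 12))
  s <- simulate_fibre(p, seed = 21)
  path <- p$protocol$path
  env_j <- round(s$envelope$strain / p$protocol$resolution)
  for (i in c(1, 5, 12)) {
    pr <- element_properties(E_app = s$elements$E_app[i],
                             eps_y_mc = s$elements$eps_y_mc[i],
                             eps_y_ef = s$elements$eps_y_ef[i],
                             chi_mc = s$elements$chi_mc[i],
                             chi_ef = s$elements$chi_ef[i],
                             eps_ult_mc = s$elements$eps_ult_mc[i],
                             eps_ult_ef = s$elements$eps_ult_ef[i])
    off <- p$recruitment$offsets_applied[i]
    # monotone envelope comparison (contact always closed while loading)
    ramp <- pmax(s$envelope$strain - off, 0)
    tr <- element_path(pr, ramp)
    expect_equal(s$env_sigma[i, env_j], pmax(tr$sigma, 0), tolerance = 1e-9)
  }
})

test_that("sensitivity scan reproduces the heterogeneity ordering", {
  p <- scenario_preset("mtlt_base", n_elements = 150)
  p$protocol <- make_protocol(resolution = 2e-4)
  tab <- sensitivity_scan(p, covs = c(0.01, 0.15, 0.30), seed = 5)
  lo <- tab[tab$cov == 0.01, ]; mid <- tab[tab$cov == 0.15, ]
  hi <- tab[tab$cov == 0.30, ]
  # low heterogeneity: later first failures but abrupt post-peak collapse
  expect_gt(lo$first_failure_strain, mid$first_failure_strain)
  expect_gt(mid$first_failure_strain, hi$first_failure_strain)
  expect_gt(lo$softening_max_step, mid$softening_max_step)
  # high heterogeneity: visible softening
  expect_gt(hi$softening_drop, 0)
})

test_that("scenario presets assemble the documented configurations", {
  base <- scenario_preset("mtlt_base")
  expect_equal(base$shear_lag$E_min, 114)
  expect_equal(base$recruitment$mu, 0.0215)
  none <- scenario_preset("mtlt_no_recruitment")
  expect_null(none$recruitment)
  bd <- scenario_preset("bone_density")
  expect_equal(bd$comp$rho, 1.90, tolerance = 1e-9)
  bdd <- scenario_preset("bone_density_diameter")
  expect_equal(bdd$shear_lag$gamma_mc, 360)
  bi <- scenario_preset("bone_interaction")
  expect_equal(bi$plasticity$eps_y_ef, 0.012 * 1.81)
  expect_equal(bi$recruitment$mu, 0.0215 * 0.25)
  # stiffness ordering of the bone scenarios
  expect_gt(fibre_modulus(bd$shear_lag), fibre_modulus(base$shear_lag))
  expect_gt(fibre_modulus(bdd$shear_lag), fibre_modulus(bd$shear_lag))
  expect_error(scenario_preset("nope"), "available")
})

test_that("empty or inconsistent configurations are rejected", {
  expect_error(fibre_params(n_elements = 10,
                            recruitment = recruitment_offsets(0.02, 0.006, 9)),
               "built for 9 elements")
  expect_error(fibre_params(plasticity = list(bogus = 1)), "unknown plasticity")
})
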