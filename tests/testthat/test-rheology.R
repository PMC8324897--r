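test_that("the element is linear elastic below the first yield", {
  pr <- table2_element()
  tr <- element_path(pr, seq(1e-3, 0.011, by = 1e-3))
  expect_equal(tr$sigma, pr$E_app * tr$eps, tolerance = 1e-12)
  expect_true(all(tr$eps_p_mc == 0 & tr$eps_p_ef == 0))
  expect_equal(sum(tr$dissipation), 0)
})

test_that("perfect plasticity plateaus at the weaker slider, in tension and compression", {
  pr <- element_properties(E_app = 10, eps_y_mc = 0.03, eps_y_ef = 0.012,
                           chi_mc = 0, chi_ef = 0,
                           eps_ult_mc = 10, eps_ult_ef = 10)
  up <- element_path(pr, seq(0, 0.06, by = 1e-4))
  expect_equal(max(up$sigma), 10 * 0.012, tolerance = 1e-10)
  expect_true(all(abs(up$eps_p_mc) < 1e-14))  # only the weaker slider flows
  down <- element_path(pr, seq(0, -0.06, by = -1e-4))
  expect_equal(min(down$sigma), -10 * 0.012, tolerance = 1e-10)
})

test_that("monotonic ramp to 12% matches the sub-stepped oracle", {
  pr <- table2_element()
  path <- seq(0, 0.12, by = 1e-3)
  mine <- element_path(pr, path)
  orac <- oracle_element_path(pr, path, substep = 1e-6)
  expect_lt(max(abs(mine$sigma - orac$sigma)), 1e-6)
  # plastic strains agree while the element is alive; at the deactivation
  # step the oracle freezes mid-step whereas the return map completes it
  ok <- mine$active & orac$active
  expect_lt(max(abs(mine$eps_p_ef[ok] - orac$eps_p_ef[ok])), 1e-6)
  expect_lt(max(abs(mine$alpha_ef[ok] - orac$alpha_ef[ok])), 1e-6)
})

test_that("return mapping equals the sub-stepping oracle on random cyclic paths", {
  set.seed(1234)
  worst <- 0
  for (i in 1:100) {
    pr <- random_props()
    path <- random_path()
    mine <- element_path(pr, path)
    orac <- oracle_element_path(pr, path, substep = 1e-6)
    worst <- max(worst, max(abs(mine$sigma - orac$sigma)))
    expect_lt(max(abs(mine$sigma - orac$sigma)), 1e-6)
    expect_identical(mine$active, orac$active)
    # dissipation increments are non-negative at every step
    expect_true(all(mine$dissipation >= -1e-12))
    # alphas bound the plastic strains and never decrease
    expect_true(all(mine$alpha_mc >= abs(mine$eps_p_mc) - 1e-12))
    expect_true(all(mine$alpha_ef >= abs(mine$eps_p_ef) - 1e-12))
    expect_true(all(diff(mine$alpha_mc) >= -1e-15))
    expect_true(all(diff(mine$alpha_ef) >= -1e-15))
  }
  expect_lt(worst, 1e-6)
})

test_that("KKT complementarity holds after every step", {
  set.seed(99)
  for (i in 1:20) {
    pr <- random_props()
    pr$eps_ult_mc <- 1; pr$eps_ult_ef <- 1  # keep the element alive
    path <- random_path(n_steps = 30)
    st <- element_state()
    eps_prev <- 0
    for (eps in path) {
      attr(st, "eps_prev") <- eps_prev
      res <- element_step(st, pr, eps)
      st <- res$state; eps_prev <- eps
      f_mc <- abs(res$sigma) - (pr$E_app * pr$eps_y_mc + pr$chi_mc * st$alpha_mc)
      f_ef <- abs(res$sigma) - (pr$E_app * pr$eps_y_ef + pr$chi_ef * st$alpha_ef)
      expect_lt(f_mc, 1e-9)
      expect_lt(f_ef, 1e-9)
    }
  }
})

test_that("unloading from a plastic state follows the elastic slope exactly", {
  pr <- table2_element()
  up <- seq(0, 0.05, by = 1e-4)
  down <- seq(0.05, 0.03, by = -1e-4)
  tr <- element_path(pr, c(up, down))
  n_up <- length(up)
  seg <- tr[(n_up + 1):(n_up + length(down)), ]
  slopes <- diff(seg$sigma) / diff(seg$eps)
  expect_equal(slopes, rep(pr$E_app, length(slopes)), tolerance = 1e-9)
})

test_that("deactivation at ultimate strain is permanent and zero-stress", {
  pr <- element_properties(E_app = 10, eps_y_ef = 0.01, eps_ult_ef = 0.02,
                           eps_ult_mc = 2, chi_ef = 0)
  tr <- element_path(pr, seq(0, 0.05, by = 1e-4))
  k <- which(!tr$active)[1]
  expect_false(is.na(k))
  expect_true(all(tr$sigma[k:nrow(tr)] == 0))
  expect_true(all(!tr$active[k:nrow(tr)]))
  # plastic strain at failure just exceeded the ultimate value
  expect_gt(abs(tr$eps_p_ef[k]), pr$eps_ult_ef)
})

test_that("dissipation matches closed forms and the energy balance", {
  # purely elastic path
  pr <- table2_element()
  el <- element_path(pr, c(0.005, 0.01, 0.002))
  expect_equal(dissipation_of_path(el), 0)

  # single plastic half-cycle at perfect plasticity:
  # plateau stress times accumulated plastic strain
  pp <- element_properties(E_app = 10, eps_y_ef = 0.01, chi_ef = 0,
                           eps_y_mc = 1, eps_ult_mc = 10, eps_ult_ef = 10)
  tr <- element_path(pp, seq(0, 0.04, by = 1e-4))
  plateau <- 10 * 0.01
  expect_equal(dissipation_of_path(tr),
               plateau * tr$alpha_ef[nrow(tr)], tolerance = 1e-9)

  # arbitrary cyclic path: dissipation = work input - stored energy change
  set.seed(5)
  for (i in 1:20) {
    pr <- random_props()
    pr$eps_ult_mc <- 1; pr$eps_ult_ef <- 1
    path <- random_path(n_steps = 40)
    tr <- element_path(pr, path)
    sig <- c(0, tr$sigma); eps <- c(0, tr$eps)
    work <- sum(0.5 * (sig[-1] + sig[-length(sig)]) * diff(eps))
    e_last <- tr$eps[nrow(tr)] - tr$eps_p_mc[nrow(tr)] - tr$eps_p_ef[nrow(tr)]
    stored <- 0.5 * pr$E_app * e_last^2
    expect_equal(dissipation_of_path(tr), work - stored, tolerance = 1e-9)
    expect_gte(dissipation_of_path(tr), -1e-12)
    expect_equal(sum(tr$dissipation), dissipation_of_path(tr),
                 tolerance = 1e-12)
  }
})

test_that("non-finite strains are rejected", {
  expect_error(element_step(element_state(), table2_element(), NaN), "finite")
  expect_error(element_step(element_state(), table2_element(), Inf), "finite")
})
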