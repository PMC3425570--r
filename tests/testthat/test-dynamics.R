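test_that("integration reproduces closed-form first-order decay", {
  # A -> B at rate k: only the deactivation reaction active
  m <- build_network("full", overrides = stats::setNames(
    rep(0, 60), setdiff(names(hsp90_parameters()$values),
                        c("k_deact", "hsf1_init"))))
  # HSF1S -> HSF1 at k_deact; start with 100 nM HSF1S only
  x0 <- stats::setNames(rep(0, 27), m$species$name)
  x0["HSF1S"] <- 100
  k <- m$parameters$values[["k_deact"]]
  tc <- integrate_network(m, x0, times = c(0, 10 / k))
  expect_equal(tc$HSF1S[2], 100 * exp(-10), tolerance = 1e-5)
  expect_equal(tc$HSF1[2], 100 * (1 - exp(-10)), tolerance = 1e-5)
})

test_that("all-zero rate constants freeze the trajectory", {
  ov <- stats::setNames(rep(0, 62), names(hsp90_parameters()$values))
  ov[c("hsf1_init", "hse_tot", "mk3_tot", "pp5_tot")] <- c(289, 1320, 92, 39.1)
  m <- build_network("full", params = hsp90_parameters(ov))
  x0 <- default_initial_state(m)
  tc <- integrate_network(m, x0, times = c(0, 1e4, 1e5))
  for (j in seq_along(x0)) expect_equal(tc[[1 + j]], rep(unname(x0[j]), 3))
})

test_that("trajectories conserve every moiety and stay non-negative", {
  m <- build_network("full", params = hsp90_parameters(k_stress = 1.2066))
  tc <- integrate_network(m, times = seq(0, 14400, length.out = 60))
  vals <- as.matrix(tc[, -1])
  expect_true(all(vals >= 0))
  for (y in conserved_moieties(m)) {
    tot <- vals %*% y[m$species$name]
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
})

test_that("halving the tolerances leaves reported trajectories unchanged", {
  m <- build_network("full", params = hsp90_parameters(k_stress = 0.9859))
  tms <- seq(0, 7200, length.out = 25)
  tc1 <- integrate_network(m, times = tms, atol = 1e-9, rtol = 1e-7)
  tc2 <- integrate_network(m, times = tms, atol = 5e-10, rtol = 5e-8)
  rel <- abs(as.matrix(tc1[, -1]) - as.matrix(tc2[, -1])) /
    (1 + abs(as.matrix(tc1[, -1])))
  expect_lt(max(rel), 1e-3)
})

test_that("high-stress runs settle at an elevated trimer plateau", {
  m <- build_network("full")
  p_hi <- hsp90_parameters(k_stress = 1.2066)
  p_lo <- hsp90_parameters(k_stress = 0.4136)
  tms <- seq(0, 14400, length.out = 30)
  hi <- integrate_network(m, times = tms, params = p_hi)
  lo <- integrate_network(m, times = tms, params = p_lo)
  # 43C-like condition ends far above the 41C-like one
  expect_gt(dplyr::last(hi$HSF1_3S), 5 * dplyr::last(lo$HSF1_3S))
  # and does not decay back towards zero at the end of the horizon
  expect_gt(dplyr::last(hi$HSF1_3S), 0.5 * max(hi$HSF1_3S))
})

test_that("steady_state solves toy fixed points with correct stability", {
  # first-order decay: x' = -kx -> 0, stable
  dec <- ode_problem(function(x, p) -0.3 * x, n = 1,
                     jac = function(x, p) matrix(-0.3, 1, 1))
  s <- steady_state(dec, 5)
  expect_true(s$converged && s$stable)
  expect_equal(unname(s$state), 0, tolerance = 1e-9)
  # logistic: x' = x(1-x); 1 stable from 0.6, 0 unstable from exactly 0
  lg <- ode_problem(function(x, p) x * (1 - x), n = 1,
                    jac = function(x, p) matrix(1 - 2 * x, 1, 1))
  s1 <- steady_state(lg, 0.6, fallback = FALSE)
  expect_true(s1$converged && s1$stable)
  expect_equal(unname(s1$state), 1, tolerance = 1e-9)
  s0 <- steady_state(lg, 0, fallback = FALSE)
  expect_true(s0$converged && !s0$stable)
  expect_equal(unname(s0$state), 0)
})

test_that("full-model steady states satisfy the residual contract and are
           fixed points of the integrator", {
  m <- build_network("full", params = hsp90_parameters(k_stress = 0.8))
  x_eq <- hsp90net:::equilibrate(m, default_initial_state(m))
  ss <- steady_state(m, pmax(x_eq, 0), tol = 1e-9)
  expect_true(ss$converged)
  expect_lte(ss$residual_norm, 1e-9)
  expect_true(ss$stable)
  # re-integration from the steady state stays put
  tc <- integrate_network(m, pmax(unname(ss$state), 0), times = c(0, 1e5))
  drift <- max(abs(as.numeric(tc[2, -1]) - unname(ss$state)) /
                 (1 + abs(unname(ss$state))))
  expect_lt(drift, 1e-6)
})

test_that("bistable window yields two distinct stable states from opposite guesses", {
  m <- build_network("full")
  p <- hsp90_parameters(k_stress = 2.6)   # inside the high-stress window
  bf <- brute_force_steady_states(m, p, parameter_grid = 2.6, n_starts = 8,
                                  seed = 2)
  expect_gte(bf$n_stable[1], 2L)
  H <- bf$states[[1]][, "HSP90c"]
  expect_gt(max(H) / max(min(H), 1e-6), 5)
})

test_that("percent conversion normalizes to max 100 and is scale invariant", {
  expect_equal(percent_conversion(c(10, 50, 25)), c(20, 100, 50))
  expect_equal(percent_conversion(c(7, 7, 7)), c(100, 100, 100))
  y <- c(0.3, 1.2, 0.8, 2.0)
  expect_equal(percent_conversion(y), percent_conversion(1e6 * y))
  expect_error(percent_conversion(c(0, 0, 0)), "positive")
  tc <- tibble::tibble(time = 1:3, A = c(1, 4, 2))
  expect_equal(percent_conversion(tc, "A"), c(25, 100, 50))
  expect_error(percent_conversion(tc, "B"), "not present")
})
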