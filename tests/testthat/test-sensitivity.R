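stressed_params <- function() hsp90_parameters(k_stress = 0.9859)

test_that("decay-toy sensitivity matches the closed form dy/dk = -t y", {
  # single active reaction HSF1S -> HSF1 at k_deact; y = HSF1S
  ov <- stats::setNames(rep(0, 62), names(hsp90_parameters()$values))
  ov["k_deact"] <- 1 / 3600
  m <- build_network("full", params = hsp90_parameters(ov))
  x0 <- stats::setNames(rep(0, 27), m$species$name)
  x0["HSF1S"] <- 100
  tms <- c(1800, 3600, 7200)
  S <- dynamic_sensitivities(m, outputs = "HSF1S", times = tms,
                             parameters = "k_deact", x0 = x0)
  k <- ov[["k_deact"]]
  expected <- -tms * 100 * exp(-k * tms)
  expect_equal(unname(S["HSF1S", "k_deact", ]), unname(expected),
               tolerance = 1e-4)
  # relative index: SI = dy/dk * k / y = -k t
  si <- relative_sensitivity_indices(S)
  expect_equal(unname(si$si_time["HSF1S", "k_deact", ]), unname(-k * tms),
               tolerance = 1e-4)
})

test_that("a parameter with no path to the output has a zero column", {
  m <- build_network("full")
  # at zero stress the activation constant never acts
  S <- dynamic_sensitivities(m, params = hsp90_parameters(k_stress = 0),
                             outputs = "HSP90c", times = c(600, 3600),
                             parameters = c("k_act", "kd_mrna"))
  expect_true(all(S["HSP90c", "k_act", ] == 0))
  expect_false(all(S["HSP90c", "kd_mrna", ] == 0))
})

test_that("finite-difference and forward-equation paths agree", {
  m <- build_network("full")
  p <- stressed_params()
  pars <- c("k_act", "k_k1_c", "k_tl")
  tms <- c(600, 1800, 3600)
  S_fd <- dynamic_sensitivities(m, p, outputs = "HSF1_3S", times = tms,
                                parameters = pars, method = "fd")
  S_fw <- dynamic_sensitivities(m, p, outputs = "HSF1_3S", times = tms,
                                parameters = pars, method = "forward")
  scale <- max(abs(S_fw))
  expect_lt(max(abs(S_fd - S_fw)) / scale, 1e-3)
})

test_that("relative indices recover log-derivatives of power laws", {
  # y = p: SI = 1; y = p^2: SI = 2 (constructed raw arrays)
  raw <- array(0, dim = c(2, 1, 2),
               dimnames = list(c("lin", "quad"), "p", c("t1", "t2")))
  pval <- 3
  raw["lin", "p", ] <- 1                 # dy/dp for y = p
  raw["quad", "p", ] <- 2 * pval         # dy/dp for y = p^2
  yv <- rbind(lin = c(pval, pval), quad = c(pval^2, pval^2))
  attr(raw, "parameter_values") <- pval
  si <- relative_sensitivity_indices(raw, outputs_values = yv)
  expect_equal(unname(si$si_matrix["lin", "p"]), 1)
  expect_equal(unname(si$si_matrix["quad", "p"]), 2)
})

test_that("SI is dimensionless: output rescaling leaves it unchanged", {
  m <- build_network("full")
  p <- stressed_params()
  S <- dynamic_sensitivities(m, p, outputs = "HHp", times = c(600, 3600),
                             parameters = c("k_k1_c", "k_p4_c"))
  si1 <- relative_sensitivity_indices(S)
  S2 <- S * 1e3
  attr(S2, "outputs_values") <- attr(S, "outputs_values") * 1e3
  attr(S2, "parameter_values") <- attr(S, "parameter_values")
  si2 <- relative_sensitivity_indices(S2)
  expect_equal(si1$si_matrix, si2$si_matrix, tolerance = 1e-12)
})

test_that("correlation matrix is symmetric, unit-diagonal and PSD", {
  m <- build_network("full")
  p <- stressed_params()
  S <- dynamic_sensitivities(m, p, outputs = c("HSF1_3S", "HHp"),
                             times = default_sampling_times(),
                             parameters = c("k_act", "k_rel", "k_k1_c",
                                            "k_p4_c", "k_tx"))
  C <- sensitivity_correlation_matrix(S)
  expect_true(isSymmetric(C))
  expect_equal(unname(diag(C)), rep(1, ncol(C)))
  expect_true(all(abs(C[!is.na(C)]) <= 1 + 1e-12))
  ev <- eigen(C, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("duplicated and lumped parameters give |correlation| 1", {
  # duplicate column: correlation +1 by construction
  raw <- array(stats::rnorm(2 * 3 * 5), dim = c(2, 3, 5),
               dimnames = list(c("a", "b"), c("p1", "p2", "p3"), NULL))
  raw[, 2, ] <- raw[, 1, ]
  C <- sensitivity_correlation_matrix(raw)
  expect_equal(unname(C["p1", "p2"]), 1)
  # two constants entering the dynamics only through their ratio: the
  # dimerization pair is equilibrium-slaved, so their sensitivity profiles
  # are anti-proportional
  m <- build_network("full")
  p <- stressed_params()
  S <- dynamic_sensitivities(m, p, outputs = "HSF1_3S",
                             times = c(1200, 3600, 7200, 14400),
                             parameters = c("k_dim_f", "k_dim_b"))
  C2 <- sensitivity_correlation_matrix(S)
  expect_true(abs(C2["k_dim_f", "k_dim_b"]) > 0.99)
})

test_that("zero-variance columns are flagged, not NaN-propagated", {
  raw <- array(stats::rnorm(1 * 2 * 4), dim = c(1, 2, 4),
               dimnames = list("y", c("live", "dead"), NULL))
  raw[, 2, ] <- 0
  C <- sensitivity_correlation_matrix(raw)
  expect_identical(unname(diag(C)), c(1, 1))
  expect_true(is.na(C["live", "dead"]))
  expect_false(any(is.nan(C)))
})
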