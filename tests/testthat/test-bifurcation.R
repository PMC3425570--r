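test_that("continuation locates the cubic normal-form folds to 1e-4", {
  cubic <- toy_cubic()
  ss <- steady_state(cubic, -1.2, params = -1)
  br <- continue_branch(cubic, params = -1, parameter_name = "mu",
                        range = c(-1, 1), start = ss, start_value = -1)
  lp <- sort(br$special_points$parameter_value[br$special_points$kind == "limit_point"])
  expect_length(lp, 2L)
  expect_equal(lp, c(-2, 2) / (3 * sqrt(3)), tolerance = 1e-4)
  # turning points traversed: parameter range covered on both sides
  expect_lt(min(br$points$parameter), -0.9)
  expect_gt(max(br$points$parameter), 0.9)
})

test_that("a monotone branch records no special points", {
  lin <- ode_problem(function(x, p) p - x, n = 1,
                     jac = function(x, p) matrix(-1, 1, 1),
                     fp = function(x, p) 1)
  dg <- bifurcation_diagram(lin, params = -1, parameter_name = "mu",
                            range = c(-1, 1), observable = "x1", x0 = -1)
  expect_identical(nrow(dg$special_points), 0L)
  expect_identical(dg$classification, "monostable")
})

test_that("continuation is direction-symmetric at the folds", {
  cubic <- toy_cubic()
  ss_lo <- steady_state(cubic, -1.2, params = -1)
  br_up <- continue_branch(cubic, params = -1, parameter_name = "mu",
                           range = c(-1, 1), start = ss_lo, start_value = -1)
  ss_hi <- steady_state(cubic, 1.2, params = 1)
  br_dn <- continue_branch(cubic, params = 1, parameter_name = "mu",
                           range = c(-1, 1), start = ss_hi, start_value = 1,
                           step_opts = list(direction = -1))
  lp_up <- sort(br_up$special_points$parameter_value[br_up$special_points$kind == "limit_point"])
  lp_dn <- sort(br_dn$special_points$parameter_value[br_dn$special_points$kind == "limit_point"])
  expect_equal(lp_up, lp_dn, tolerance = 1e-5)
})

test_that("brute force finds both cubic attractors inside the fold interval", {
  cubic <- toy_cubic()
  bf <- brute_force_steady_states(cubic, parameter_grid = c(0, 1),
                                  n_starts = 10, seed = 2)
  expect_identical(bf$n_stable, c(2L, 1L))
  expect_equal(sort(bf$states[[1]][, 1]), c(-1, 1), tolerance = 1e-6)
})

test_that("every reported branch point satisfies the steady-state contract", {
  m <- build_network("full")
  dg <- bifurcation_diagram(m, range = c(0, 3), observable = "HSP90c",
                            step_opts = list(max_points = 1500, h_max = 0.1))
  pts <- dg$branches[[1]]$points
  idx <- unique(round(seq(1, nrow(pts), length.out = 40)))
  for (i in idx) {
    x <- as.numeric(pts[i, -(1:6)])
    pp <- hsp90_parameters(k_stress = pts$parameter[i])
    f <- network_rhs(m, pmax(x, 0), params = pp)
    expect_lt(max(abs(f)), 1e-6)
  }
})

test_that("classification rules distinguish the canonical topologies", {
  mk_branch <- function(par, val, stable = TRUE, closed = FALSE,
                        lps = numeric(0)) {
    pts <- tibble::tibble(parameter = par, stable = stable, marginal = FALSE,
                          physical = TRUE, re_leading = -1, im_leading = 0,
                          HSP90c = val)
    sp <- tibble::tibble(kind = rep("limit_point", length(lps)),
                         parameter_value = lps,
                         state = lapply(lps, function(z) c(HSP90c = 1)))
    structure(list(points = pts, special_points = sp, closed = closed,
                   termination = "range_exit", parameter_name = "k_stress",
                   range = c(0, 3), totals = numeric(0)),
              class = "hsp90_branch")
  }
  # monotone -> monostable
  b1 <- mk_branch(seq(0, 3, 0.1), seq(0, 3, 0.1))
  expect_identical(classify_diagram(list(b1), range = c(0, 3))$classification,
                   "monostable")
  # steep logistic -> ultrasensitive_monostable
  p <- seq(0, 3, 0.01)
  b2 <- mk_branch(p, 1 / (1 + exp(-80 * (p - 1.5))))
  expect_identical(classify_diagram(list(b2), range = c(0, 3))$classification,
                   "ultrasensitive_monostable")
  # 2 LPs, upper state at high parameter -> s_hysteresis
  p3 <- c(seq(0, 2, 0.05), seq(2, 1, -0.05), seq(1, 3, 0.05))
  v3 <- c(seq(0, 0.2, length.out = 41), seq(0.2, 0.5, length.out = 21),
          seq(0.5, 3, length.out = 41))
  b3 <- mk_branch(p3, v3, lps = c(1, 2))
  expect_identical(classify_diagram(list(b3), range = c(0, 3))$classification,
                   "s_hysteresis")
  # 4 LPs with two disjoint windows -> mushroom
  b4 <- mk_branch(seq(0, 3, 0.05), seq(0, 3, 0.05),
                  lps = c(0.5, 0.7, 1.5, 2.0))
  expect_identical(classify_diagram(list(b4), range = c(0, 3))$classification,
                   "mushroom")
  # odd LP count (partner outside the range) -> irreversible
  b5 <- mk_branch(seq(0, 3, 0.05), seq(0, 3, 0.05), lps = 1.2)
  expect_identical(classify_diagram(list(b5), range = c(0, 3))$classification,
                   "irreversible")
  # closed loop plus separate branch -> isola_plus_branch
  b6 <- mk_branch(seq(0, 3, 0.05), rep(0.1, 61))
  b7 <- mk_branch(c(seq(1, 2, 0.05), seq(2, 1, -0.05)),
                  c(seq(1, 1.5, length.out = 21), seq(1.5, 1, length.out = 21)),
                  closed = TRUE)
  expect_identical(classify_diagram(list(b6, b7),
                                    range = c(0, 3))$classification,
                   "isola_plus_branch")
})

test_that("zero-length knockout reproduces the baseline diagram exactly", {
  m <- build_network("full")
  p <- m$parameters
  dg0 <- bifurcation_diagram(m, range = c(0, 1), observable = "HSP90c",
                             step_opts = list(max_points = 400, h_max = 0.1))
  dg1 <- feedback_knockout_scan(m, p, range = c(0, 1), knockout = character(0),
                                step_opts = list(max_points = 400, h_max = 0.1))
  expect_equal(dg0$branches[[1]]$points$parameter,
               dg1$branches[[1]]$points$parameter, tolerance = 1e-10)
  expect_identical(dg0$classification, dg1$classification)
})

test_that("secondary scan at the baseline value reproduces the baseline diagram", {
  m <- build_network("full")
  base_val <- m$parameters$values[["k_k1_c"]]
  sc <- secondary_parameter_scan(m, secondary_values = base_val,
                                 range = c(0, 3),
                                 step_opts = list(max_points = 1500, h_max = 0.1))
  dg0 <- bifurcation_diagram(m, range = c(0, 3), observable = "HSP90c",
                             step_opts = list(max_points = 1500, h_max = 0.1))
  expect_identical(sc$classification[1], dg0$classification)
  lp0 <- sort(dg0$special_points$parameter_value[dg0$special_points$kind == "limit_point"])
  lp1 <- sort(sc$diagram[[1]]$special_points$parameter_value[
    sc$diagram[[1]]$special_points$kind == "limit_point"])
  expect_equal(lp0, lp1, tolerance = 1e-8)
})

test_that("stability flags agree with perturbed reintegration on sampled points", {
  m <- build_network("full")
  dg <- bifurcation_diagram(m, range = c(0, 3), observable = "HSP90c",
                            step_opts = list(max_points = 1200, h_max = 0.1))
  pts <- dg$branches[[1]]$points
  stab <- which(pts$stable & pts$physical)
  pick <- stab[unique(round(seq(1, length(stab), length.out = 4)))]
  for (i in pick) {
    x <- pmax(as.numeric(pts[i, -(1:6)]), 0)
    pp <- hsp90_parameters(k_stress = pts$parameter[i])
    x_kick <- pmax(x * (1 + 0.01), 0)   # 1% multiplicative kick
    tc <- integrate_network(m, x_kick, times = c(0, 2e5), params = pp)
    back <- max(abs(as.numeric(tc[2, -1]) - x) / (1 + x))
    expect_lt(back, 5e-2)
  }
})
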