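test_that("cost is zero at the truth and counts squared residuals", {
  m <- full_model()
  st <- generate_study(m, noise_sd = 0, seed = 4, times = short_times)
  expect_identical(cost_function(m, st), 0)
  # one experiment, one residual of 2 percent -> cost 4
  ex <- st$datasets[[1]]
  ex$values_percent[3] <- ex$values_percent[3] + 2
  expect_equal(cost_function(m, list(ex)), 4, tolerance = 1e-8)
  expect_error(cost_function(m, list()), "empty")
})

test_that("cost at the truth on noisy data equals the injected noise exactly", {
  m <- full_model()
  st <- generate_study(m, noise_sd = 5, seed = 11, times = short_times)
  inj <- sum(unlist(lapply(st$datasets, function(e) e$injected_noise^2)))
  expect_equal(cost_function(m, st), inj, tolerance = 1e-10)
})

test_that("cost is invariant to experiment and sampling-point order", {
  m <- full_model()
  st <- generate_study(m, noise_sd = 5, seed = 6, times = short_times)
  c0 <- cost_function(m, st)
  expect_equal(cost_function(m, rev(st$datasets)), c0, tolerance = 1e-10)
  shuf <- lapply(st$datasets, function(e) {
    o <- c(3, 1, 5, 2, 4)
    e$times <- e$times[o]; e$values_percent <- e$values_percent[o]
    e$injected_noise <- e$injected_noise[o]
    e
  })
  expect_equal(cost_function(m, shuf), c0, tolerance = 1e-10)
})

test_that("single-parameter refit recovers the generating stress to 1e-3 relative", {
  m <- full_model()
  for (truth in c(0.4136, 0.9859)) {
    d <- generate_timecourse_data(m, k_stress = truth, species = "HSF1_3S",
                                  times = short_times, noise_sd = 0, seed = 1)
    fit <- fit_single_parameter(m, list(d), "k_stress", bracket = c(0.1, 3))
    expect_lt(abs(fit$stress_values[1] - truth) / truth, 1e-3)
    # the optimum beats both bracket ends
    c_lo <- cost_function(m, list(d), stress_values = 0.1)
    c_hi <- cost_function(m, list(d), stress_values = 3)
    expect_lte(fit$cost, min(c_lo, c_hi))
  }
})

test_that("single-parameter refit also recovers a kinetic constant", {
  m <- full_model()
  d <- generate_timecourse_data(m, k_stress = 0.9557, species = "HHp",
                                times = short_times, noise_sd = 0, seed = 2)
  truth <- m$parameters$values[["k_deact"]]
  fit <- fit_single_parameter(m, list(d), "k_deact",
                              bracket = truth * c(1 / 5, 5))
  expect_lt(abs(fit$parameters$values[["k_deact"]] - truth) / truth, 0.05)
})

test_that("zero-width bounds return the bound point and its cost", {
  m <- full_model()
  st <- generate_study(m, noise_sd = 0, seed = 4, times = short_times)
  v <- m$parameters$values[["k_act"]]
  fit <- fit_global(m, st, free_names = "k_act",
                    bounds = cbind(c(v, st$truth$stress_values),
                                   c(v, st$truth$stress_values)),
                    seed = 1, budget = 10)
  expect_equal(fit$parameters$values[["k_act"]], v)
  expect_equal(fit$cost, 0, tolerance = 1e-8)
})

test_that("scatter search recovers perturbed constants on noiseless data and
           its trace is non-increasing", {
  m <- full_model()
  st <- generate_study(m, noise_sd = 0, seed = 9, times = short_times)
  fit <- fit_global(m, st, free_names = c("k_act", "k_rel"), span = 0.7,
                    seed = 3, budget = 260, refset_size = 6)
  expect_true(all(diff(fit$trace) <= 0))
  expect_lte(fit$cost, fit$trace[1])
  # recovered stress values close to the generating ones
  expect_equal(fit$stress_values, st$truth$stress_values, tolerance = 0.1)
  # cost field equals a re-evaluation at the returned parameters
  c_re <- cost_function(m, st, fit$parameters, stress_values = fit$stress_values)
  expect_equal(fit$cost, c_re, tolerance = 1e-9)
})

test_that("cold-started runs with different seeds give similar costs but
           different parameter vectors", {
  m <- full_model()
  st <- generate_study(m, noise_sd = 5, seed = 21, times = short_times)
  fn <- c("k_tri_f", "k_tri_b", "k_dim_f", "k_dim_b")
  fits <- lapply(c(5, 6), function(s)
    fit_global(m, st, free_names = fn, span = 1,
               seed = s, budget = 220, refset_size = 6, warm_start = FALSE))
  costs <- vapply(fits, `[[`, 0, "cost")
  inj <- sum(unlist(lapply(st$datasets, function(e) e$injected_noise^2)))
  # both runs reach the noise-floor neighbourhood with comparable costs
  expect_lt(abs(costs[1] - costs[2]) / max(costs), 0.5)
  expect_lt(max(costs), 5 * inj)
  # ... but end in different corners of the degenerate oligomerization ridge
  th <- vapply(fits, function(f) unname(f$parameters$values[fn]), numeric(4))
  expect_gt(max(abs(log10(th[, 1] / th[, 2]))), 0.02)
})
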