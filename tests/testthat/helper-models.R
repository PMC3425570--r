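# shared fixtures built in code

toy_cubic <- function() {
  ode_problem(function(x, p) p + x - x^3, n = 1,
              jac = function(x, p) matrix(1 - 3 * x^2, 1, 1),
              fp = function(x, p) 1)
}

# two-step linear chain A -> B -> C used for estimation recovery tests:
# built from the full machinery via a wrapped ode_problem is overkill; the
# estimation tests instead refit k_stress / named constants of the full model.

full_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_network("full")
    cache
  }
})

# a short time grid keeping integration cheap in unit tests
short_times <- c(60, 300, 1200, 3600, 7200)
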