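#' Wrap a plain ODE system for the steady-state and continuation tools
#'
#' Lets \code{\link{steady_state}}, \code{\link{continue_branch}},
#' \code{\link{bifurcation_diagram}} and
#' \code{\link{brute_force_steady_states}} operate on arbitrary autonomous
#' systems \code{dx/dt = f(x, p)} with a scalar parameter — used for normal
#' forms (e.g. the cubic fold \code{mu + x - x^3}) that serve as closed-form
#' oracles for the continuation engine.
#'
#' @param f function of \code{(x, p)} returning the derivative vector.
#' @param n state dimension.
#' @param jac optional Jacobian function of \code{(x, p)} returning an
#'   \code{n x n} matrix; central finite differences when omitted.
#' @param fp optional derivative of \code{f} with respect to \code{p};
#'   finite differences when omitted.
#' @param state_names character labels for the state components.
#' @return an object of class \code{ode_problem}.
#' @examples
#' cubic <- ode_problem(function(x, p) p + x - x^3, n = 1)
#' @export
ode_problem <- function(f, n, jac = NULL, fp = NULL,
                        state_names = paste0("x", seq_len(n))) {
  stopifnot(is.function(f), n >= 1)
  if (is.null(jac)) {
    jac <- function(x, p) {
      J <- matrix(0, n, n)
      for (i in seq_len(n)) {
        h <- 1e-6 * max(1, abs(x[i]))
        xp <- x; xm <- x; xp[i] <- x[i] + h; xm[i] <- x[i] - h
        J[, i] <- (f(xp, p) - f(xm, p)) / (2 * h)
      }
      J
    }
  }
  if (is.null(fp)) {
    fp <- function(x, p) {
      h <- 1e-6 * max(1, abs(p))
      (f(x, p + h) - f(x, p - h)) / (2 * h)
    }
  }
  structure(list(f = f, jac = jac, fp = fp, n = n, state_names = state_names),
            class = "ode_problem")
}

# Uniform continuation interface over hsp90_model (moiety-reduced) and
# ode_problem (direct). Returns the functions the continuation core needs.
cont_problem <- function(model, params, parameter_name, x_start) {
  if (inherits(model, "hsp90_model")) {
    red <- moiety_reduction(model)
    totals <- moiety_totals(red, unname(x_start))
    list(
      n = length(red$indep),
      x_ind = unname(x_start)[red$indep],
      F = function(xi, p) reduced_rhs(model, red, xi, totals,
                                      param_assign(params, parameter_name, p)),
      J = function(xi, p) reduced_jacobian(model, red, xi, totals,
                                           param_assign(params, parameter_name, p)),
      Fp = function(xi, p) {
        pp <- param_assign(params, parameter_name, p)
        xf <- expand_state(red, xi, totals)
        rhs_param_derivative(model, xf, parameter_name, pp)[red$indep]
      },
      expand = function(xi) stats::setNames(expand_state(red, xi, totals),
                                            model$species$name),
      names = model$species$name,
      totals = totals,
      check_physical = TRUE
    )
  } else if (inherits(model, "ode_problem")) {
    list(
      n = model$n,
      x_ind = unname(x_start),
      F = function(xi, p) model$f(xi, p),
      J = function(xi, p) model$jac(xi, p),
      Fp = function(xi, p) model$fp(xi, p),
      expand = function(xi) stats::setNames(xi, model$state_names),
      names = model$state_names,
      totals = numeric(0),
      check_physical = FALSE   # generic states may be legitimately negative
    )
  } else stop("model must be an hsp90_model or an ode_problem")
}
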