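#' Integrate the network ODE system
#'
#' Solves the stiff initial-value problem with \code{deSolve::lsoda} using
#' the analytic Jacobian. The model mixes sub-second
#' phosphorylation-dephosphorylation kinetics with hour-scale transcription,
#' so a stiff method is required.
#'
#' @param model an \code{hsp90_model}.
#' @param x0 non-negative initial concentration vector (defaults to
#'   \code{\link{default_initial_state}}).
#' @param times output time grid (s), strictly increasing.
#' @param atol,rtol absolute (nM) and relative integrator tolerances.
#' @param params optional parameter set overriding the model's.
#' @return a tibble of class \code{hsp90_timecourse} with columns
#'   \code{time} and one column per species (nM); tiny negative excursions
#'   within integrator slack are clamped to zero.
#' @examples
#' m <- build_network(params = hsp90_parameters(k_stress = 1))
#' tc <- integrate_network(m, times = seq(0, 600, by = 60))
#' @export
integrate_network <- function(model, x0 = default_initial_state(model),
                              times = seq(0, 14400, length.out = 241),
                              atol = 1e-9, rtol = 1e-7,
                              params = model$parameters) {
  stopifnot(inherits(model, "hsp90_model"))
  if (length(x0) != model$n_species) stop("x0 length must equal species count")
  if (any(x0 < 0)) stop("initial state must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (atol <= 0 || rtol <= 0) stop("tolerances must be positive")

  func <- function(t, y, p) list(network_rhs_raw(model, y, params))
  jac <- function(t, y, p) network_jacobian(model, pmax(y, 0), params)
  out <- deSolve::lsoda(y = unname(x0), times = times, func = func, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        atol = atol, rtol = rtol, maxsteps = 50000)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop(sprintf("integration failure (istate = %d) near t = %.6g s",
                 diagn[1], max(out[, 1])))
  }
  if (nrow(out) < length(times)) {
    stop(sprintf("integration failure: stopped at t = %.6g s", max(out[, 1])))
  }
  vals <- out[, -1, drop = FALSE]
  slack <- 100 * atol + 1e-12
  if (any(vals < -slack)) {
    # beyond tolerance slack: report, do not silently clamp
    warning("negative concentrations beyond integrator slack; check tolerances")
  }
  vals[vals < 0] <- 0
  colnames(vals) <- model$species$name
  tc <- tibble::as_tibble(as.data.frame(vals))
  tc <- dplyr::bind_cols(tibble::tibble(time = out[, 1]), tc)
  class(tc) <- c("hsp90_timecourse", class(tc))
  tc
}

# rhs without the non-negativity guard (the integrator may probe slightly
# negative states internally).
network_rhs_raw <- function(model, state, params = model$parameters) {
  k <- effective_k(model, params)
  ra <- model$ra; rb <- model$rb
  fa <- ifelse(is.na(ra), 1, state[ifelse(is.na(ra), 1L, ra)])
  fb <- ifelse(is.na(rb), 1, state[ifelse(is.na(rb), 1L, rb)])
  drop(model$S %*% (k * fa * fb))
}

# --- conserved-moiety reduction -------------------------------------------
# Steady-state work (Newton, continuation, eigenvalues) uses the reduced
# system in which one pivot species per conserved moiety is eliminated via
# the moiety total; the full-system Jacobian is singular along moiety
# directions and Newton would fail on it.

moiety_reduction <- function(model) {
  mo <- conserved_moieties(model)
  n <- model$n_species
  if (length(mo) == 0L) {
    return(list(moieties = mo, dep = integer(0), indep = seq_len(n), W = NULL))
  }
  Y <- do.call(rbind, mo)                 # n_moiety x n
  dep <- integer(0)
  for (i in seq_len(nrow(Y))) {
    cand <- which(Y[i, ] == 1 & !(seq_len(n) %in% dep))
    # prefer a species unique to this moiety
    uniq <- cand[colSums(Y[, cand, drop = FALSE] != 0) == 1]
    dep <- c(dep, if (length(uniq) > 0) uniq[1] else cand[1])
  }
  indep <- setdiff(seq_len(n), dep)
  # x_dep = (totals - Y_indep x_indep) / diag(Y_dep) ; pivots have coef 1
  list(moieties = mo, dep = dep, indep = indep,
       Ydep = Y[, dep, drop = FALSE], Yindep = Y[, indep, drop = FALSE])
}

expand_state <- function(red, x_ind, totals) {
  n <- length(red$indep) + length(red$dep)
  x <- numeric(n)
  x[red$indep] <- x_ind
  if (length(red$dep) > 0L) {
    x[red$dep] <- solve(red$Ydep, totals - drop(red$Yindep %*% x_ind))
  }
  x
}

moiety_totals <- function(red, x_full) {
  if (length(red$dep) == 0L) return(numeric(0))
  vapply(red$moieties, function(y) sum(y * x_full), 0)
}

reduced_rhs <- function(model, red, x_ind, totals, params = model$parameters) {
  x <- expand_state(red, x_ind, totals)
  network_rhs_raw(model, x, params)[red$indep]
}

reduced_jacobian <- function(model, red, x_ind, totals, params = model$parameters) {
  x <- expand_state(red, x_ind, totals)
  J <- network_jacobian(model, x, params)
  Ji <- J[red$indep, red$indep, drop = FALSE]
  if (length(red$dep) > 0L) {
    # dx_dep/dx_ind = -Ydep^{-1} Yindep
    Dd <- -solve(red$Ydep, red$Yindep)
    Ji <- Ji + J[red$indep, red$dep, drop = FALSE] %*% Dd
  }
  Ji
}

#' Solve for a steady state
#'
#' Newton refinement of a root of the right-hand side on the
#' moiety-reduced system (conserved totals are fixed by the initial guess),
#' with a fallback to long-horizon integration followed by Newton when the
#' direct iteration diverges. Stability is classified from the eigenvalues
#' of the reduced Jacobian: stable when the largest real part is below
#' -1e-9, unstable above +1e-9, marginal in between.
#'
#' @param model an \code{hsp90_model}.
#' @param x0_guess non-negative initial guess (full state).
#' @param tol convergence tolerance on the infinity norm of the rhs.
#' @param max_iter Newton iteration budget.
#' @param params optional parameter override.
#' @param fallback integrate to near-equilibrium first if Newton fails.
#' @return a list of class \code{hsp90_steady_state}: \code{state} (named,
#'   full), \code{residual_norm}, \code{stable}, \code{marginal},
#'   \code{eigenvalues} (of the reduced Jacobian), \code{converged}.
#' @export
steady_state <- function(model, x0_guess = default_initial_state(model),
                         tol = 1e-9, max_iter = 50, params = model$parameters,
                         fallback = TRUE) {
  if (inherits(model, "ode_problem")) {
    return(steady_state_ode(model, x0_guess, tol, max_iter, params, fallback))
  }
  stopifnot(inherits(model, "hsp90_model"))
  if (any(x0_guess < 0)) stop("guess must be non-negative")
  red <- moiety_reduction(model)
  totals <- moiety_totals(red, x0_guess)

  newton <- function(x_ind) {
    fn <- function(x) max(abs(reduced_rhs(model, red, x, totals, params)))
    f_norm <- fn(x_ind)
    best_x <- x_ind; best_f <- f_norm
    free_steps <- 0L  # non-monotone allowance: Newton is not descent-monotone
    for (it in seq_len(max_iter)) {
      if (f_norm <= tol) return(list(x = x_ind, ok = TRUE))
      f <- reduced_rhs(model, red, x_ind, totals, params)
      J <- reduced_jacobian(model, red, x_ind, totals, params)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      # trust-region cap: near-singular Jacobians (slow modes) otherwise
      # throw the iterate onto a distant non-physical root
      cap <- 0.5 * (1 + max(abs(x_ind)))
      if (max(abs(step)) > cap) step <- step * cap / max(abs(step))
      # residual line search (mass-action rhs is polynomial, so probing
      # slightly negative intermediate iterates is harmless)
      lambda <- 1; accepted <- FALSE
      for (ls in 1:10) {
        x_new <- x_ind + lambda * step
        f_new <- fn(x_new)
        if (is.finite(f_new) && (f_new < f_norm || f_new <= tol)) {
          accepted <- TRUE; break
        }
        lambda <- lambda / 2
      }
      if (!accepted) {
        # allow a bounded number of residual-increasing full steps; the
        # quadratic phase often follows a transient residual rise
        x_new <- x_ind + step
        f_new <- fn(x_new)
        if (free_steps < 5L && is.finite(f_new) && f_new < 1e4 * (best_f + tol)) {
          free_steps <- free_steps + 1L
        } else break
      }
      x_ind <- x_new; f_norm <- f_new
      if (f_norm < best_f) { best_f <- f_norm; best_x <- x_ind }
    }
    list(x = best_x, ok = best_f <= tol)
  }

  # pseudo-transient continuation: implicit-Euler steps with an adaptive
  # pseudo-timestep; robust against the ultra-slow relaxation modes that
  # defeat both plain Newton (long near-singular steps) and direct
  # integration (10^6 s horizons)
  ptc <- function(x_ind, delta = 1e2, max_steps = 250) {
    fn <- function(x) reduced_rhs(model, red, x, totals, params)
    f <- fn(x_ind); f_norm <- max(abs(f))
    n <- length(x_ind)
    for (it in seq_len(max_steps)) {
      if (!is.finite(f_norm)) return(list(x = x_ind, ok = FALSE))
      if (f_norm <= tol) return(list(x = x_ind, ok = TRUE))
      J <- reduced_jacobian(model, red, x_ind, totals, params)
      A <- diag(1 / delta, n) - J
      dx <- tryCatch(solve(A, f), error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) { delta <- delta / 4; next }
      x_new <- x_ind + dx
      f_new <- fn(x_new); f_new_norm <- max(abs(f_new))
      if (is.finite(f_new_norm) && f_new_norm < 2 * f_norm) {
        # switched-evolution relaxation: grow the step as the residual falls
        delta <- min(delta * max(f_norm / max(f_new_norm, 1e-300), 1.1), 1e12)
        x_ind <- x_new; f <- f_new; f_norm <- f_new_norm
      } else {
        delta <- delta / 4
        if (delta < 1e-6) return(list(x = x_ind, ok = FALSE))
      }
    }
    list(x = x_ind, ok = f_norm <= tol)
  }

  res <- newton(x0_guess[red$indep])
  if (!res$ok && fallback) {
    res <- ptc(x0_guess[red$indep])
    if (!res$ok) res <- newton(res$x)
  }
  if (!res$ok && fallback) {
    x_eq <- equilibrate(model, pmax(x0_guess, 0), params)
    res <- newton(x_eq[red$indep])
    if (!res$ok) res <- ptc(res$x)
  }
  x_full <- expand_state(red, res$x, totals)
  f_full <- network_rhs_raw(model, x_full, params)
  Jr <- reduced_jacobian(model, red, res$x, totals, params)
  ev <- eigen(Jr, only.values = TRUE)$values
  mre <- max(Re(ev))
  structure(list(
    state = stats::setNames(x_full, model$species$name),
    residual_norm = max(abs(f_full)),
    stable = mre < -1e-9,
    marginal = abs(mre) <= 1e-9,
    eigenvalues = ev,
    converged = res$ok
  ), class = "hsp90_steady_state")
}

# Newton (with integration fallback) for a wrapped plain ODE system; params
# is the scalar parameter value.
steady_state_ode <- function(model, x0_guess, tol = 1e-9, max_iter = 50,
                             params = 0, fallback = TRUE) {
  p <- if (is.numeric(params)) params else 0
  newton <- function(x) {
    for (it in seq_len(max_iter)) {
      f <- model$f(x, p)
      if (max(abs(f)) <= tol) return(list(x = x, ok = TRUE))
      step <- tryCatch(solve(model$jac(x, p), -f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(list(x = x, ok = FALSE))
      if (max(abs(step)) > 1e6) return(list(x = x, ok = FALSE))
      x <- x + step
    }
    list(x = x, ok = max(abs(model$f(x, p))) <= tol)
  }
  res <- newton(unname(x0_guess))
  if (!res$ok && fallback) {
    sol <- deSolve::lsoda(unname(x0_guess), times = c(0, 1e3, 1e5),
                          func = function(t, y, pp) list(model$f(y, p)),
                          parms = NULL, atol = 1e-10, rtol = 1e-8)
    res <- newton(as.numeric(sol[nrow(sol), -1]))
  }
  ev <- eigen(model$jac(res$x, p), only.values = TRUE)$values
  mre <- max(Re(ev))
  structure(list(
    state = stats::setNames(res$x, model$state_names),
    residual_norm = max(abs(model$f(res$x, p))),
    stable = mre < -1e-9, marginal = abs(mre) <= 1e-9,
    eigenvalues = ev, converged = res$ok
  ), class = "hsp90_steady_state")
}

# Long-horizon equilibration: integrate until ||rhs||_inf is small relative
# to the state scale, or a 1e6 s cap.
equilibrate <- function(model, x0, params = model$parameters,
                        rhs_tol = 1e-6, t_cap = 1e6) {
  if (inherits(model, "ode_problem")) {
    p <- if (is.numeric(params)) params else 0
    sol <- deSolve::lsoda(unname(x0), times = c(0, 1e3, 1e5),
                          func = function(t, y, pp) list(model$f(y, p)),
                          parms = NULL, atol = 1e-10, rtol = 1e-8)
    return(as.numeric(sol[nrow(sol), -1]))
  }
  x <- unname(x0)
  t_span <- 1e3
  t_tot <- 0
  while (t_tot < t_cap) {
    tc <- tryCatch(
      integrate_network(model, x, times = c(0, t_span), params = params,
                        atol = 1e-10, rtol = 1e-8),
      error = function(e) NULL)
    if (is.null(tc)) break
    x <- as.numeric(tc[nrow(tc), -1])
    t_tot <- t_tot + t_span
    f <- network_rhs_raw(model, x, params)
    if (max(abs(f)) < rhs_tol * (1 + max(abs(x)))) break
    t_span <- min(t_span * 4, t_cap - t_tot)
    if (t_span <= 0) break
  }
  x
}

#' @export
print.hsp90_steady_state <- function(x, ...) {
  cat("<hsp90_steady_state> residual ", format(x$residual_norm, digits = 3),
      ", ", if (x$stable) "stable" else if (x$marginal) "marginal" else "unstable",
      ", max Re(lambda) = ", format(max(Re(x$eigenvalues)), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Percent-of-maximum conversion of a time series
#'
#' Returns \code{100 * value / max(value)} over the series, the
#' normalization used for comparison with arbitrary-scale densitometry
#' data. The maximum of the output is exactly 100; the result is invariant
#' under positive rescaling of the raw series.
#'
#' @param tc an \code{hsp90_timecourse} tibble (or any data frame with the
#'   species column), or a bare numeric vector.
#' @param species species label to convert (ignored for a bare vector).
#' @return numeric vector of percent-of-max values.
#' @examples
#' percent_conversion(c(10, 50, 25))  # 20 100 50
#' @export
percent_conversion <- function(tc, species = NULL) {
  y <- if (is.numeric(tc)) tc else {
    if (is.null(species)) stop("species label required")
    if (!species %in% names(tc)) stop("species not present in time course: ", species)
    tc[[species]]
  }
  m <- max(y)
  if (!is.finite(m) || m <= 0) stop("series maximum must be positive")
  100 * y / m
}
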