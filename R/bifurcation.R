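#' @importFrom rlang .data
NULL

# --- parameter plumbing ----------------------------------------------------

param_value <- function(params, pname) {
  if (!inherits(params, "hsp90_parameters")) return(as.numeric(params))
  if (pname == "k_stress") params$k_stress else unname(params$values[[pname]])
}

param_assign <- function(params, pname, value) {
  if (!inherits(params, "hsp90_parameters")) return(value)
  if (pname == "k_stress") params$k_stress <- value else params$values[[pname]] <- value
  params
}

# d(rhs)/d(pname): mass-action rates are linear in each rate constant and in
# k_stress, so the derivative is the rate monomial without that factor.
rhs_param_derivative <- function(model, state, pname, params) {
  ra <- model$ra; rb <- model$rb
  fa <- ifelse(is.na(ra), 1, state[ifelse(is.na(ra), 1L, ra)])
  fb <- ifelse(is.na(rb), 1, state[ifelse(is.na(rb), 1L, rb)])
  f <- fa * fb
  dv <- numeric(model$n_reactions)
  if (pname == "k_stress") {
    w <- model$stress_flag
    dv[w] <- unname(params$values[model$k_index[w]]) * f[w]
  } else {
    w <- which(names(params$values)[model$k_index] == pname)
    if (length(w) > 0L) {
      fac <- ifelse(model$stress_flag[w], params$k_stress, 1)
      dv[w] <- fac * f[w]
    }
  }
  drop(model$S %*% dv)
}

# --- pseudo-arclength continuation ----------------------------------------

#' Continue a steady-state branch in one parameter
#'
#' Pseudo-arclength continuation (secant predictor, Newton corrector on the
#' arclength-augmented system) of the moiety-reduced steady-state equations,
#' with adaptive step control. Turning points are traversed, limit points
#' are located by the sign change of the parameter component of the branch
#' tangent and refined by bisection, and Hopf points by the sign change of
#' the real part of a complex conjugate eigenvalue pair. Each accepted point
#' carries a stability flag from the reduced Jacobian.
#'
#' @param model an \code{hsp90_model}.
#' @param params parameter set (defaults to the model's).
#' @param parameter_name \code{"k_stress"} or the name of a kinetic constant.
#' @param range length-2 numeric parameter interval to scan.
#' @param start a converged \code{\link{steady_state}} at the starting
#'   parameter value (defaults to \code{range[1]}; see \code{start_value}).
#' @param step_opts list of continuation controls: \code{h0} initial scaled
#'   arclength step, \code{h_min}, \code{h_max}, \code{max_points},
#'   \code{corrector_tol}, \code{direction} (+1/-1).
#' @param start_value parameter value at which \code{start} was computed.
#' @return a list of class \code{hsp90_branch}: \code{points} (tibble with
#'   \code{parameter}, stability flags, leading eigenvalue and one column
#'   per species), \code{special_points} (tibble), \code{closed},
#'   \code{termination}.
#' @export
continue_branch <- function(model, params = model$parameters,
                            parameter_name = "k_stress",
                            range = c(0, 3), start,
                            step_opts = list(), start_value = range[1]) {
  stopifnot(inherits(model, "hsp90_model") || inherits(model, "ode_problem"))
  opts <- utils::modifyList(list(
    h0 = 1e-3, h_min = 1e-8, h_max = 5e-2, max_points = 4000,
    corrector_tol = 1e-9, corrector_iter = 12, direction = 1,
    loop_tol = 1e-4, eig_every = 1L, x_floor = 1
  ), step_opts)
  if (inherits(start, "hsp90_steady_state")) {
    x_start <- unname(start$state)
  } else x_start <- unname(start)

  prob <- cont_problem(model, params, parameter_name, x_start)
  n <- prob$n

  p0 <- start_value
  f0 <- prob$F(prob$x_ind, p0)
  if (max(abs(f0)) > 1e-6) {
    ss <- steady_state(model, x_start,
                       params = param_assign(params, parameter_name, p0))
    if (!ss$converged) stop("start is not a converged steady state at range start")
    x_start <- unname(ss$state)
    prob <- cont_problem(model, params, parameter_name, x_start)
  }

  # scaling: states by their starting magnitude (floored), parameter by a
  # tenth of the range width; the floor keeps the arclength from being
  # dominated by components that grow orders of magnitude along the branch
  xsc <- pmax(abs(prob$x_ind), opts$x_floor)
  psc <- max(abs(diff(range)) / 10, 1e-4)

  Fu <- function(xi, p) prob$F(xi, p)
  Ju <- function(xi, p) {
    Jx <- prob$J(xi, p)
    Fp <- prob$Fp(xi, p)
    cbind(Jx * rep(xsc, each = nrow(Jx)), Fp * psc)  # scaled Jacobian [n x (n+1)]
  }

  corrector <- function(z_pred, tz) {
    z <- z_pred
    for (it in seq_len(opts$corrector_iter)) {
      xi <- z[1:n] * xsc; p <- z[n + 1] * psc
      f <- Fu(xi, p)
      g <- sum(tz * (z - z_pred))
      if (max(abs(f)) < opts$corrector_tol && abs(g) < 1e-12) {
        return(list(z = z, ok = TRUE, iters = it))
      }
      A <- rbind(Ju(xi, p), tz)
      step <- tryCatch(solve(A, -c(f, g)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(list(z = z, ok = FALSE, iters = it))
      z <- z + step
    }
    xi <- z[1:n] * xsc; p <- z[n + 1] * psc
    list(z = z, ok = max(abs(Fu(xi, p))) < opts$corrector_tol, iters = opts$corrector_iter)
  }

  tangent <- function(z, t_prev) {
    xi <- z[1:n] * xsc; p <- z[n + 1] * psc
    A <- rbind(Ju(xi, p), t_prev)
    t_new <- tryCatch(solve(A, c(rep(0, n), 1)), error = function(e) NULL)
    if (is.null(t_new) || any(!is.finite(t_new))) return(t_prev)
    t_new / sqrt(sum(t_new^2))
  }

  eig_info <- function(z) {
    xi <- z[1:n] * xsc; p <- z[n + 1] * psc
    ev <- eigen(prob$J(xi, p), only.values = TRUE)$values
    ev[order(-Re(ev))]
  }

  z0 <- c(prob$x_ind / xsc, p0 / psc)
  t0 <- c(rep(0, n), opts$direction)
  t0 <- tangent(z0, t0)
  if (sign(t0[n + 1]) != sign(opts$direction) && t0[n + 1] != 0) t0 <- -t0

  pts_z <- list(z0)
  tangents <- list(t0)
  eigs <- list(eig_info(z0))
  special <- list()
  termination <- "max_points"
  closed <- FALSE
  h <- opts$h0

  z <- z0; tz <- t0
  for (k in seq_len(opts$max_points - 1L)) {
    accepted <- FALSE
    while (!accepted) {
      z_pred <- z + h * tz
      res <- corrector(z_pred, tz)
      if (res$ok) {
        accepted <- TRUE
      } else if (h > opts$h_min) {
        h <- max(h / 2, opts$h_min)
      } else {
        termination <- "corrector_divergence"
        break
      }
    }
    if (!accepted) break
    z_new <- res$z
    t_new <- tangent(z_new, tz)
    if (sum(t_new * tz) < 0) t_new <- -t_new

    # limit point: parameter tangent component changes sign
    if (sign(t_new[n + 1]) != sign(tz[n + 1]) && tz[n + 1] != 0 && t_new[n + 1] != 0) {
      lp <- refine_fold(corrector, tangent, z, tz, h, n)
      if (!is.null(lp)) special <- c(special, list(list(kind = "limit_point", z = lp)))
    }
    ev_new <- eig_info(z_new)
    ev_old <- eigs[[length(eigs)]]
    hp <- hopf_crossing(ev_old, ev_new)
    if (hp) {
      hz <- refine_hopf(corrector, tangent, eig_info, z, tz, h, n)
      if (!is.null(hz)) special <- c(special, list(list(kind = "hopf", z = hz)))
    }

    pts_z <- c(pts_z, list(z_new))
    tangents <- c(tangents, list(t_new))
    eigs <- c(eigs, list(ev_new))

    # loop closure (isola): returned near the start after some travel
    if (k > 20) {
      d0 <- sqrt(sum((z_new - z0)^2))
      if (d0 < opts$loop_tol * (1 + sqrt(sum(z0^2)))) {
        closed <- TRUE
        termination <- "closed_loop"
        break
      }
    }

    p_new <- z_new[n + 1] * psc
    if (p_new < min(range) - 1e-9 || p_new > max(range) + 1e-9) {
      termination <- "range_exit"
      break
    }
    if (res$iters <= 3) h <- min(h * 1.4, opts$h_max)
    else if (res$iters >= 8) h <- max(h / 1.5, opts$h_min)
    z <- z_new; tz <- t_new
  }
  if (termination == "max_points" && length(pts_z) >= opts$max_points) termination <- "max_points"

  # materialize points
  to_row <- function(z, ev) {
    xi <- z[1:n] * xsc; p <- z[n + 1] * psc
    xf <- prob$expand(xi)
    mre <- max(Re(ev))
    lead <- ev[which.max(Re(ev))]
    phys <- !isTRUE(prob$check_physical) ||
      min(xf) > -1e-6 * (1 + max(abs(xf)))
    c(parameter = p, stable = as.numeric(mre < -1e-9),
      marginal = as.numeric(abs(mre) <= 1e-9),
      physical = as.numeric(phys),
      re_leading = Re(lead), im_leading = Im(lead), xf)
  }
  mat <- do.call(rbind, Map(to_row, pts_z, eigs))
  points <- tibble::as_tibble(as.data.frame(mat))
  points$stable <- points$stable > 0.5
  points$marginal <- points$marginal > 0.5
  points$physical <- points$physical > 0.5

  sp_tb <- if (length(special) > 0L) {
    rows <- lapply(special, function(s) {
      xi <- s$z[1:n] * xsc; p <- s$z[n + 1] * psc
      tibble::tibble(kind = s$kind, parameter_value = p,
                     state = list(prob$expand(xi)))
    })
    dplyr::bind_rows(rows)
  } else tibble::tibble(kind = character(0), parameter_value = numeric(0), state = list())

  structure(list(points = points, special_points = sp_tb, closed = closed,
                 termination = termination, parameter_name = parameter_name,
                 range = range, totals = prob$totals),
            class = "hsp90_branch")
}

# true when a complex pair's real part crosses zero between two spectra
# (fold crossings are real and excluded by the |Im| guard)
hopf_crossing <- function(ev_old, ev_new, im_min = 1e-8) {
  re_old <- max(c(-Inf, Re(ev_old)[abs(Im(ev_old)) > im_min]))
  re_new <- max(c(-Inf, Re(ev_new)[abs(Im(ev_new)) > im_min]))
  is.finite(re_old) && is.finite(re_new) && sign(re_old) != sign(re_new) &&
    re_old != 0 && re_new != 0
}

# bisection in arclength step on the tangent parameter component
refine_fold <- function(corrector, tangent, z_base, t_base, h_full, n,
                        tol = 1e-10, max_iter = 60) {
  g <- function(h) {
    res <- corrector(z_base + h * t_base, t_base)
    if (!res$ok) return(NULL)
    t_h <- tangent(res$z, t_base)
    if (sum(t_h * t_base) < 0) t_h <- -t_h
    list(val = t_h[n + 1], z = res$z)
  }
  lo <- 0; hi <- h_full
  glo <- t_base[n + 1]
  best <- NULL
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (is.null(gm)) { hi <- mid; next }
    best <- gm$z
    if (sign(gm$val) == sign(glo)) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  best
}

# bisection on the real part of the crossing complex pair
refine_hopf <- function(corrector, tangent, eig_info, z_base, t_base, h_full, n,
                        tol = 1e-10, max_iter = 50, im_min = 1e-8) {
  cplx_re <- function(ev) max(c(-Inf, Re(ev)[abs(Im(ev)) > im_min]))
  g0 <- cplx_re(eig_info(z_base))
  if (!is.finite(g0)) return(NULL)
  lo <- 0; hi <- h_full
  best <- NULL
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    res <- corrector(z_base + mid * t_base, t_base)
    if (!res$ok) { hi <- mid; next }
    gm <- cplx_re(eig_info(res$z))
    best <- res$z
    if (!is.finite(gm)) { hi <- mid; next }
    if (sign(gm) == sign(g0)) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  best
}

# --- brute-force oracle ----------------------------------------------------

#' Brute-force stable steady states over a parameter grid
#'
#' Independent oracle for the continuation engine: for each grid value the
#' system is integrated to equilibrium from \code{n_starts} random initial
#' conditions drawn on the conserved-moiety manifold of \code{x_ref}
#' (log-uniform free pools, random splits of each conserved total),
#' Newton-polished, and the distinct stable endpoints are clustered at
#' relative radius \code{cluster_tol}.
#'
#' @param model an \code{hsp90_model}.
#' @param params parameter set (defaults to the model's).
#' @param parameter_name parameter to scan.
#' @param parameter_grid numeric vector of parameter values.
#' @param n_starts random starts per grid value.
#' @param seed integer seed.
#' @param x_ref reference state fixing the conserved totals.
#' @param cluster_tol relative clustering radius.
#' @param ic_box for wrapped \code{\link{ode_problem}} systems: initial
#'   conditions are drawn uniformly in \code{[-ic_box, ic_box]} per
#'   component.
#' @return a tibble with columns \code{parameter}, \code{n_stable},
#'   \code{states} (list of matrices, one row per distinct stable state),
#'   \code{n_failed}.
#' @export
brute_force_steady_states <- function(model, params = model$parameters,
                                      parameter_name = "k_stress",
                                      parameter_grid, n_starts = 8, seed = 1,
                                      x_ref = default_initial_state(model),
                                      cluster_tol = 1e-3, ic_box = 3) {
  stopifnot(n_starts >= 1)
  if (inherits(model, "ode_problem")) {
    return(brute_force_ode(model, parameter_grid, n_starts, seed,
                           cluster_tol, ic_box))
  }
  red <- moiety_reduction(model)
  totals <- moiety_totals(red, unname(x_ref))
  sp <- model$species$name
  n <- model$n_species

  moiety_members <- lapply(red$moieties, function(y) which(y > 0))
  in_moiety <- unique(unlist(moiety_members))
  free_idx <- setdiff(seq_len(n), in_moiety)

  draw_state <- function(rng_scale = c(1e-3, 1e3)) {
    x <- numeric(n)
    x[free_idx] <- exp(stats::runif(length(free_idx),
                                    log(rng_scale[1]), log(rng_scale[2])))
    for (im in seq_along(moiety_members)) {
      mem <- moiety_members[[im]]
      # split the total over the simple (non-shared) members to stay feasible
      shared <- vapply(mem, function(i)
        sum(vapply(red$moieties, function(y) y[i] != 0, TRUE)) > 1, TRUE)
      simple <- mem[!shared]
      if (length(simple) == 0L) simple <- mem[1]
      w <- stats::rexp(length(simple))
      x[simple] <- x[simple] + totals[im] * w / sum(w)
    }
    x
  }

  out <- vector("list", length(parameter_grid))
  for (gi in seq_along(parameter_grid)) {
    pp <- param_assign(params, parameter_name, parameter_grid[gi])
    set.seed(seed + 7919L * gi)
    found <- list()
    n_failed <- 0L
    for (s in seq_len(n_starts)) {
      x0 <- if (s == 1L) unname(x_ref) else draw_state()
      # integrate towards the attractor first (stays physical), then polish
      # with Newton / pseudo-transient continuation
      x_eq <- tryCatch(equilibrate(model, pmax(x0, 0), pp, rhs_tol = 1e-6,
                                   t_cap = 3e5),
                       error = function(e) NULL)
      if (is.null(x_eq)) { n_failed <- n_failed + 1L; next }
      ss <- tryCatch(steady_state(model, pmax(x_eq, 0), params = pp,
                                  tol = 1e-6, fallback = TRUE),
                     error = function(e) NULL)
      if (is.null(ss) || !ss$converged ||
          min(ss$state) < -1e-6 * (1 + max(abs(ss$state)))) {
        n_failed <- n_failed + 1L; next
      }
      if (!ss$stable) next
      found <- c(found, list(unname(ss$state)))
    }
    if (length(found) > 0L) {
      M <- do.call(rbind, found)
      keep <- rep(TRUE, nrow(M))
      for (i in seq_len(nrow(M))) {
        if (!keep[i]) next
        for (j in seq_len(nrow(M))) {
          if (j <= i || !keep[j]) next
          rel <- max(abs(M[i, ] - M[j, ]) / (1 + pmax(abs(M[i, ]), abs(M[j, ]))))
          if (rel < cluster_tol) keep[j] <- FALSE
        }
      }
      M <- M[keep, , drop = FALSE]
      colnames(M) <- sp
    } else M <- matrix(numeric(0), 0, n, dimnames = list(NULL, sp))
    out[[gi]] <- tibble::tibble(parameter = parameter_grid[gi],
                                n_stable = nrow(M), states = list(M),
                                n_failed = n_failed)
  }
  dplyr::bind_rows(out)
}

brute_force_ode <- function(model, parameter_grid, n_starts, seed,
                            cluster_tol, ic_box) {
  out <- vector("list", length(parameter_grid))
  for (gi in seq_along(parameter_grid)) {
    p <- parameter_grid[gi]
    set.seed(seed + 7919L * gi)
    found <- list(); n_failed <- 0L
    for (s in seq_len(n_starts)) {
      x0 <- stats::runif(model$n, -ic_box, ic_box)
      ss <- tryCatch(steady_state(model, x0, params = p, tol = 1e-10),
                     error = function(e) NULL)
      if (is.null(ss) || !ss$converged) { n_failed <- n_failed + 1L; next }
      if (!ss$stable) next
      found <- c(found, list(unname(ss$state)))
    }
    if (length(found) > 0L) {
      M <- do.call(rbind, found)
      keep <- rep(TRUE, nrow(M))
      for (i in seq_len(nrow(M))) for (j in seq_len(nrow(M))) {
        if (j > i && keep[i] && keep[j]) {
          rel <- max(abs(M[i, ] - M[j, ]) / (1 + pmax(abs(M[i, ]), abs(M[j, ]))))
          if (rel < cluster_tol) keep[j] <- FALSE
        }
      }
      M <- M[keep, , drop = FALSE]
      colnames(M) <- model$state_names
    } else M <- matrix(numeric(0), 0, model$n,
                       dimnames = list(NULL, model$state_names))
    out[[gi]] <- tibble::tibble(parameter = p, n_stable = nrow(M),
                                states = list(M), n_failed = n_failed)
  }
  dplyr::bind_rows(out)
}

# --- diagram assembly and classification ----------------------------------

#' One-parameter bifurcation diagram
#'
#' Runs pseudo-arclength continuation across \code{range} starting from the
#' steady state at the lower range end, optionally hunts for disconnected
#' branches (isolas) by seeding extra continuations from brute-force stable
#' states not matched to the branches found, and classifies the resulting
#' topology.
#'
#' @inheritParams continue_branch
#' @param observable species label used for plotting and classification
#'   geometry (default \code{"HSP90c"}).
#' @param hunt_isolas logical; brute-force search for disconnected branches.
#' @param isola_grid parameter values probed when hunting (default: 9 evenly
#'   spaced interior points).
#' @param n_starts random starts per probe value during the hunt.
#' @param seed seed for the hunt.
#' @param x0 initial state from which the starting steady state is found.
#' @param extra_seeds optional list of \code{list(parameter =, state =)}
#'   pairs; each is refined to a steady state and, when stable and not on an
#'   already-found branch, seeds an additional continuation. Used by
#'   \code{\link{secondary_parameter_scan}} to track a detaching isola with
#'   states remembered from neighbouring scan values.
#' @return an object of class \code{hsp90_bifurcation}: \code{branches}
#'   (list of \code{hsp90_branch}), \code{special_points} (tibble with
#'   branch index), \code{classification}, \code{hopf_present},
#'   \code{observable}, \code{parameter_name}, \code{range}.
#' @export
bifurcation_diagram <- function(model, params = model$parameters,
                                parameter_name = "k_stress", range = c(0, 3),
                                observable = "HSP90c", step_opts = list(),
                                hunt_isolas = FALSE, isola_grid = NULL,
                                n_starts = 6, seed = 1,
                                x0 = default_initial_state(model),
                                extra_seeds = NULL) {
  p_lo <- min(range)
  if (inherits(model, "hsp90_model") && is.null(step_opts$x_floor)) {
    step_opts$x_floor <- 20  # nM; concentrations span 0 to ~hse_tot
  }
  pp <- param_assign(params, parameter_name, p_lo)
  x_eq <- equilibrate(model, x0, pp)
  ss <- steady_state(model, x_eq, params = pp)
  if (!ss$converged) stop("no converged steady state at the lower range end")
  br <- continue_branch(model, params, parameter_name, range, ss,
                        step_opts = step_opts, start_value = p_lo)
  branches <- list(br)

  if (!is.null(extra_seeds)) {
    for (sd in extra_seeds) {
      pv <- sd$parameter
      pp2 <- param_assign(params, parameter_name, pv)
      x_sd <- tryCatch(equilibrate(model, pmax(unname(sd$state), 0), pp2,
                                   rhs_tol = 1e-8),
                       error = function(e) NULL)
      if (is.null(x_sd)) next
      ss2 <- tryCatch(steady_state(model, pmax(x_sd, 0), params = pp2, tol = 1e-7),
                      error = function(e) NULL)
      if (is.null(ss2) || !ss2$converged || !ss2$stable) next
      if (min(ss2$state) < -1e-6 * (1 + max(abs(ss2$state)))) next
      if (state_on_branches(branches, pv, unname(ss2$state), tol = 2e-2)) next
      so <- utils::modifyList(step_opts, list(max_points = 2500, loop_tol = 1e-3))
      br2 <- tryCatch(
        continue_branch(model, params, parameter_name, range, ss2,
                        step_opts = so, start_value = pv),
        error = function(e) NULL)
      if (!is.null(br2) && !branch_duplicate(br2, branches)) {
        branches <- c(branches, list(br2))
      }
    }
  }

  if (hunt_isolas) {
    if (is.null(isola_grid)) {
      isola_grid <- seq(min(range), max(range), length.out = 11)[2:10]
    }
    bf <- brute_force_steady_states(model, params, parameter_name, isola_grid,
                                    n_starts = n_starts, seed = seed, x_ref = x0)
    for (gi in seq_len(nrow(bf))) {
      M <- bf$states[[gi]]
      if (nrow(M) == 0L) next
      for (r in seq_len(nrow(M))) {
        st <- M[r, ]
        if (state_on_branches(branches, bf$parameter[gi], st, tol = 2e-2)) next
        ss2 <- steady_state(model, st,
                            params = param_assign(params, parameter_name, bf$parameter[gi]))
        if (!ss2$converged) next
        br2 <- tryCatch(
          continue_branch(model, params, parameter_name, range, ss2,
                          step_opts = utils::modifyList(step_opts, list(direction = 1)),
                          start_value = bf$parameter[gi]),
          error = function(e) NULL)
        if (is.null(br2)) next
        if (!br2$closed) {
          # also continue downward and merge for full coverage
          br2b <- tryCatch(
            continue_branch(model, params, parameter_name, range, ss2,
                            step_opts = utils::modifyList(step_opts, list(direction = -1)),
                            start_value = bf$parameter[gi]),
            error = function(e) NULL)
          if (!is.null(br2b)) br2 <- merge_branches(br2b, br2)
        }
        if (!branch_duplicate(br2, branches)) branches <- c(branches, list(br2))
      }
    }
  }

  special <- dplyr::bind_rows(lapply(seq_along(branches), function(i) {
    sp <- branches[[i]]$special_points
    if (nrow(sp) > 0L) sp$branch <- i
    sp
  }))
  cls <- classify_diagram(branches, special, range, observable)
  structure(list(branches = branches, special_points = special,
                 classification = cls$classification,
                 hopf_present = cls$hopf_present,
                 observable = observable, parameter_name = parameter_name,
                 range = range),
            class = "hsp90_bifurcation")
}

# a freshly continued branch is a duplicate if most of its sampled points
# already lie on an existing branch
branch_duplicate <- function(br, branches, n_sample = 12, tol = 2e-2) {
  pts <- br$points
  if (nrow(pts) < 2L || length(branches) == 0L) return(FALSE)
  idx <- unique(round(seq(1, nrow(pts), length.out = n_sample)))
  hit <- 0L
  for (i in idx) {
    st <- as.numeric(pts[i, -(1:6)])
    if (state_on_branches(branches, pts$parameter[i], st, tol = tol)) hit <- hit + 1L
  }
  hit / length(idx) > 0.8
}

state_on_branches <- function(branches, p, state, tol = 5e-3) {
  for (br in branches) {
    pts <- br$points
    near <- which(abs(pts$parameter - p) < max(1e-3, 0.02 * diff(br$range)))
    if (length(near) == 0L) next
    X <- as.matrix(pts[near, -(1:6)])
    for (i in seq_len(nrow(X))) {
      rel <- max(abs(X[i, ] - state) / (1 + pmax(abs(X[i, ]), abs(state))))
      if (rel < tol) return(TRUE)
    }
  }
  FALSE
}

merge_branches <- function(br_down, br_up) {
  pts <- dplyr::bind_rows(br_down$points[rev(seq_len(nrow(br_down$points))), ],
                          br_up$points[-1, ])
  sp <- dplyr::bind_rows(br_down$special_points, br_up$special_points)
  structure(list(points = pts, special_points = sp,
                 closed = br_down$closed || br_up$closed,
                 termination = paste(br_down$termination, br_up$termination, sep = "/"),
                 parameter_name = br_up$parameter_name, range = br_up$range,
                 totals = br_up$totals),
            class = "hsp90_branch")
}

#' Count stable steady states predicted by a diagram at given parameter values
#'
#' Interpolates every branch at each requested parameter value and counts the
#' distinct stable (and physical) crossings, clustering nearby states.
#'
#' @param diagram an \code{hsp90_bifurcation}.
#' @param parameter_values numeric vector of parameter values.
#' @param cluster_tol relative clustering radius between crossings.
#' @return a tibble with columns \code{parameter} and \code{n_stable}.
#' @export
branch_state_count <- function(diagram, parameter_values, cluster_tol = 1e-2) {
  stopifnot(inherits(diagram, "hsp90_bifurcation"))
  out <- vapply(parameter_values, function(p) {
    states <- list()
    for (br in diagram$branches) {
      pts <- br$points
      n <- nrow(pts)
      if (n < 2L) next
      for (i in seq_len(n - 1L)) {
        p1 <- pts$parameter[i]; p2 <- pts$parameter[i + 1L]
        if ((p1 - p) * (p2 - p) > 0) next
        if (!(pts$stable[i] && pts$stable[i + 1L])) next
        if (!(pts$physical[i] && pts$physical[i + 1L])) next
        w <- if (p2 == p1) 0.5 else (p - p1) / (p2 - p1)
        x <- (1 - w) * as.numeric(pts[i, -(1:6)]) +
          w * as.numeric(pts[i + 1L, -(1:6)])
        states <- c(states, list(x))
      }
    }
    if (length(states) == 0L) return(0L)
    M <- do.call(rbind, states)
    keep <- rep(TRUE, nrow(M))
    for (a in seq_len(nrow(M))) for (b in seq_len(nrow(M))) {
      if (b > a && keep[a] && keep[b]) {
        rel <- max(abs(M[a, ] - M[b, ]) / (1 + pmax(abs(M[a, ]), abs(M[b, ]))))
        if (rel < cluster_tol) keep[b] <- FALSE
      }
    }
    sum(keep)
  }, 0L)
  tibble::tibble(parameter = parameter_values, n_stable = out)
}

#' Classify a bifurcation diagram topology
#'
#' Rule-based classification from the limit points and branch geometry:
#' no limit point and a monotone branch is \code{monostable} (or
#' \code{ultrasensitive_monostable} when the normalized maximum slope of
#' the observable exceeds \code{slope_threshold}); two limit points on one
#' connected branch give \code{s_hysteresis} or \code{z_hysteresis} by
#' orientation; four limit points with two disjoint bistable windows give
#' \code{mushroom}; a closed branch disconnected from another branch gives
#' \code{isola_plus_branch}; a limit point whose partner lies outside the
#' scanned range gives \code{irreversible}. Hopf points set the
#' \code{hopf_present} flag alongside the label.
#'
#' @param branches list of \code{hsp90_branch} objects (or an
#'   \code{hsp90_bifurcation}).
#' @param special_points tibble of special points (kind, parameter_value).
#' @param range scanned parameter interval.
#' @param observable species label used for orientation geometry.
#' @param slope_threshold normalized slope above which a monotone response
#'   is called ultrasensitive.
#' @return list with \code{classification} (character) and
#'   \code{hopf_present} (logical).
#' @export
classify_diagram <- function(branches, special_points = NULL, range = NULL,
                             observable = "HSP90c", slope_threshold = 10) {
  if (inherits(branches, "hsp90_bifurcation")) {
    dg <- branches
    branches <- dg$branches
    if (is.null(special_points)) special_points <- dg$special_points
    if (is.null(range)) range <- dg$range
    observable <- dg$observable
  }
  if (length(branches) == 0L) stop("at least one branch is required")
  if (is.null(special_points)) {
    special_points <- dplyr::bind_rows(lapply(branches, `[[`, "special_points"))
  }
  hopf_present <- any(special_points$kind == "hopf")
  # collapse special points duplicated by overlapping branch traversals
  if (nrow(special_points) > 0L) {
    key <- paste(special_points$kind, signif(special_points$parameter_value, 4))
    special_points <- special_points[!duplicated(key), , drop = FALSE]
  }
  lps <- special_points[special_points$kind == "limit_point", , drop = FALSE]
  # negative-steady-state (non-physical) folds are excluded from the topology
  if (nrow(lps) > 0L && "state" %in% names(lps)) {
    phys <- vapply(lps$state, function(s)
      min(s) > -1e-6 * (1 + max(abs(s))), TRUE)
    lps <- lps[phys, , drop = FALSE]
  }
  # keep LPs inside the scanned range
  if (!is.null(range) && nrow(lps) > 0L) {
    lps <- lps[lps$parameter_value >= min(range) - 1e-9 &
               lps$parameter_value <= max(range) + 1e-9, , drop = FALSE]
  }
  closed_flags <- vapply(branches, function(b) {
    if (isTRUE(b$closed)) return(TRUE)
    # a branch that never reaches either end of the scanned range must be a
    # closed loop (possibly traversed several times before hitting the
    # point budget)
    if (!is.null(range) && nrow(b$points) > 50L) {
      pr <- range(b$points$parameter)
      tol <- 1e-3 * diff(range(range))
      return(pr[1] > min(range) + tol && pr[2] < max(range) - tol)
    }
    FALSE
  }, TRUE)
  has_closed <- any(closed_flags)
  n_lp <- nrow(lps)

  label <- if (has_closed && length(branches) >= 2L) {
    "isola_plus_branch"
  } else if (n_lp == 0L) {
    cls_monotone(branches[[1]], observable, slope_threshold)
  } else if (n_lp %% 2L == 1L) {
    "irreversible"
  } else if (n_lp == 2L) {
    cls_hysteresis(branches[[1]], lps, observable)
  } else if (n_lp >= 4L) {
    # two disjoint bistable windows on one connected branch = mushroom
    pv <- sort(lps$parameter_value)
    win1 <- pv[1:2]; win2 <- pv[3:4]
    if (win1[2] < win2[1]) "mushroom" else "irreversible"
  } else "irreversible"

  list(classification = label, hopf_present = hopf_present)
}

cls_monotone <- function(branch, observable, slope_threshold) {
  pts <- branch$points
  if (!observable %in% names(pts)) return("monostable")
  p <- pts$parameter; y <- pts[[observable]]
  if (length(p) < 3L || diff(range(p)) == 0 || diff(range(y)) == 0) return("monostable")
  slope <- abs(diff(y) / diff(p))
  slope_norm <- max(slope[is.finite(slope)]) * diff(range(p)) / diff(range(y))
  if (slope_norm > slope_threshold) "ultrasensitive_monostable" else "monostable"
}

# orientation of a 2-LP hysteresis from the stable levels outside the window
cls_hysteresis <- function(branch, lps, observable) {
  pts <- branch$points
  pv <- sort(lps$parameter_value)
  below <- pts[pts$parameter < pv[1] & pts$stable, , drop = FALSE]
  above <- pts[pts$parameter > pv[2] & pts$stable, , drop = FALSE]
  if (nrow(below) == 0L || nrow(above) == 0L || !observable %in% names(pts)) {
    return("s_hysteresis")
  }
  y_below <- stats::median(below[[observable]])
  y_above <- stats::median(above[[observable]])
  if (y_above >= y_below) "s_hysteresis" else "z_hysteresis"
}

#' Bifurcation scan with the negative feedback silenced
#'
#' Applies \code{\link{apply_knockout}} to the two HSP90closed--HSF1
#' binding constants and re-runs the continuation.
#'
#' @inheritParams bifurcation_diagram
#' @param knockout constants to silence.
#' @return an \code{hsp90_bifurcation}.
#' @export
feedback_knockout_scan <- function(model, params = model$parameters,
                                   parameter_name = "k_stress", range = c(0, 3),
                                   observable = "HSP90c",
                                   knockout = c("k_fb_f", "k_fb_b"),
                                   step_opts = list(), ...) {
  m_ko <- apply_knockout(model, knockout)
  m_ko$parameters$k_stress <- params$k_stress
  pko <- params
  if (length(knockout) > 0L) pko$values[knockout] <- 0
  bifurcation_diagram(m_ko, pko, parameter_name, range, observable,
                      step_opts = step_opts, ...)
}

#' Sweep a secondary PdP constant and track the inner limit-point gap
#'
#' For each value of the secondary constant (default: the
#' mono-phosphorylation forward rate), a full continuation in the primary
#' parameter is run with isola hunting, and the parameter gap between the
#' two inner limit points of the mushroom is reported (NA once the diagram
#' has pinched off into an isola).
#'
#' @inheritParams bifurcation_diagram
#' @param secondary_name name of the PdP constant swept.
#' @param secondary_values numeric vector of values for the sweep.
#' @param hunt_isolas logical, passed through.
#' @return a tibble with columns \code{secondary_value},
#'   \code{classification}, \code{n_limit_points}, \code{inner_gap},
#'   \code{diagram} (list).
#' @export
secondary_parameter_scan <- function(model, params = model$parameters,
                                     secondary_name = "k_k1_c",
                                     secondary_values,
                                     parameter_name = "k_stress",
                                     range = c(0, 3), observable = "HSP90c",
                                     step_opts = list(), hunt_isolas = FALSE,
                                     n_starts = 6, seed = 1) {
  rows <- list()
  seeds <- NULL  # stable states remembered from the previous sweep value
  for (sv in secondary_values) {
    pp <- param_assign(params, secondary_name, sv)
    dg <- bifurcation_diagram(model, pp, parameter_name, range, observable,
                              step_opts = step_opts, hunt_isolas = hunt_isolas,
                              n_starts = n_starts, seed = seed,
                              extra_seeds = seeds)
    lp <- sort(unique(signif(
      dg$special_points$parameter_value[dg$special_points$kind == "limit_point"], 6)))
    gap <- if (length(lp) >= 4L && dg$classification == "mushroom") {
      lp[3] - lp[2]
    } else NA_real_
    rows[[length(rows) + 1L]] <-
      tibble::tibble(secondary_value = sv, classification = dg$classification,
                     n_limit_points = length(lp), inner_gap = gap,
                     diagram = list(dg))
    # remember stable upper-branch states spread across the cap to seed the
    # next (lower) sweep value: an isola that detaches from the main branch
    # stays reachable through these memories even when its basin is small
    seeds <- list()
    for (b in dg$branches) {
      pts <- b$points[b$points$stable & b$points$physical, , drop = FALSE]
      if (nrow(pts) == 0L) next
      hi <- pts[pts[[observable]] >= 0.3 * max(pts[[observable]]), , drop = FALSE]
      if (nrow(hi) == 0L) next
      qs <- stats::quantile(hi$parameter, c(0.15, 0.5, 0.85), names = FALSE)
      for (q in qs) {
        i <- which.min(abs(hi$parameter - q))
        seeds <- c(seeds, list(list(parameter = hi$parameter[i],
                                    state = as.numeric(hi[i, -(1:6)]))))
      }
    }
    if (length(seeds) > 4L) seeds <- seeds[seq_len(4L)]
  }
  dplyr::bind_rows(rows)
}

#' @export
print.hsp90_bifurcation <- function(x, ...) {
  n_lp <- sum(x$special_points$kind == "limit_point")
  n_h <- sum(x$special_points$kind == "hopf")
  cat("<hsp90_bifurcation> ", x$parameter_name, " in [",
      paste(format(x$range), collapse = ", "), "], ",
      length(x$branches), " branch(es), ", n_lp, " limit point(s), ",
      n_h, " Hopf point(s) -> ", x$classification, "\n", sep = "")
  invisible(x)
}

#' @export
print.hsp90_branch <- function(x, ...) {
  cat("<hsp90_branch> ", nrow(x$points), " points, ",
      nrow(x$special_points), " special point(s), termination: ",
      x$termination, if (x$closed) " (closed loop)", "\n", sep = "")
  invisible(x)
}
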