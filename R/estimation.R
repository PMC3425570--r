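#' Least-squares cost over percent-of-max time-course experiments
#'
#' The objective used for parameter estimation: the sum over experiments and
#' sampling points of squared differences between experimental and predicted
#' percent-of-max values of the measured species, each experiment simulated
#' at its own stress value. Both sides are normalized to 100 at their series
#' maximum, mirroring arbitrary-scale densitometry. A candidate at which the
#' simulation fails returns a large penalty (1e12) rather than an error.
#'
#' @param model an \code{hsp90_model}.
#' @param data a list of experiment records (or the \code{datasets} element
#'   of a \code{\link{generate_study}} result); each record needs fields
#'   \code{measured_species}, \code{k_stress}, \code{times},
#'   \code{values_percent}. A tibble with columns \code{experiment_id},
#'   \code{measured_species}, \code{k_stress}, \code{time}, \code{value_percent}
#'   is also accepted.
#' @param params parameter set evaluated (defaults to the model's).
#' @param stress_values optional named/numeric vector overriding the per-
#'   experiment stress values in \code{data} (one entry per experiment, in
#'   order).
#' @param weights optional per-experiment weights (default 1).
#' @param x0 initial state for the simulations.
#' @return non-negative scalar cost.
#' @export
cost_function <- function(model, data, params = model$parameters,
                          stress_values = NULL, weights = NULL,
                          x0 = default_initial_state(model)) {
  stopifnot(inherits(model, "hsp90_model"))
  data <- as_experiment_list(data)
  if (length(data) == 0L) stop("empty data list")
  if (is.null(weights)) weights <- rep(1, length(data))
  total <- 0
  for (i in seq_along(data)) {
    ex <- data[[i]]
    ks <- if (!is.null(stress_values)) stress_values[i] else ex$k_stress
    pred <- tryCatch(
      predict_percent(model, params, ks, ex$measured_species, ex$times, x0),
      error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e12)
    total <- total + weights[i] * sum((ex$values_percent - pred)^2)
  }
  total
}

# simulate one condition and return the percent-of-max series of one species
# at the requested sampling times
predict_percent <- function(model, params, k_stress, species, times, x0) {
  pp <- params
  pp$k_stress <- k_stress
  t_grid <- sort(unique(c(0, times)))
  tc <- integrate_network(model, x0, times = t_grid, params = pp)
  y <- tc[[species]][match(times, t_grid)]
  percent_conversion(y)
}

as_experiment_list <- function(data) {
  if (is.data.frame(data)) {
    ids <- unique(data$experiment_id)
    return(lapply(ids, function(id) {
      d <- data[data$experiment_id == id, , drop = FALSE]
      list(experiment_id = id,
           measured_species = d$measured_species[1],
           k_stress = d$k_stress[1],
           times = d$time, values_percent = d$value_percent)
    }))
  }
  if (!is.null(data$datasets)) return(data$datasets)
  data
}

#' Global parameter fitting by scatter search
#'
#' A scatter-search-style stochastic global optimizer for the least-squares
#' objective of \code{\link{cost_function}}: a log-uniform initial
#' population (diverse by design), a reference set of elite and diverse
#' members, pairwise log-space recombination with over-relaxation, and
#' periodic local polish of the incumbent by Nelder-Mead on the log scale.
#' Runs are reproducible for a fixed seed; because the objective is
#' multimodal, different seeds typically end in different parameter sets of
#' similar cost.
#'
#' @param model an \code{hsp90_model}.
#' @param data experiment list (see \code{\link{cost_function}}).
#' @param free_names names of constants to fit (stress values of the
#'   experiments are appended automatically when \code{fit_stress} is TRUE).
#' @param bounds two-column matrix (lower, upper) with one row per free
#'   constant, positive; default: each rate constant within a factor
#'   \code{span} of its current value (the model is simulable there).
#' @param span default bounds half-width in log10 units.
#' @param fit_stress also fit one stress value per experiment.
#' @param seed integer seed.
#' @param budget simulation-evaluation cap.
#' @param n_pop initial population size (default \code{10 * sqrt(n_free)}).
#' @param refset_size reference-set size.
#' @param top_k number of distinct best solutions to report.
#' @param warm_start include the current parameter values in the initial
#'   population (default TRUE); FALSE gives a fully randomized cold start.
#' @param verbose print progress.
#' @return an object of class \code{hsp90_fit}: list with \code{parameters}
#'   (an \code{hsp90_parameters}), \code{stress_values}, \code{cost},
#'   \code{trace} (best cost per improvement, non-increasing),
#'   \code{evaluations}, \code{seed}, \code{top_solutions} (list).
#' @export
fit_global <- function(model, data, free_names, bounds = NULL, span = 1.5,
                       fit_stress = TRUE, seed = 1, budget = 2000,
                       n_pop = NULL, refset_size = 8, top_k = 3,
                       warm_start = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "hsp90_model"))
  data <- as_experiment_list(data)
  set.seed(seed)
  base <- model$parameters
  n_exp <- length(data)
  stress0 <- vapply(data, function(e) e$k_stress, 0)
  n_free <- length(free_names) + if (fit_stress) n_exp else 0L

  theta0 <- c(unname(base$values[free_names]),
              if (fit_stress) stress0)
  theta0[theta0 <= 0] <- 1e-6
  if (is.null(bounds)) {
    bounds <- cbind(theta0 / 10^span, theta0 * 10^span)
  }
  if (any(bounds <= 0)) stop("bounds must be positive")
  lo <- log10(bounds[, 1]); hi <- log10(bounds[, 2])
  if (is.null(n_pop)) n_pop <- max(10L, ceiling(10 * sqrt(n_free)))

  evals <- 0L
  obj <- function(z) {
    # z on log10 scale, clipped into bounds
    z <- pmin(pmax(z, lo), hi)
    th <- 10^z
    pp <- base
    pp$values[free_names] <- th[seq_along(free_names)]
    sv <- if (fit_stress) th[length(free_names) + seq_len(n_exp)] else stress0
    evals <<- evals + 1L
    cost_function(model, data, pp, stress_values = sv)
  }

  # zero-width bounds: nothing to search
  if (all(hi - lo < 1e-12)) {
    cost <- obj(lo)
    pp <- base; pp$values[free_names] <- 10^lo[seq_along(free_names)]
    sv <- if (fit_stress) 10^lo[length(free_names) + seq_len(n_exp)] else stress0
    return(structure(list(parameters = pp, stress_values = sv, cost = cost,
                          trace = cost, evaluations = evals, seed = seed,
                          top_solutions = list(list(z = lo, cost = cost))),
                     class = "hsp90_fit"))
  }

  # initial population: log-uniform diversification, optionally joined by
  # the current parameter values as a warm start
  Z <- matrix(stats::runif(n_pop * n_free, lo, hi),
              ncol = n_free, byrow = TRUE)
  if (warm_start) Z[1, ] <- pmin(pmax(log10(theta0), lo), hi)
  costs <- apply(Z, 1, obj)
  ord <- order(costs)
  ref_n <- min(refset_size, nrow(Z))
  ref_idx <- ord[seq_len(ref_n)]
  refZ <- Z[ref_idx, , drop = FALSE]
  refC <- costs[ref_idx]

  trace <- min(refC)
  best_hist <- list(list(z = refZ[which.min(refC), ], cost = min(refC)))

  while (evals < budget) {
    improved <- FALSE
    for (i in seq_len(ref_n - 1L)) {
      for (j in seq(i + 1L, ref_n)) {
        if (evals >= budget) break
        d <- refZ[j, ] - refZ[i, ]
        lambda <- stats::runif(1, -0.4, 1.4)   # combination with over-relaxation
        cand <- refZ[i, ] + lambda * d +
          stats::rnorm(n_free, 0, 0.05 * (hi - lo))
        cand <- pmin(pmax(cand, lo), hi)
        cc <- obj(cand)
        worst <- which.max(refC)
        if (cc < refC[worst]) {
          refZ[worst, ] <- cand; refC[worst] <- cc
          improved <- TRUE
          if (cc < trace[length(trace)]) {
            trace <- c(trace, cc)
            best_hist <- c(best_hist, list(list(z = cand, cost = cc)))
            if (verbose) message(sprintf("eval %d: cost %.6g", evals, cc))
          }
        }
      }
      if (evals >= budget) break
    }
    # local polish of the incumbent (log-scale Nelder-Mead, small budget)
    if (evals < budget) {
      b <- which.min(refC)
      pol <- tryCatch(
        stats::optim(refZ[b, ], obj, method = "Nelder-Mead",
                     control = list(maxit = min(60, budget - evals))),
        error = function(e) NULL)
      if (!is.null(pol) && pol$value < refC[b]) {
        refZ[b, ] <- pmin(pmax(pol$par, lo), hi); refC[b] <- pol$value
        if (pol$value < trace[length(trace)]) {
          trace <- c(trace, pol$value)
          best_hist <- c(best_hist, list(list(z = refZ[b, ], cost = pol$value)))
        }
        improved <- TRUE
      }
    }
    if (!improved) {
      # diversification restart of the worst half
      nrep <- max(1L, floor(ref_n / 2))
      for (w in utils::tail(order(refC), nrep)) {
        if (evals >= budget) break
        cand <- stats::runif(n_free, lo, hi)
        refZ[w, ] <- cand; refC[w] <- obj(cand)
      }
    }
  }

  b <- which.min(refC)
  z_best <- refZ[b, ]
  th <- 10^z_best
  pp <- base
  pp$values[free_names] <- th[seq_along(free_names)]
  sv <- if (fit_stress) th[length(free_names) + seq_len(n_exp)] else stress0
  final_cost <- refC[b]

  # distinct top-k from the improvement history (most recent first)
  tops <- list()
  for (h in rev(best_hist)) {
    if (length(tops) >= top_k) break
    dup <- any(vapply(tops, function(t) max(abs(t$z - h$z)) < 1e-3, TRUE))
    if (!dup) tops <- c(tops, list(h))
  }

  structure(list(parameters = pp, stress_values = unname(sv),
                 cost = final_cost, trace = trace, evaluations = evals,
                 seed = seed, free_names = free_names,
                 top_solutions = tops),
            class = "hsp90_fit")
}

#' @export
print.hsp90_fit <- function(x, ...) {
  cat("<hsp90_fit> cost ", format(x$cost, digits = 6), " after ",
      x$evaluations, " evaluations (seed ", x$seed, ")\n", sep = "")
  if (length(x$stress_values) > 0)
    cat("  stress values: ", paste(format(x$stress_values, digits = 5),
                                   collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a fit result
#' @param x an \code{hsp90_fit}.
#' @param ... unused.
#' @return tibble of fitted constants (and stress values) with their values.
#' @method tidy hsp90_fit
#' @export
tidy.hsp90_fit <- function(x, ...) {
  tibble::tibble(
    term = c(x$free_names, paste0("k_stress_exp", seq_along(x$stress_values))),
    estimate = c(unname(x$parameters$values[x$free_names]), x$stress_values)
  )
}

#' One-line fit summary
#' @param x an \code{hsp90_fit}.
#' @param ... unused.
#' @return tibble with cost, number of evaluations, number of free
#'   parameters and the seed.
#' @method glance hsp90_fit
#' @export
glance.hsp90_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, evaluations = x$evaluations,
                 n_free = length(x$free_names) + length(x$stress_values),
                 seed = x$seed)
}

#' Fit a single named constant by 1-D bounded minimization
#'
#' Minimizes the least-squares objective over one constant (all others held
#' at the supplied set), using golden-section/parabolic search on the log
#' scale within the bracket.
#'
#' @param model an \code{hsp90_model}.
#' @param data experiment list (see \code{\link{cost_function}}).
#' @param free_name constant name, or \code{"k_stress"} to fit a shared
#'   stress value for all experiments in \code{data}.
#' @param params fixed parameter set for the other constants.
#' @param bracket positive length-2 interval to search.
#' @param tol relative convergence tolerance of the 1-D search.
#' @return an \code{hsp90_fit} with the single refitted value.
#' @export
fit_single_parameter <- function(model, data, free_name,
                                 params = model$parameters,
                                 bracket, tol = 1e-7) {
  stopifnot(inherits(model, "hsp90_model"))
  if (any(bracket <= 0)) stop("bracket must be positive")
  data <- as_experiment_list(data)
  fs <- function(logv) {
    v <- 10^logv
    if (free_name == "k_stress") {
      cost_function(model, data, params,
                    stress_values = rep(v, length(data)))
    } else {
      pp <- params
      pp$values[free_name] <- v
      cost_function(model, data, pp)
    }
  }
  opt <- stats::optimize(fs, interval = log10(sort(bracket)), tol = tol)
  v <- 10^opt$minimum
  # reject optima pinned at the bracket ends
  lb <- log10(sort(bracket))
  if (min(abs(opt$minimum - lb)) < 1e-9) {
    warning("minimum at the bracket boundary; widen the bracket")
  }
  pp <- params
  sv <- vapply(data, function(e) e$k_stress, 0)
  if (free_name == "k_stress") sv <- rep(v, length(data)) else pp$values[free_name] <- v
  structure(list(parameters = pp, stress_values = unname(sv), cost = opt$objective,
                 trace = opt$objective, evaluations = NA_integer_, seed = NA_integer_,
                 free_names = free_name,
                 top_solutions = list(list(z = opt$minimum, cost = opt$objective))),
            class = "hsp90_fit")
}
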