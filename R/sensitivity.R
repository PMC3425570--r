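#' Dynamic output sensitivities to the kinetic parameters
#'
#' Computes the raw sensitivities dy_k(t_j)/dp_m of the measured outputs to
#' the named parameters at the sampling times, by central finite differences
#' with a relative step (default) or by forward sensitivity equations
#' (augmented ODE system; practical for small parameter subsets and used as
#' the cross-check path).
#'
#' @param model an \code{hsp90_model}.
#' @param params parameter set at which to evaluate (defaults to the
#'   model's).
#' @param outputs character vector of observed species.
#' @param times sampling times (s); default the synthetic experiments' grid.
#' @param parameters names of constants to perturb; default all 53
#'   estimated constants.
#' @param rel_step relative finite-difference step.
#' @param method \code{"fd"} (central differences) or \code{"forward"}
#'   (forward sensitivity equations).
#' @param x0 initial state.
#' @return a 3-d array (output x parameter x time) with dimnames, plus
#'   attribute \code{"outputs_values"} (output x time matrix of nominal
#'   trajectories).
#' @export
dynamic_sensitivities <- function(model, params = model$parameters,
                                  outputs = c("HSF1_3S", "HHp"),
                                  times = default_sampling_times(),
                                  parameters = estimated_names(params),
                                  rel_step = 1e-4,
                                  method = c("fd", "forward"),
                                  x0 = default_initial_state(model)) {
  stopifnot(inherits(model, "hsp90_model"))
  method <- match.arg(method)
  bad <- setdiff(outputs, model$species$name)
  if (length(bad)) stop("unknown output species: ", paste(bad, collapse = ", "))
  t_grid <- sort(unique(c(0, times)))
  idx_t <- match(times, t_grid)
  sim <- function(pp) {
    tc <- integrate_network(model, x0, times = t_grid, params = pp)
    vapply(outputs, function(o) tc[[o]][idx_t], numeric(length(times)))
  }
  y0 <- sim(params)                       # time x output
  S <- array(0, dim = c(length(outputs), length(parameters), length(times)),
             dimnames = list(outputs, parameters, paste0("t", times)))
  if (method == "fd") {
    for (m in seq_along(parameters)) {
      pm <- parameters[m]
      v <- params$values[[pm]]
      h <- rel_step * max(abs(v), 1e-12)
      pu <- params; pu$values[pm] <- v + h
      pd <- params; pd$values[pm] <- max(v - h, 0)
      hh <- (v + h) - pd$values[[pm]]
      yu <- sim(pu); yd <- sim(pd)
      for (k in seq_along(outputs)) S[k, m, ] <- (yu[, k] - yd[, k]) / hh
    }
  } else {
    # forward sensitivity equations: d/dt s_m = J s_m + df/dp_m, s_m(0) = 0
    n <- model$n_species
    np <- length(parameters)
    aug_rhs <- function(t, y, p) {
      x <- y[seq_len(n)]
      J <- network_jacobian(model, pmax(x, 0), params)
      d <- network_rhs_raw(model, x, params)
      out <- numeric(n * (np + 1L))
      out[seq_len(n)] <- d
      for (m in seq_len(np)) {
        sm <- y[n * m + seq_len(n)]
        fp <- rhs_param_derivative(model, x, parameters[m], params)
        out[n * m + seq_len(n)] <- drop(J %*% sm) + fp
      }
      list(out)
    }
    y_init <- c(unname(x0), rep(0, n * np))
    sol <- deSolve::lsoda(y_init, times = t_grid, func = aug_rhs, parms = NULL,
                          atol = 1e-9, rtol = 1e-7, maxsteps = 50000)
    io <- match(outputs, model$species$name)
    for (m in seq_len(np)) {
      block <- sol[idx_t, 1 + n * m + seq_len(n), drop = FALSE]
      for (k in seq_along(outputs)) S[k, m, ] <- block[, io[k]]
    }
  }
  attr(S, "outputs_values") <- t(y0)      # output x time
  attr(S, "parameter_values") <- unname(params$values[parameters])
  S
}

estimated_names <- function(params) {
  names(params$values)[params$provenance == "estimated"]
}

#' Relative sensitivity indices
#'
#' Converts raw sensitivities to dimensionless relative indices
#' SI = (dy/dp) * p / y and aggregates over sampling times by
#' root-mean-square (configurable). Times where an output magnitude is
#' below \code{zero_tol} are excluded from the relative scaling.
#'
#' @param raw array from \code{\link{dynamic_sensitivities}}.
#' @param params parameter set (for nominal values; optional if the array
#'   carries them).
#' @param outputs_values optional output x time matrix of nominal values
#'   (taken from the array attribute when omitted).
#' @param aggregate \code{"rms"}, \code{"mean_abs"} or \code{"end"}.
#' @param zero_tol outputs below this magnitude (nM) are skipped.
#' @return list of class \code{hsp90_sensitivity}: \code{si_matrix}
#'   (output x parameter), \code{raw}, \code{si_time} (full relative array),
#'   \code{ranking} (tibble, parameters ordered by aggregate |SI|).
#' @export
relative_sensitivity_indices <- function(raw, params = NULL,
                                         outputs_values = NULL,
                                         aggregate = c("rms", "mean_abs", "end"),
                                         zero_tol = 1e-12) {
  aggregate <- match.arg(aggregate)
  if (is.null(outputs_values)) outputs_values <- attr(raw, "outputs_values")
  pvals <- if (!is.null(params)) unname(params$values[dimnames(raw)[[2]]])
           else attr(raw, "parameter_values")
  if (is.null(outputs_values) || is.null(pvals)) {
    stop("nominal output and parameter values are required")
  }
  d <- dim(raw)
  si <- array(NA_real_, dim = d, dimnames = dimnames(raw))
  for (k in seq_len(d[1])) {
    y <- outputs_values[k, ]
    ok <- abs(y) > zero_tol
    if (!any(ok)) stop("all sampled outputs are zero for ", dimnames(raw)[[1]][k])
    for (m in seq_len(d[2])) {
      si[k, m, ok] <- raw[k, m, ok] * pvals[m] / y[ok]
    }
  }
  agg <- matrix(NA_real_, d[1], d[2], dimnames = dimnames(raw)[1:2])
  for (k in seq_len(d[1])) for (m in seq_len(d[2])) {
    v <- si[k, m, ]
    v <- v[is.finite(v)]
    agg[k, m] <- switch(aggregate,
                        rms = sqrt(mean(v^2)),
                        mean_abs = mean(abs(v)),
                        end = abs(v[length(v)]))
  }
  total <- colSums(abs(agg))
  ranking <- tibble::tibble(parameter = colnames(agg),
                            aggregate_si = unname(total))
  ranking <- ranking[order(-ranking$aggregate_si), ]
  structure(list(si_matrix = agg, raw = raw, si_time = si, ranking = ranking,
                 aggregate = aggregate),
            class = "hsp90_sensitivity")
}

#' @export
print.hsp90_sensitivity <- function(x, ...) {
  cat("<hsp90_sensitivity> ", nrow(x$si_matrix), " output(s) x ",
      ncol(x$si_matrix), " parameter(s), aggregate = ", x$aggregate, "\n",
      sep = "")
  cat("top parameters: ",
      paste(utils::head(x$ranking$parameter, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy relative sensitivities
#' @param x an \code{hsp90_sensitivity}.
#' @param ... unused.
#' @return long tibble (output, parameter, si).
#' @method tidy hsp90_sensitivity
#' @export
tidy.hsp90_sensitivity <- function(x, ...) {
  m <- x$si_matrix
  tibble::tibble(output = rep(rownames(m), ncol(m)),
                 parameter = rep(colnames(m), each = nrow(m)),
                 si = as.vector(m))
}

#' Identifiability correlation matrix of the sensitivity profiles
#'
#' Pearson correlation between parameter columns of the raw sensitivity
#' array stacked over outputs and sampling times. A pair of parameters
#' with correlation near +1 or -1 cannot be distinguished by the data:
#' a change in one is compensated by the other.
#'
#' @param raw array from \code{\link{dynamic_sensitivities}} (or an
#'   \code{hsp90_sensitivity}).
#' @param zero_var_flag value placed on rows/columns with zero variance
#'   (flagged, not NaN-propagated); their diagonal stays 1.
#' @return symmetric parameter x parameter matrix with unit diagonal.
#' @export
sensitivity_correlation_matrix <- function(raw, zero_var_flag = NA_real_) {
  if (inherits(raw, "hsp90_sensitivity")) raw <- raw$raw
  d <- dim(raw)
  if (d[3] < 2L) stop("at least 2 sampling points are required")
  # stack outputs and times: (outputs*times) x parameters
  M <- matrix(aperm(raw, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  colnames(M) <- dimnames(raw)[[2]]
  sds <- apply(M, 2, stats::sd)
  C <- matrix(zero_var_flag, d[2], d[2],
              dimnames = list(colnames(M), colnames(M)))
  ok <- which(sds > 0)
  if (length(ok) > 1L) C[ok, ok] <- stats::cor(M[, ok, drop = FALSE])
  diag(C) <- 1
  # exact symmetry
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  C
}
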