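#' Generate one synthetic percent-of-max time course
#'
#' Simulates the model from the default initial condition at the given
#' stress strength, takes the series of one species at the requested
#' sampling times, converts it to percent of maximum, and adds i.i.d.
#' Gaussian noise (in percent units) clamped below at zero. The injected
#' noise draws are recorded so that bookkeeping identities (e.g. the cost
#' at the generating truth equalling the summed squared noise) can be
#' verified exactly.
#'
#' @param model an \code{hsp90_model}.
#' @param params parameter set (defaults to the model's).
#' @param k_stress stress strength of the condition.
#' @param species measured species label.
#' @param times sampling times (s).
#' @param noise_sd noise standard deviation in percent units (>= 0).
#' @param seed integer seed.
#' @param experiment_id identifier carried in the record.
#' @param noise one of \code{"additive"} (default) or
#'   \code{"multiplicative"} (sd interpreted as a relative factor).
#' @param x0 initial state for the simulation.
#' @return a list (experiment record) with fields \code{experiment_id},
#'   \code{measured_species}, \code{k_stress}, \code{times},
#'   \code{values_percent}, \code{noiseless_percent}, \code{injected_noise},
#'   \code{noise_sd}, \code{seed}.
#' @export
generate_timecourse_data <- function(model, params = model$parameters,
                                     k_stress, species, times,
                                     noise_sd = 5, seed = 1,
                                     experiment_id = 1L,
                                     noise = c("additive", "multiplicative"),
                                     x0 = default_initial_state(model)) {
  stopifnot(inherits(model, "hsp90_model"))
  noise <- match.arg(noise)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!species %in% model$species$name) stop("species not in model: ", species)
  clean <- predict_percent(model, params, k_stress, species, times, x0)
  set.seed(seed)
  eps <- if (noise == "additive") {
    stats::rnorm(length(times), 0, noise_sd)
  } else {
    clean * (stats::rnorm(length(times), 0, noise_sd / 100))
  }
  if (noise_sd == 0) eps <- rep(0, length(times))
  raw <- clean + eps
  vals <- pmax(raw, 0)
  # re-record the effectively injected noise after the clamp so that
  # sum(injected^2) equals the cost at the generating truth exactly
  injected <- vals - clean
  list(experiment_id = experiment_id, measured_species = species,
       k_stress = k_stress, times = times, values_percent = vals,
       noiseless_percent = clean, injected_noise = injected,
       noise_sd = noise_sd, seed = seed)
}

#' Default irregular sampling grid of the synthetic experiments
#'
#' Dense early points over the fast rise (0--600 s) and sparse late points
#' out to 14400 s, emulating blot sampling schedules.
#'
#' @return numeric vector of times (s).
#' @export
default_sampling_times <- function() {
  c(60, 180, 300, 600, 1200, 2400, 3600, 7200, 10800, 14400)
}

#' Generate the four-experiment synthetic fitting study
#'
#' Emulates the statistical structure of the fitting data: three
#' trimer-occupancy (HSF1_3S) time courses at increasing stress strengths
#' and one mono-phosphorylated complex (HHp) course at a fourth stress
#' value, all as sparse, noisy percent-of-max series.
#'
#' @param model an \code{hsp90_model}.
#' @param params parameter set (defaults to the model's).
#' @param stress_triplet increasing stress values of the three HSF1_3S
#'   experiments; defaults to the fitted estimates 0.4136, 0.9859, 1.2066.
#' @param hhp_stress stress value of the HHp experiment (default 0.9557).
#' @param times sampling times, shared by the four experiments.
#' @param noise_sd Gaussian noise sd in percent units (default 5).
#' @param seed integer seed.
#' @return an object of class \code{hsp90_study}: list with
#'   \code{datasets} (4 experiment records, ids 1--4), \code{truth}
#'   (generating parameters + stress values), \code{noise_sd}, \code{seed}.
#' @export
generate_study <- function(model, params = model$parameters,
                           stress_triplet = c(0.4136, 0.9859, 1.2066),
                           hhp_stress = 0.9557,
                           times = default_sampling_times(),
                           noise_sd = 5, seed = 1) {
  if (is.unsorted(stress_triplet, strictly = TRUE)) {
    stop("stress_triplet must be strictly increasing")
  }
  specs <- list(
    list(id = 1L, sp = "HSF1_3S", ks = stress_triplet[1]),
    list(id = 2L, sp = "HSF1_3S", ks = stress_triplet[2]),
    list(id = 3L, sp = "HSF1_3S", ks = stress_triplet[3]),
    list(id = 4L, sp = "HHp",     ks = hhp_stress)
  )
  datasets <- lapply(specs, function(s) {
    generate_timecourse_data(model, params, s$ks, s$sp, times,
                             noise_sd = noise_sd, seed = seed + 101L * s$id,
                             experiment_id = s$id)
  })
  structure(list(datasets = datasets,
                 truth = list(parameters = params,
                              stress_values = c(stress_triplet, hhp_stress)),
                 noise_sd = noise_sd, seed = seed),
            class = "hsp90_study")
}

#' @export
print.hsp90_study <- function(x, ...) {
  cat("<hsp90_study> ", length(x$datasets), " synthetic experiments, noise sd ",
      x$noise_sd, "%, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Tidy a synthetic study into a long tibble
#'
#' @param x an \code{hsp90_study}.
#' @param ... unused.
#' @return tibble with columns \code{experiment_id}, \code{measured_species},
#'   \code{k_stress}, \code{time}, \code{value_percent}.
#' @method tidy hsp90_study
#' @export
tidy.hsp90_study <- function(x, ...) {
  dplyr::bind_rows(lapply(x$datasets, function(e) {
    tibble::tibble(experiment_id = e$experiment_id,
                   measured_species = e$measured_species,
                   k_stress = e$k_stress,
                   time = e$times, value_percent = e$values_percent)
  }))
}

#' Write a study to CSV (+ truth JSON)
#'
#' @param x an \code{hsp90_study}.
#' @param csv_path path for the long-format CSV.
#' @param truth_path optional path for the generating-truth JSON.
#' @return \code{csv_path}, invisibly.
#' @export
write_study <- function(x, csv_path, truth_path = NULL) {
  utils::write.csv(tidy.hsp90_study(x), csv_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    jsonlite::write_json(
      list(stress_values = x$truth$stress_values,
           noise_sd = x$noise_sd, seed = x$seed,
           constants = as.list(x$truth$parameters$values)),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
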