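#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_linetype_manual theme_minimal facet_wrap
NULL

#' Tidy a time course into long format
#'
#' @param x an \code{hsp90_timecourse} tibble.
#' @param ... optional character vector \code{species} to keep.
#' @return long tibble (time, species, concentration).
#' @method tidy hsp90_timecourse
#' @export
tidy.hsp90_timecourse <- function(x, ...) {
  args <- list(...)
  out <- tidyr::pivot_longer(tibble::as_tibble(unclass(x)), -"time",
                             names_to = "species",
                             values_to = "concentration")
  if (!is.null(args$species)) out <- out[out$species %in% args$species, ]
  out
}

#' Plot a simulated time course
#'
#' @param object an \code{hsp90_timecourse}.
#' @param species species to show (default: the measured outputs and the
#'   closed chaperone).
#' @param percent show percent-of-max instead of concentrations.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot hsp90_timecourse
#' @export
autoplot.hsp90_timecourse <- function(object,
                                      species = c("HSF1_3S", "HHp", "HSP90c"),
                                      percent = FALSE, ...) {
  long <- tidy.hsp90_timecourse(object, species = species)
  if (percent) {
    long <- dplyr::group_by(long, .data$species)
    long <- dplyr::mutate(long,
      concentration = 100 * .data$concentration / max(.data$concentration))
    long <- dplyr::ungroup(long)
  }
  ggplot(long, aes(x = .data$time, y = .data$concentration,
                   colour = .data$species)) +
    geom_line() +
    labs(x = "time (s)",
         y = if (percent) "percent of maximum" else "concentration (nM)") +
    theme_minimal()
}

#' Tidy a bifurcation diagram into plottable branch segments
#'
#' Splits each branch at its turning points so stable and unstable segments
#' can be drawn with distinct line types.
#'
#' @param x an \code{hsp90_bifurcation}.
#' @param ... unused.
#' @return tibble (branch, segment, parameter, value, stable, physical).
#' @method tidy hsp90_bifurcation
#' @export
tidy.hsp90_bifurcation <- function(x, ...) {
  obs <- x$observable
  out <- lapply(seq_along(x$branches), function(i) {
    pts <- x$branches[[i]]$points
    seg <- cumsum(c(1, abs(diff(pts$stable)) > 0))
    tibble::tibble(branch = i, segment = paste(i, seg, sep = "."),
                   parameter = pts$parameter, value = pts[[obs]],
                   stable = pts$stable, physical = pts$physical)
  })
  dplyr::bind_rows(out)
}

#' Plot a bifurcation diagram
#'
#' Stable branches solid, unstable dashed; limit and Hopf points marked.
#'
#' @param object an \code{hsp90_bifurcation}.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot hsp90_bifurcation
#' @export
autoplot.hsp90_bifurcation <- function(object, ...) {
  long <- tidy.hsp90_bifurcation(object)
  sp <- object$special_points
  g <- ggplot(long, aes(x = .data$parameter, y = .data$value,
                        group = .data$segment,
                        linetype = .data$stable)) +
    geom_line() +
    scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                          labels = c(`TRUE` = "stable", `FALSE` = "unstable"),
                          name = NULL) +
    labs(x = object$parameter_name, y = object$observable,
         subtitle = paste("classification:", object$classification)) +
    theme_minimal()
  if (nrow(sp) > 0) {
    spv <- tibble::tibble(
      parameter = sp$parameter_value,
      value = vapply(sp$state, function(s) unname(s[object$observable]), 0),
      kind = sp$kind)
    g <- g + geom_point(data = spv,
                        aes(x = .data$parameter, y = .data$value,
                            shape = .data$kind),
                        inherit.aes = FALSE, size = 2)
  }
  g
}

#' Glance at a bifurcation diagram
#' @param x an \code{hsp90_bifurcation}.
#' @param ... unused.
#' @return one-row tibble (classification, limit points, Hopf points,
#'   branches, hopf_present).
#' @method glance hsp90_bifurcation
#' @export
glance.hsp90_bifurcation <- function(x, ...) {
  sp <- x$special_points
  tibble::tibble(
    classification = x$classification,
    n_limit_points = length(unique(signif(
      sp$parameter_value[sp$kind == "limit_point"], 6))),
    n_hopf = length(unique(signif(sp$parameter_value[sp$kind == "hopf"], 6))),
    n_branches = length(x$branches),
    hopf_present = x$hopf_present
  )
}
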