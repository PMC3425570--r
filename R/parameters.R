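#' Kinetic parameter set for the HSP90 heat-shock network
#'
#' Builds the canonical set of 62 named kinetic constants of the three-module
#' HSP90 network together with the scalar stress strength \code{k_stress}.
#' Fifty-three constants (modules 1 and 2 plus the transcription/translation
#' bridge of module 3) are flagged \code{"estimated"}; the nine constants of
#' the ATP-assisted open-to-closed conformational cycle are flagged
#' \code{"literature"}. Four entries are concentrations in nM (the initial
#' HSF1 pool and the conserved HSE, MK3 and PP5 totals); all others are rate
#' constants in 1/s (unimolecular or zeroth order, the latter in nM/s) or
#' 1/(nM s) (bimolecular).
#'
#' @param overrides named numeric vector or list of constants to override,
#'   e.g. \code{c(k_k1_f = 0.05)}.
#' @param k_stress non-negative scalar stress strength (dimensionless rate
#'   multiplier on the stress-activation steps). Default 0 (unstressed).
#' @return an object of class \code{hsp90_parameters}: a list with elements
#'   \code{values} (named numeric, length 62), \code{k_stress},
#'   \code{provenance}, \code{units} and \code{number} (Table position).
#' @examples
#' p <- hsp90_parameters(k_stress = 0.9859)
#' sum(p$provenance == "estimated")
#' @export
hsp90_parameters <- function(overrides = NULL, k_stress = 0) {
  def <- parameter_definitions()
  values <- stats::setNames(def$value, def$name)
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), names(values))
    if (length(bad) > 0L) {
      stop("unknown parameter constant(s): ", paste(bad, collapse = ", "))
    }
    values[names(overrides)] <- overrides
  }
  if (any(values < 0)) stop("all kinetic constants must be non-negative")
  if (length(k_stress) != 1L || is.na(k_stress) || k_stress < 0) {
    stop("k_stress must be a single non-negative number")
  }
  structure(
    list(
      values = values,
      k_stress = as.numeric(k_stress),
      provenance = stats::setNames(def$provenance, def$name),
      units = stats::setNames(def$unit, def$name),
      number = stats::setNames(def$number, def$name)
    ),
    class = "hsp90_parameters"
  )
}

# Canonical definition table for the 62 constants. Order is the Table
# position: module 1 first (with the four concentration entries at rows 5-8),
# then the PdP constants of module 2, the transcription/translation bridge,
# and the nine literature constants of the conformational cycle at rows
# 53-61.  Values are the shipped calibration used for all bifurcation and
# sensitivity analyses.
parameter_definitions <- function() {
  d <- function(name, value, unit, provenance, description) {
    data.frame(name = name, value = value, unit = unit,
               provenance = provenance, description = description,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    ## -- module 1: HSF1 activation, oligomerization, HSE binding, feedback
    d("k_act",     6.5e-05, "1/s",      "estimated", "stress activation HSF1 -> HSF1S (rate carries k_stress)"),
    d("k_deact",   0.01, "1/s",      "estimated", "deactivation HSF1S -> HSF1"),
    d("k_rel",     0.0004, "1/s",      "estimated", "stress dissociation C90 -> HSF1S + HSP90c (rate carries k_stress)"),
    d("k_rel0",    1e-06, "1/s",      "estimated", "basal dissociation C90 -> HSF1S + HSP90c"),
    d("hsf1_init", 2.89e2, "nM",       "estimated", "initial inactive HSF1 monomer pool"),
    d("hse_tot",   1.32e3, "nM",       "estimated", "total heat-shock element (conserved)"),
    d("mk3_tot",   9.20e1, "nM",       "estimated", "total kinase MK3 (conserved)"),
    d("pp5_tot",   3.91e1, "nM",       "estimated", "total phosphatase PP5 (conserved)"),
    d("k_dim_f",   0.0002, "1/(nM s)", "estimated", "slow dimerization 2 HSF1S -> HSF1_2S"),
    d("k_dim_b",   0.01, "1/s",      "estimated", "dimer dissociation"),
    d("k_tri_f",   0.01, "1/(nM s)", "estimated", "fast trimerization HSF1_2S + HSF1S -> HSF1_3S"),
    d("k_tri_b",   0.0005, "1/s",      "estimated", "trimer dissociation"),
    d("k_hse_f",   0.0006936, "1/(nM s)", "estimated", "trimer-HSE binding -> HH"),
    d("k_hse_b",   0.02312, "1/s",      "estimated", "HH dissociation"),
    d("k_fb_f",    0.001, "1/(nM s)", "estimated", "negative feedback HSP90c + HSF1 -> C90"),
    d("k_fb_b",    1e-05, "1/s",      "estimated", "C90 -> HSP90c + HSF1"),
    d("k_syn_hsf1", 0.05, "nM/s",    "estimated", "zeroth-order HSF1 synthesis"),
    d("kd_hsf1",   0.0002, "1/s",      "estimated", "degradation of HSF1"),
    d("kd_hsf1s",  0.0001, "1/s",      "estimated", "degradation of HSF1S"),
    d("kd_hsf12s", 0.0001, "1/s",      "estimated", "degradation of HSF1_2S"),
    d("kd_hsf13s", 0.0001, "1/s",      "estimated", "degradation of HSF1_3S"),
    ## -- module 2: four kinase steps (Michaelis complexes with MK3)
    d("k_k1_f", 0.08, "1/(nM s)", "estimated", "MK3 binding to HH (mono-phosphorylation forward)"),
    d("k_k1_b", 3.445,    "1/s",      "estimated", "MK3:HH dissociation"),
    d("k_k1_c", 0.08, "1/s",      "estimated", "catalysis MK3:HH -> HHp + MK3"),
    d("k_k2_f", 0.04624, "1/(nM s)", "estimated", "MK3 binding to HHp"),
    d("k_k2_b", 5.341,    "1/s",      "estimated", "MK3:HHp dissociation"),
    d("k_k2_c", 0.4393, "1/s",      "estimated", "catalysis MK3:HHp -> HHpp + MK3"),
    d("k_k3_f", 0.04624, "1/(nM s)", "estimated", "MK3 binding to HHpp"),
    d("k_k3_b", 5.341,    "1/s",      "estimated", "MK3:HHpp dissociation"),
    d("k_k3_c", 0.4393, "1/s",      "estimated", "catalysis MK3:HHpp -> HHppp + MK3"),
    d("k_k4_f", 0.04624, "1/(nM s)", "estimated", "MK3 binding to HHppp"),
    d("k_k4_b", 5.341,    "1/s",      "estimated", "MK3:HHppp dissociation"),
    d("k_k4_c", 0.4393, "1/s",      "estimated", "catalysis MK3:HHppp -> HHpppp + MK3"),
    ## -- module 2: dephosphorylation (PP5 activation cascade)
    d("k_p4_f", 0.05318, "1/(nM s)", "estimated", "PP5 binding to HHpppp"),
    d("k_p4_b", 1.156, "1/s",      "estimated", "PP5:HHpppp dissociation"),
    d("k_p4_c", 0.05549, "1/s",      "estimated", "catalysis PP5:HHpppp -> HHppp + PP5S"),
    d("k_p3",   0.002312, "1/(nM s)", "estimated", "direct catalysis HHppp + PP5S -> HHpp + PP5S"),
    d("k_dec_f", 0.001387, "1/(nM s)", "estimated", "decoy sequestration of MK3 by free HSF1_3S trimer"),
    d("k_dec_b", 0.2312, "1/s",     "estimated", "MK3:HSF1_3S decoy dissociation"),
    d("k_p2",   0.148, "1/(nM s)", "estimated", "direct catalysis HHpp + PP5 -> HHp + PP5"),
    d("k_p1",   0.001618, "1/(nM s)", "estimated", "direct catalysis HHp + PP5S -> HH + PP5S"),
    d("k_p1_pp5", 0.03699, "1/(nM s)", "estimated", "direct catalysis HHp + PP5 -> HH + PP5"),
    d("k_pdeact", 0.01156, "1/s",    "estimated", "phosphatase deactivation PP5S -> PP5"),
    d("k_seq_f", 0.01387, "1/(nM s)", "estimated", "high-affinity sequestration HH + PP5 -> PP5:HH"),
    d("k_seq_b", 0.3699, "1/s",     "estimated", "PP5:HH dissociation"),
    ## -- module 3 bridge: transcription, translation, degradation
    d("k_tx",   1e-05, "1/s",  "estimated", "transcription driven by HHpppp (zeroth order in mRNA)"),
    d("k_tx0",  1e-08, "nM/s", "estimated", "basal transcription"),
    d("kd_mrna", 0.001, "1/s", "estimated", "mRNA90 decay"),
    d("k_tl",   0.006, "1/s",  "estimated", "translation mRNA90 -> mRNA90 + HSP90open"),
    d("kd_c",   0.002, "1/s",  "estimated", "degradation of HSP90closed"),
    d("kd_o",   0.0001, "1/s",  "estimated", "degradation of HSP90open"),
    d("kd_c90", 0.001, "1/s",  "estimated", "degradation of the C90 complex"),
    ## -- module 3: ATP-assisted conformational cycle (literature, rows 53-61)
    d("kh_on_atp",  1.0e-1, "1/s", "literature", "ATP loading HSP90open -> open:ATP (ATP lumped, fixed)"),
    d("kh_off_atp", 4.0e-1, "1/s", "literature", "ATP unloading open:ATP -> HSP90open"),
    d("kh1_f", 6.0e-2,  "1/s", "literature", "open:ATP -> I1"),
    d("kh1_b", 1.5e-2,  "1/s", "literature", "I1 -> open:ATP"),
    d("kh2_f", 2.5e-1,  "1/s", "literature", "I1 -> I2"),
    d("kh2_b", 5.0e-2,  "1/s", "literature", "I2 -> I1"),
    d("kh3_f", 6.0e-1,  "1/s", "literature", "I2 -> HSP90closed"),
    d("kh3_b", 1.0e-2,  "1/s", "literature", "HSP90closed -> I2"),
    d("kh_cyc", 2.0e-2, "1/s", "literature", "ATPase reset HSP90closed -> HSP90open"),
    ## -- row 62
    d("k_clear", 0.002312, "1/s", "estimated", "promoter clearance HHpppp -> HSE + HSF1_3S (spent complex displaced after transcription)")
  )
  tab$number <- seq_len(nrow(tab))
  tab
}

#' @export
print.hsp90_parameters <- function(x, ...) {
  cat("<hsp90_parameters> 62 kinetic constants (",
      sum(x$provenance == "estimated"), " estimated, ",
      sum(x$provenance == "literature"), " literature), k_stress = ",
      format(x$k_stress), "\n", sep = "")
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x an \code{hsp90_parameters} object.
#' @param ... unused.
#' @return a tibble with columns \code{number}, \code{name}, \code{value},
#'   \code{unit}, \code{provenance}.
#' @importFrom generics tidy
#' @method tidy hsp90_parameters
#' @export
tidy.hsp90_parameters <- function(x, ...) {
  tibble::tibble(
    number = unname(x$number),
    name = names(x$values),
    value = unname(x$values),
    unit = unname(x$units),
    provenance = unname(x$provenance)
  )
}

#' Update constants in a parameter set
#'
#' @param params an \code{hsp90_parameters} object.
#' @param ... named constants, e.g. \code{set_constants(p, k_k1_f = 0.05)}.
#' @param k_stress optionally a new stress strength.
#' @return the modified parameter set.
#' @export
set_constants <- function(params, ..., k_stress = NULL) {
  stopifnot(inherits(params, "hsp90_parameters"))
  upd <- unlist(list(...))
  if (length(upd) > 0L) {
    bad <- setdiff(names(upd), names(params$values))
    if (length(bad) > 0L) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    params$values[names(upd)] <- upd
  }
  if (!is.null(k_stress)) {
    if (k_stress < 0) stop("k_stress must be non-negative")
    params$k_stress <- k_stress
  }
  params
}

#' Write a parameter set to a flat key=value text file
#'
#' One line per constant, \code{name = value  # unit, provenance}; a final
#' line carries \code{k_stress}. The format round-trips through
#' \code{\link{read_parameter_file}}.
#'
#' @param params an \code{hsp90_parameters} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameter_file <- function(params, path) {
  stopifnot(inherits(params, "hsp90_parameters"))
  lines <- sprintf("%s = %.10g  # %s, %s",
                   names(params$values), unname(params$values),
                   unname(params$units), unname(params$provenance))
  lines <- c(lines, sprintf("k_stress = %.10g  # 1, bifurcation parameter",
                            params$k_stress))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from a key=value file
#'
#' Accepts the flat format of \code{\link{write_parameter_file}} and is
#' tolerant of XPPAUT parameter syntax (\code{par name=value}, optionally
#' several per line separated by commas). Unknown names are an error;
#' missing names keep their default value.
#'
#' @param path input file path.
#' @return an \code{hsp90_parameters} object.
#' @export
read_parameter_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- sub("^\\s*par(am(eters?)?)?\\s+", "", lines, ignore.case = TRUE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  pieces <- unlist(strsplit(lines, ","))
  pieces <- trimws(pieces)
  pieces <- pieces[grepl("=", pieces, fixed = TRUE)]
  kv <- strsplit(pieces, "=", fixed = TRUE)
  nm <- trimws(vapply(kv, `[`, "", 1L))
  val <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(val)) stop("non-numeric parameter value for: ",
                       paste(nm[is.na(val)], collapse = ", "))
  ks <- 0
  if ("k_stress" %in% nm) {
    ks <- val[match("k_stress", nm)]
    val <- val[nm != "k_stress"]
    nm <- nm[nm != "k_stress"]
  }
  hsp90_parameters(overrides = stats::setNames(val, nm), k_stress = ks)
}
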