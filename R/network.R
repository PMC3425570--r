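#' Build the three-module HSP90 reaction network
#'
#' Assembles the canonical mass-action scheme of the HSP90 heat-shock
#' network and returns it as an \code{hsp90_model} object carrying the
#' species list, the reaction list, the stoichiometric matrix and the bound
#' parameter set.
#'
#' The full variant has exactly 27 dynamical species across three modules:
#' \describe{
#'   \item{module 1}{stress activation of the HSF1 monomer, step-wise
#'     dimer/trimer formation, trimer binding to the heat-shock element
#'     (HSE) giving the HH complex, and the negative-feedback sequestration
#'     of inactive HSF1 by closed HSP90 (complex C90). Stress enters as the
#'     multiplicative factor \code{k_stress} on the two activation steps
#'     (HSF1 -> HSF1S and C90 -> HSF1S + HSP90c).}
#'   \item{module 2}{the four-step phosphorylation ladder HH -> HHp -> HHpp
#'     -> HHppp -> HHpppp via Michaelis complexes with the kinase MK3, and
#'     dephosphorylation by the phosphatase PP5: PP5 binds the
#'     tetra-phosphorylated form and its catalytic release generates the
#'     activated form PP5S, which strips the remaining phosphates (the two
#'     lowest steps as direct second-order catalysis); PP5S deactivates back
#'     to PP5, and PP5 sequesters unphosphorylated HH with high affinity.}
#'   \item{module 3}{HHpppp-driven transcription of mRNA90, translation to
#'     open HSP90, the ATP-assisted conformational cycle open -> open:ATP ->
#'     I1 -> I2 -> closed (ATP held as a fixed input, lumped into the
#'     pseudo-first-order loading rate), the ATPase reset closed -> open,
#'     first-order degradation, and the closed form feeding back onto HSF1.}
#' }
#'
#' @param variant one of \code{"full"} (default), \code{"no_feedback"} (the
#'   two HSP90closed--HSF1 binding constants zeroed) or \code{"module2_only"}
#'   (the isolated PdP ladder).
#' @param params an \code{hsp90_parameters} object; default
#'   \code{hsp90_parameters()}.
#' @param overrides optional named numeric vector of constants forwarded to
#'   \code{\link{set_constants}}.
#' @return an object of class \code{hsp90_model}.
#' @examples
#' m <- build_network("full")
#' nrow(m$species)  # 27
#' @export
build_network <- function(variant = c("full", "no_feedback", "module2_only"),
                          params = hsp90_parameters(), overrides = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "hsp90_parameters"))
  if (!is.null(overrides)) params <- do.call(set_constants, c(list(params), as.list(overrides)))
  if (variant == "no_feedback") {
    params <- set_constants(params, k_fb_f = 0, k_fb_b = 0)
  }

  sp <- species_definitions()
  rx <- reaction_definitions()
  if (variant == "module2_only") {
    rx <- rx[rx$tag == "module2", , drop = FALSE]
    keep <- unlist(strsplit(trimws(paste(rx$reactants, rx$products)), "\\s+"))
    keep <- unique(sub(":[0-9]+$", "", keep[nzchar(keep)]))
    sp <- sp[sp$name %in% keep, , drop = FALSE]
  }
  rownames(sp) <- NULL

  bad <- setdiff(rx$rate_constant, names(params$values))
  if (length(bad) > 0L) stop("unresolved rate constant(s): ", paste(bad, collapse = ", "))

  model <- structure(
    list(
      variant = variant,
      species = tibble::as_tibble(sp),
      reactions = tibble::as_tibble(rx),
      parameters = params,
      fixed_inputs = c(ATP = 2e6)  # nM, lumped into kh_on_atp (pseudo-first order)
    ),
    class = "hsp90_model"
  )
  model <- compile_model(model)
  if (variant != "module2_only" && nrow(model$species) != 27L) {
    stop("model assembly error: expected 27 dynamical species, got ",
         nrow(model$species))
  }
  model
}

# Species table: name, role, default initial concentration key.
species_definitions <- function() {
  s <- function(name, role) data.frame(name = name, role = role, stringsAsFactors = FALSE)
  rbind(
    s("HSF1",       "monomer"),
    s("HSF1S",      "monomer"),
    s("HSF1_2S",    "oligomer"),
    s("HSF1_3S",    "oligomer"),
    s("HSE",        "dna_element"),
    s("HH",         "complex"),
    s("C90",        "complex"),
    s("HHp",        "complex"),
    s("HHpp",       "complex"),
    s("HHppp",      "complex"),
    s("HHpppp",     "complex"),
    s("MK3",        "enzyme"),
    s("MK3_HH",     "complex"),
    s("MK3_HHp",    "complex"),
    s("MK3_HHpp",   "complex"),
    s("MK3_HHppp",  "complex"),
    s("PP5",        "enzyme"),
    s("PP5S",       "enzyme"),
    s("PP5_HHpppp", "complex"),
    s("MK3_HSF1_3S","complex"),
    s("PP5_HH",     "complex"),
    s("mRNA90",     "mrna"),
    s("HSP90o",     "protein_conformer"),
    s("HSP90o_ATP", "protein_conformer"),
    s("I1",         "protein_conformer"),
    s("I2",         "protein_conformer"),
    s("HSP90c",     "protein_conformer")
  )
}

# Reaction table. reactants/products are space-separated species names with
# an optional ":stoich" suffix (only "2" occurs, for the dimerization step).
# stress = TRUE marks rates that additionally carry the k_stress factor.
reaction_definitions <- function() {
  r <- function(reactants, products, k, tag, stress = FALSE) {
    data.frame(reactants = reactants, products = products, rate_constant = k,
               tag = tag, stress = stress, stringsAsFactors = FALSE)
  }
  rbind(
    ## module 1
    r("",                 "HSF1",             "k_syn_hsf1", "module1"),
    r("HSF1",             "HSF1S",            "k_act",      "module1", stress = TRUE),
    r("HSF1S",            "HSF1",             "k_deact",    "module1"),
    r("HSF1S:2",          "HSF1_2S",          "k_dim_f",    "module1"),
    r("HSF1_2S",          "HSF1S:2",          "k_dim_b",    "module1"),
    r("HSF1_2S HSF1S",    "HSF1_3S",          "k_tri_f",    "module1"),
    r("HSF1_3S",          "HSF1_2S HSF1S",    "k_tri_b",    "module1"),
    r("HSF1_3S HSE",      "HH",               "k_hse_f",    "module1"),
    r("HH",               "HSF1_3S HSE",      "k_hse_b",    "module1"),
    r("HSP90c HSF1",      "C90",              "k_fb_f",     "feedback"),
    r("C90",              "HSP90c HSF1",      "k_fb_b",     "feedback"),
    r("C90",              "HSF1S HSP90c",     "k_rel",      "module1", stress = TRUE),
    r("C90",              "HSF1S HSP90c",     "k_rel0",     "module1"),
    r("HSF1",             "",                 "kd_hsf1",    "degradation"),
    r("HSF1S",            "",                 "kd_hsf1s",   "degradation"),
    r("HSF1_2S",          "",                 "kd_hsf12s",  "degradation"),
    r("HSF1_3S",          "",                 "kd_hsf13s",  "degradation"),
    ## module 2: kinase ladder
    r("HH MK3",           "MK3_HH",           "k_k1_f", "module2"),
    r("MK3_HH",           "HH MK3",           "k_k1_b", "module2"),
    r("MK3_HH",           "HHp MK3",          "k_k1_c", "module2"),
    r("HHp MK3",          "MK3_HHp",          "k_k2_f", "module2"),
    r("MK3_HHp",          "HHp MK3",          "k_k2_b", "module2"),
    r("MK3_HHp",          "HHpp MK3",         "k_k2_c", "module2"),
    r("HHpp MK3",         "MK3_HHpp",         "k_k3_f", "module2"),
    r("MK3_HHpp",         "HHpp MK3",         "k_k3_b", "module2"),
    r("MK3_HHpp",         "HHppp MK3",        "k_k3_c", "module2"),
    r("HHppp MK3",        "MK3_HHppp",        "k_k4_f", "module2"),
    r("MK3_HHppp",        "HHppp MK3",        "k_k4_b", "module2"),
    r("MK3_HHppp",        "HHpppp MK3",       "k_k4_c", "module2"),
    ## module 2: phosphatase cascade
    r("HHpppp PP5",       "PP5_HHpppp",       "k_p4_f", "module2"),
    r("PP5_HHpppp",       "HHpppp PP5",       "k_p4_b", "module2"),
    r("PP5_HHpppp",       "HHppp PP5S",       "k_p4_c", "module2"),
    r("HHppp PP5S",       "HHpp PP5S",        "k_p3",   "module2"),
    r("HSF1_3S MK3",      "MK3_HSF1_3S",      "k_dec_f", "module1"),
    r("MK3_HSF1_3S",      "HSF1_3S MK3",      "k_dec_b", "module1"),
    r("HHpp PP5",         "HHp PP5",          "k_p2",   "module2"),
    r("HHp PP5S",         "HH PP5S",          "k_p1",   "module2"),
    r("HHp PP5",          "HH PP5",           "k_p1_pp5", "module2"),
    r("HHpppp",           "HSE HSF1_3S",      "k_clear",  "module1"),
    r("PP5S",             "PP5",              "k_pdeact", "module2"),
    r("HH PP5",           "PP5_HH",           "k_seq_f", "module2"),
    r("PP5_HH",           "HH PP5",           "k_seq_b", "module2"),
    ## module 3
    r("HHpppp",           "HHpppp mRNA90",    "k_tx",   "module3"),
    r("",                 "mRNA90",           "k_tx0",  "module3"),
    r("mRNA90",           "",                 "kd_mrna", "degradation"),
    r("mRNA90",           "mRNA90 HSP90o",    "k_tl",   "module3"),
    r("HSP90o",           "HSP90o_ATP",       "kh_on_atp",  "module3"),
    r("HSP90o_ATP",       "HSP90o",           "kh_off_atp", "module3"),
    r("HSP90o_ATP",       "I1",               "kh1_f",  "module3"),
    r("I1",               "HSP90o_ATP",       "kh1_b",  "module3"),
    r("I1",               "I2",               "kh2_f",  "module3"),
    r("I2",               "I1",               "kh2_b",  "module3"),
    r("I2",               "HSP90c",           "kh3_f",  "module3"),
    r("HSP90c",           "I2",               "kh3_b",  "module3"),
    r("HSP90c",           "HSP90o",           "kh_cyc", "module3"),
    r("HSP90c",           "",                 "kd_c",   "degradation"),
    r("HSP90o",           "",                 "kd_o",   "degradation"),
    r("C90",              "",                 "kd_c90", "degradation")
  )
}

# Parse "A B:2" into index/stoich pairs and precompute everything the rate,
# rhs and Jacobian evaluations need.
compile_model <- function(model) {
  sp_names <- model$species$name
  n_sp <- length(sp_names)
  rx <- model$reactions
  n_rx <- nrow(rx)

  parse_side <- function(str) {
    if (!nzchar(str)) return(data.frame(idx = integer(0), st = integer(0)))
    parts <- strsplit(trimws(str), "\\s+")[[1]]
    nm <- sub(":[0-9]+$", "", parts)
    st <- ifelse(grepl(":", parts), as.integer(sub("^.*:", "", parts)), 1L)
    idx <- match(nm, sp_names)
    if (anyNA(idx)) stop("undeclared species in reaction: ", paste(nm[is.na(idx)], collapse = ", "))
    if (any(st < 1L)) stop("stoichiometries must be positive integers")
    data.frame(idx = idx, st = st)
  }

  S <- matrix(0L, n_sp, n_rx, dimnames = list(sp_names, NULL))
  # reactant index encoding: ra/rb are species indices (NA when absent);
  # a second-order homodimerization has ra == rb.
  ra <- rb <- rep(NA_integer_, n_rx)
  for (j in seq_len(n_rx)) {
    re <- parse_side(rx$reactants[j])
    pr <- parse_side(rx$products[j])
    if (sum(re$st) > 2L) stop("at most bimolecular reactant sides are allowed")
    for (i in seq_len(nrow(re))) S[re$idx[i], j] <- S[re$idx[i], j] - re$st[i]
    for (i in seq_len(nrow(pr))) S[pr$idx[i], j] <- S[pr$idx[i], j] + pr$st[i]
    if (nrow(re) == 1L) {
      ra[j] <- re$idx[1]
      if (re$st[1] == 2L) rb[j] <- re$idx[1]
    } else if (nrow(re) == 2L) {
      ra[j] <- re$idx[1]; rb[j] <- re$idx[2]
    }
  }

  model$S <- S
  model$ra <- ra
  model$rb <- rb
  model$k_index <- match(rx$rate_constant, names(model$parameters$values))
  model$stress_flag <- rx$stress
  model$n_species <- n_sp
  model$n_reactions <- n_rx
  model
}

# Effective rate-constant vector (stress factor applied).
effective_k <- function(model, params = model$parameters) {
  k <- unname(params$values[model$k_index])
  k[model$stress_flag] <- k[model$stress_flag] * params$k_stress
  k
}

#' Stoichiometric matrix of a model
#'
#' @param model an \code{hsp90_model}.
#' @return integer matrix (species x reactions); entry (i, j) is the net
#'   stoichiometry of species i in reaction j.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "hsp90_model"))
  model$S
}

#' Mass-action reaction rate vector
#'
#' Rate j equals the effective rate constant times the product of reactant
#' concentrations raised to their stoichiometries; rates of stress-tagged
#' reactions carry the additional factor \code{k_stress}.
#'
#' @param model an \code{hsp90_model}.
#' @param state numeric concentration vector (nM), one entry per species.
#' @param params optional parameter set overriding the one bound in the
#'   model.
#' @return numeric rate vector (nM/s), one entry per reaction.
#' @export
reaction_rates <- function(model, state, params = model$parameters) {
  stopifnot(inherits(model, "hsp90_model"))
  if (length(state) != model$n_species) stop("state length must equal species count")
  if (any(state < 0)) stop("negative concentration in state")
  k <- effective_k(model, params)
  fa <- ifelse(is.na(model$ra), 1, state[ifelse(is.na(model$ra), 1L, model$ra)])
  fb <- ifelse(is.na(model$rb), 1, state[ifelse(is.na(model$rb), 1L, model$rb)])
  k * fa * fb
}

#' Right-hand side of the mass-action ODE system
#'
#' The system is autonomous; \code{t} is accepted for the integrator
#' contract and ignored. The derivative equals the stoichiometric matrix
#' times the reaction-rate vector.
#'
#' @inheritParams reaction_rates
#' @param t time (s), unused.
#' @return derivative vector (nM/s).
#' @export
network_rhs <- function(model, state, t = 0, params = model$parameters) {
  v <- reaction_rates(model, state, params)
  drop(model$S %*% v)
}

#' Analytic Jacobian of the mass-action right-hand side
#'
#' Closed form from stoichiometry and molecularity: for a unimolecular
#' reaction the rate derivative is k; for A + B it is k[B] and k[A]; for
#' 2A it is 2k[A].
#'
#' @inheritParams reaction_rates
#' @return numeric matrix (species x species).
#' @export
network_jacobian <- function(model, state, params = model$parameters) {
  stopifnot(inherits(model, "hsp90_model"))
  n <- model$n_species
  k <- effective_k(model, params)
  # dv/dx as a dense (reactions x species) matrix
  D <- matrix(0, model$n_reactions, n)
  ra <- model$ra; rb <- model$rb
  for (j in seq_len(model$n_reactions)) {
    if (is.na(ra[j])) next
    if (!is.na(rb[j]) && ra[j] == rb[j]) {
      D[j, ra[j]] <- 2 * k[j] * state[ra[j]]
    } else if (!is.na(rb[j])) {
      D[j, ra[j]] <- k[j] * state[rb[j]]
      D[j, rb[j]] <- k[j] * state[ra[j]]
    } else {
      D[j, ra[j]] <- k[j]
    }
  }
  J <- model$S %*% D
  dimnames(J) <- list(model$species$name, model$species$name)
  J
}

#' Conserved moieties of the network
#'
#' Returns a basis of the left null space of the stoichiometric matrix,
#' scaled to small non-negative integers where such a representative exists
#' (for this network: the total heat-shock element, total kinase and total
#' phosphatase pools). Every returned vector y satisfies y'S = 0 exactly.
#'
#' @param model an \code{hsp90_model}.
#' @return a list of named integer vectors (possibly empty).
#' @export
conserved_moieties <- function(model) {
  stopifnot(inherits(model, "hsp90_model"))
  S <- model$S
  ns <- left_null_basis(S)
  lapply(ns, function(y) stats::setNames(y, model$species$name))
}

# Integer left-null-space basis of an integer matrix via fraction-free
# RREF of t(S). Vectors with mixed signs are flipped/combined towards
# non-negativity when possible.
left_null_basis <- function(S) {
  A <- t(S)                      # reactions x species; null(A) = left null of S
  m <- nrow(A); n <- ncol(A)
  A <- matrix(as.numeric(A), m, n)
  # Gauss-Jordan with partial pivoting (entries stay rational with small
  # denominators; we re-integerize at the end and verify exactly).
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which.max(abs(A[row:m, col])) + row - 1L
    if (abs(A[p, col]) < 1e-10) next
    if (p != row) A[c(p, row), ] <- A[c(row, p), ]
    A[row, ] <- A[row, ] / A[row, col]
    for (r in seq_len(m)) {
      if (r != row && abs(A[r, col]) > 1e-12) A[r, ] <- A[r, ] - A[r, col] * A[row, ]
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivots)
  basis <- list()
  for (f in free) {
    y <- numeric(n)
    y[f] <- 1
    for (i in seq_along(pivots)) y[pivots[i]] <- -A[i, f]
    # rationalize to integers
    y[abs(y) < 1e-10] <- 0
    nz <- y[y != 0]
    if (length(nz) > 0) {
      scale <- min(abs(nz))
      cand <- y / scale
      for (mult in 1:24) {
        if (all(abs(cand * mult - round(cand * mult)) < 1e-8)) { y <- round(cand * mult); break }
      }
    }
    if (sum(y < 0) > sum(y > 0)) y <- -y
    basis <- c(basis, list(y))
  }
  # exact verification; drop anything that fails integer check
  keep <- vapply(basis, function(y) {
    all(y == round(y)) && all(drop(crossprod(y, S)) == 0)
  }, logical(1))
  nonneg_combine(basis[keep])
}

# Greedy recombination of an integer null-space basis towards non-negative
# representatives (moieties). Leaves vectors mixed-sign when no small
# integer combination removes the negatives.
nonneg_combine <- function(basis) {
  if (length(basis) < 2L) return(basis)
  negsum <- function(y) sum(pmax(-y, 0))
  improved <- TRUE
  guard <- 0L
  while (improved && guard < 50L) {
    improved <- FALSE
    guard <- guard + 1L
    for (i in seq_along(basis)) {
      if (negsum(basis[[i]]) == 0) next
      for (j in seq_along(basis)) {
        if (i == j) next
        for (mult in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
          for (cand in list(basis[[i]] + mult * basis[[j]],
                            mult * basis[[j]] - basis[[i]])) {
            if (any(cand != 0) && negsum(cand) < negsum(basis[[i]])) {
              basis[[i]] <- cand
              improved <- TRUE
            }
          }
        }
      }
    }
  }
  # canonical order/scale: divide by gcd, positive orientation
  lapply(basis, function(y) {
    g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), abs(y[y != 0]))
    if (!is.null(g) && length(g) == 1L && g > 1) y <- y / g
    if (sum(y < 0) > sum(y > 0)) y <- -y
    y
  })
}

#' Silence named kinetic constants
#'
#' Returns a copy of the model with the named constants set to zero. Used
#' for the negative-feedback knockout (the forward and backward constants of
#' HSP90closed + HSF1 binding).
#'
#' @param model an \code{hsp90_model}.
#' @param constant_names character vector of constant names (may be empty).
#' @return the modified model.
#' @examples
#' m <- build_network()
#' m_ko <- apply_knockout(m, c("k_fb_f", "k_fb_b"))
#' @export
apply_knockout <- function(model, constant_names) {
  stopifnot(inherits(model, "hsp90_model"))
  if (length(constant_names) == 0L) return(model)
  bad <- setdiff(constant_names, names(model$parameters$values))
  if (length(bad) > 0L) stop("unknown constant name(s): ", paste(bad, collapse = ", "))
  model$parameters$values[constant_names] <- 0
  model
}

#' Default initial state of a model
#'
#' All states start at a small identical positive concentration (a
#' relaxation-experiment convention), except that the conserved pools are
#' loaded at their parameter totals: free HSE at \code{hse_tot}, MK3 at
#' \code{mk3_tot}, PP5 at \code{pp5_tot}, and the inactive HSF1 monomer at
#' \code{hsf1_init}.
#'
#' @param model an \code{hsp90_model}.
#' @param eps background concentration (nM) for all other states.
#' @return named numeric vector of length \code{nrow(model$species)}.
#' @export
default_initial_state <- function(model, eps = 1e-2) {
  x <- stats::setNames(rep(eps, model$n_species), model$species$name)
  v <- model$parameters$values
  if ("HSE" %in% names(x)) x["HSE"] <- v[["hse_tot"]]
  if ("MK3" %in% names(x)) x["MK3"] <- v[["mk3_tot"]]
  if ("PP5" %in% names(x)) x["PP5"] <- v[["pp5_tot"]]
  if ("HSF1" %in% names(x)) x["HSF1"] <- v[["hsf1_init"]]
  x
}

#' @export
print.hsp90_model <- function(x, ...) {
  cat("<hsp90_model> variant '", x$variant, "': ", x$n_species, " species, ",
      x$n_reactions, " reactions, k_stress = ", format(x$parameters$k_stress),
      "\n", sep = "")
  invisible(x)
}

#' Model report as a JSON string
#'
#' Serializes species, reactions and the stoichiometric matrix.
#'
#' @param model an \code{hsp90_model}.
#' @param path optional file to write to.
#' @return the JSON string, invisibly if written to a file.
#' @export
model_report_json <- function(model, path = NULL) {
  rep <- list(
    variant = model$variant,
    species = model$species,
    reactions = model$reactions[, c("reactants", "products", "rate_constant", "tag", "stress")],
    stoichiometric_matrix = unclass(model$S),
    k_stress = model$parameters$k_stress
  )
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Export the model as an XPPAUT .ode file
#'
#' Emits a well-formed XPPAUT file with \code{par} lines for all constants
#' (including \code{k_stress}), the mass-action ODE block, and initial
#' conditions, for cross-checking in external continuation software.
#'
#' @param model an \code{hsp90_model}.
#' @param path output file path.
#' @param x0 optional initial state (defaults to
#'   \code{\link{default_initial_state}}).
#' @return \code{path}, invisibly.
#' @export
export_xpp_ode <- function(model, path, x0 = default_initial_state(model)) {
  sp <- model$species$name
  rx <- model$reactions
  term <- function(j) {
    k <- rx$rate_constant[j]
    fac <- if (rx$stress[j]) paste0(k, "*k_stress") else k
    ra <- model$ra[j]; rb <- model$rb[j]
    if (is.na(ra)) return(fac)
    if (!is.na(rb) && ra == rb) return(paste0(fac, "*", sp[ra], "^2"))
    if (!is.na(rb)) return(paste0(fac, "*", sp[ra], "*", sp[rb]))
    paste0(fac, "*", sp[ra])
  }
  terms <- vapply(seq_len(model$n_reactions), term, "")
  lines <- c(sprintf("# HSP90 heat-shock network, variant %s", model$variant),
             sprintf("par %s=%.10g", names(model$parameters$values),
                     unname(model$parameters$values)),
             sprintf("par k_stress=%.10g", model$parameters$k_stress))
  for (i in seq_along(sp)) {
    coefs <- model$S[i, ]
    use <- which(coefs != 0)
    if (length(use) == 0L) { rhs <- "0" } else {
      parts <- sprintf("%+d*%s", coefs[use], terms[use])
      parts <- sub("^\\+1\\*", "+", parts); parts <- sub("^-1\\*", "-", parts)
      rhs <- paste(parts, collapse = "")
      rhs <- sub("^\\+", "", rhs)
    }
    lines <- c(lines, sprintf("d%s/dt=%s", sp[i], rhs))
  }
  lines <- c(lines, sprintf("init %s=%.10g", sp, unname(x0[sp])), "done")
  writeLines(lines, path)
  invisible(path)
}
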