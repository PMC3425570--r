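test_that("full model assembles with the canonical state and parameter counts", {
  m <- build_network("full")
  expect_identical(nrow(m$species), 27L)
  expect_identical(anyDuplicated(m$species$name), 0L)
  p <- m$parameters
  expect_length(p$values, 62L)
  expect_identical(anyDuplicated(names(p$values)), 0L)
  expect_identical(sum(p$provenance == "estimated"), 53L)
  expect_identical(sum(p$provenance == "literature"), 9L)
  expect_identical(sum(p$units == "nM"), 4L)
  expect_true(all(p$values >= 0))
})

test_that("model variants restrict and zero constants as specified", {
  m2 <- build_network("module2_only")
  expect_true(all(m2$reactions$tag == "module2"))
  expect_setequal(m2$species$name,
                  c("HH", "HHp", "HHpp", "HHppp", "HHpppp",
                    "MK3", "MK3_HH", "MK3_HHp", "MK3_HHpp", "MK3_HHppp",
                    "PP5", "PP5S", "PP5_HHpppp", "PP5_HH"))

  m_ko <- build_network("no_feedback")
  m_full <- build_network("full")
  expect_identical(unname(m_ko$parameters$values[c("k_fb_f", "k_fb_b")]), c(0, 0))
  other <- setdiff(names(m_full$parameters$values), c("k_fb_f", "k_fb_b"))
  expect_identical(m_ko$parameters$values[other], m_full$parameters$values[other])

  expect_error(build_network("unknown"), "arg")
  expect_error(build_network("full", overrides = c(nonsense = 1)), "unknown")
})

test_that("stoichiometric matrix columns encode net stoichiometry", {
  m <- build_network("full")
  S <- stoichiometric_matrix(m)
  rx <- m$reactions
  # A + B -> C single column: reactants -1, products +1
  j <- which(rx$reactants == "HSF1_3S HSE" & rx$products == "HH")
  expect_identical(unname(S["HSF1_3S", j]), -1L)
  expect_identical(unname(S["HSE", j]), -1L)
  expect_identical(unname(S["HH", j]), 1L)
  # reversible pair appears as opposite columns
  jf <- which(rx$reactants == "HSP90c HSF1" & rx$products == "C90")
  jb <- which(rx$reactants == "C90" & rx$products == "HSP90c HSF1")
  expect_identical(S[, jf], -S[, jb])
  # dimerization consumes two monomers
  jd <- which(rx$rate_constant == "k_dim_f")
  expect_identical(unname(S["HSF1S", jd]), -2L)
  # rank equals species count minus number of conserved moieties
  expect_identical(qr(S)$rank, 27L - length(conserved_moieties(m)))
})

test_that("mass-action rates follow molecularity and the stress factor", {
  m <- build_network("full", params = hsp90_parameters(k_stress = 0))
  x <- default_initial_state(m)
  v0 <- reaction_rates(m, x)
  expect_true(all(is.finite(v0)) && all(v0 >= 0))
  # k_stress = 0 silences the stress-tagged reactions regardless of state
  expect_true(all(v0[m$stress_flag] == 0))
  # all-zero state: only the zeroth-order synthesis reactions fire
  vz <- reaction_rates(m, rep(0, 27))
  expect_true(all(vz[!is.na(m$ra)] == 0))
  expect_gt(vz[which(m$reactions$rate_constant == "k_syn_hsf1")], 0)
  expect_error(reaction_rates(m, rep(-1, 27)), "negative")
  # hand-computed bimolecular rate: HSF1_3S + HSE -> HH
  j <- which(m$reactions$rate_constant == "k_hse_f")
  k <- m$parameters$values[["k_hse_f"]]
  expect_equal(v0[j], k * x[["HSF1_3S"]] * x[["HSE"]])
})

test_that("rhs equals S %*% v against an independent accumulation loop", {
  m <- build_network("full", params = hsp90_parameters(k_stress = 0.7))
  set.seed(42)
  for (rep in 1:20) {
    x <- runif(27, 0, 50)
    v <- reaction_rates(m, x)
    acc <- numeric(27)
    for (j in seq_len(m$n_reactions)) acc <- acc + m$S[, j] * v[j]
    expect_equal(unname(network_rhs(m, x)), unname(acc), tolerance = 1e-12)
  }
  # zero state with synthesis terms removed gives a zero derivative
  m0 <- build_network("full", overrides = c(k_syn_hsf1 = 0, k_tx0 = 0))
  expect_equal(unname(network_rhs(m0, rep(0, 27))), rep(0, 27))
})

test_that("analytic Jacobian matches central finite differences", {
  m <- build_network("full", params = hsp90_parameters(k_stress = 1.1))
  set.seed(7)
  worst <- 0
  for (rep in 1:100) {
    x <- runif(27, 0, 100)
    J <- network_jacobian(m, x)
    Jfd <- matrix(0, 27, 27)
    for (i in 1:27) {
      h <- 1e-6 * max(1, abs(x[i]))
      xp <- x; xm <- x
      xp[i] <- x[i] + h; xm[i] <- x[i] - h
      Jfd[, i] <- (network_rhs(m, xp) - network_rhs(m, xm)) / (2 * h)
    }
    worst <- max(worst, max(abs(J - Jfd)) / max(abs(J)))
  }
  expect_lt(worst, 1e-5)
  # zero state: entries from purely bimolecular reactions vanish
  Jz <- network_jacobian(m, rep(0, 27))
  expect_equal(Jz["HH", "HSF1_3S"], 0)
})

test_that("conserved moieties are exact non-negative left-null vectors", {
  m <- build_network("full")
  mo <- conserved_moieties(m)
  expect_length(mo, 3L)
  for (y in mo) {
    expect_true(all(y >= 0))
    expect_true(all(y == round(y)))
    expect_true(all(drop(crossprod(y, m$S)) == 0))
  }
  # the kinase, phosphatase and promoter-element pools are each conserved
  free_of <- vapply(mo, function(y) {
    nm <- names(y)[y != 0]
    if ("MK3" %in% nm) "MK3" else if ("PP5" %in% nm) "PP5" else "HSE"
  }, "")
  expect_setequal(free_of, c("MK3", "PP5", "HSE"))
})

test_that("knockout zeroes the named constants and nothing else", {
  m <- build_network("full")
  expect_identical(apply_knockout(m, character(0)), m)
  m_ko <- apply_knockout(m, c("k_fb_f", "k_fb_b"))
  expect_identical(unname(m_ko$parameters$values[c("k_fb_f", "k_fb_b")]), c(0, 0))
  # feedback-complex formation flux is identically zero for any state
  set.seed(1)
  x <- runif(27, 0, 100)
  v <- reaction_rates(m_ko, x)
  j <- which(m_ko$reactions$tag == "feedback")
  expect_true(all(v[j] == 0))
  expect_error(apply_knockout(m, "no_such_constant"), "unknown")
})

test_that("parameter files round-trip and tolerate XPPAUT syntax", {
  p <- hsp90_parameters(k_stress = 0.9859)
  f <- tempfile(fileext = ".txt")
  write_parameter_file(p, f)
  p2 <- read_parameter_file(f)
  expect_equal(p2$values, p$values)
  expect_equal(p2$k_stress, 0.9859)
  # XPPAUT-style lines
  f2 <- tempfile(fileext = ".ode")
  writeLines(c("par k_k1_c=0.05, k_deact=0.02", "# comment",
               "par k_stress=1.5"), f2)
  p3 <- read_parameter_file(f2)
  expect_equal(p3$values[["k_k1_c"]], 0.05)
  expect_equal(p3$values[["k_deact"]], 0.02)
  expect_equal(p3$k_stress, 1.5)
  unlink(c(f, f2))
})

test_that("XPPAUT export emits parseable par and ode lines for all species", {
  m <- build_network("full")
  f <- tempfile(fileext = ".ode")
  export_xpp_ode(m, f)
  lines <- readLines(f)
  expect_identical(sum(grepl("^par ", lines)), 63L)  # 62 constants + k_stress
  expect_identical(sum(grepl("^d[A-Za-z0-9_]+/dt=", lines)), 27L)
  expect_identical(sum(grepl("^init ", lines)), 27L)
  expect_identical(lines[length(lines)], "done")
  unlink(f)
})

test_that("model report serializes species, reactions and stoichiometry", {
  m <- build_network("full")
  js <- model_report_json(m)
  rep <- jsonlite::fromJSON(js)
  expect_identical(nrow(rep$species), 27L)
  expect_identical(dim(rep$stoichiometric_matrix), c(27L, m$n_reactions))
})
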