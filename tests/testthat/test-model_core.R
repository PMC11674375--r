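test_that("reference model has the declared species inventory", {
  m <- ref_model_cached()
  expect_setequal(m$dynamic_ids,
                  c("DHAP", "Fru", "Fru1P", "Fru6P", "Fru16P2", "Fru26P2",
                    "GAP", "Glc", "Glc6P", "Lac", "Mal", "OA", "P", "PEP",
                    "13P2G", "23P2G", "2PG", "3PG", "PP", "Pyr", "Sorb"))
  clamped <- m$metabolites$id[m$metabolites$role == "clamped"]
  expect_false("ATP" %in% m$dynamic_ids)
  expect_true(all(c("NAD", "NADH", "ADP", "ATP") %in% clamped))
  expect_true(all(c("NAD", "NADH", "ADP", "ATP") %in% names(m$boundary)))
  # Rapoport-Luebering shunt present with the expected stoichiometry
  expect_equal(m$reactions$BPGM$stoich, c(`13P2G` = -1, `23P2G` = 1))
  expect_equal(m$reactions$BPG_PHOSPHATASE$stoich,
               c(`23P2G` = -1, `3PG` = 1, P = 1))
  # dimensions of S
  expect_equal(dim(stoich_matrix(m)), c(21L, length(m$reactions)))
})

test_that("missing parameters and broken invariants are configuration errors", {
  src <- system.file("extdata", "reference_model.json", package = "glycoren")
  doc <- jsonlite::read_json(src, simplifyVector = FALSE)
  i_hk <- which(vapply(doc$reactions, function(r) r$id, "") == "HK")
  doc$reactions[[i_hk]]$rate_law$km <- NULL
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(read_model_json(tmp), "HK")

  # parameters without units are rejected
  doc2 <- jsonlite::read_json(src, simplifyVector = FALSE)
  i <- which(vapply(doc2$reactions, function(r) r$id, "") == "PGK")
  doc2$reactions[[i]]$rate_law$vmax$unit <- NULL
  tmp2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc2, tmp2, auto_unbox = TRUE, digits = NA)
  expect_error(read_model_json(tmp2), "PGK.*unit")

  # carbon imbalance is a validation error
  mets <- rbind(metabolite("A", role = "dynamic", carbon = 2, conc = 1),
                metabolite("B", role = "dynamic", carbon = 1, conc = 1),
                metabolite("X", role = "external", carbon = 2, conc = 1))
  bad <- list(reaction("IN", c(X = -1, A = 1),
                       rate_law("mass_action_irreversible", 1)),
              reaction("R1", c(A = -1, B = 1),
                       rate_law("mass_action_irreversible", 1)))
  expect_error(kinetic_model(mets, bad), "carbon-balanced")

  # Haldane violation: explicit vmax_reverse inconsistent with keq
  mets2 <- rbind(metabolite("A", role = "dynamic", carbon = 1, conc = 1),
                 metabolite("B", role = "dynamic", carbon = 1, conc = 1))
  rl <- rate_law("mass_action_reversible", vmax = 2, keq = 4, vmax_reverse = 0.7)
  expect_error(kinetic_model(mets2, list(reaction("R", c(A = -1, B = 1), rl))),
               "Haldane")
})

test_that("reaction_rate matches direct evaluation of the closed-form laws", {
  # reversible Michaelis-Menten, hand-evaluated oracle
  r <- reaction("R", c(S = -1, P = 1),
                rate_law("michaelis_menten_reversible", vmax = 2,
                         km = c(S = 0.5, P = 1.5), keq = 4))
  S <- 0.8; P <- 1.2
  vr <- 2 * 1.5 / (4 * 0.5)
  expected <- (2 * (S / 0.5) - vr * (P / 1.5)) /
    ((1 + S / 0.5) + (1 + P / 1.5) - 1)
  expect_equal(reaction_rate(r, c(S = S, P = P)), expected, tolerance = 1e-14)

  # irreversible MM with zero substrate
  r2 <- reaction("R2", c(S = -1, P = 1),
                 rate_law("michaelis_menten_irreversible", vmax = 3, km = c(S = 0.2)))
  expect_identical(reaction_rate(r2, c(S = 0, P = 5)), 0)

  # reversible mass action at its equilibrium ratio is exactly zero
  r3 <- reaction("R3", c(A = -1, B = 1),
                 rate_law("mass_action_reversible", vmax = 1.7, keq = 2))
  expect_identical(reaction_rate(r3, c(A = 1, B = 2)), 0)

  # transporter is zero at equal concentrations on both sides
  r4 <- reaction("T", c(Out = -1, In = 1),
                 rate_law("transporter_facilitated", vmax = 5, km = c(In = 2)))
  expect_identical(reaction_rate(r4, c(In = 1.3), c(Out = 1.3)), 0)

  # unresolvable reference errors
  expect_error(reaction_rate(r2, c(P = 1)), "unresolvable")
})

test_that("competitive inhibition strictly decreases rate magnitude", {
  base <- reaction("R", c(S = -1, P = 1),
                   rate_law("michaelis_menten_irreversible", vmax = 3, km = c(S = 0.2)))
  inh <- reaction("R", c(S = -1, P = 1),
                  rate_law("michaelis_menten_irreversible", vmax = 3, km = c(S = 0.2),
                           modifiers = list(rate_modifier("I", "competitive_inhibitor", 0.5))))
  v0 <- reaction_rate(base, c(S = 1, P = 0))
  prev <- v0
  for (conc in c(0.01, 0.1, 1, 10)) {
    v <- reaction_rate(inh, c(S = 1, P = 0, I = conc))
    expect_lt(v, prev)
    prev <- v
  }
  # competitive term preserves the equilibrium zero of reversible laws
  rev_inh <- reaction("R", c(A = -1, B = 1),
                      rate_law("michaelis_menten_reversible", vmax = 2,
                               km = c(A = 0.5, B = 1.5), keq = 4,
                               modifiers = list(rate_modifier("I", "competitive_inhibitor", 0.3))))
  expect_equal(reaction_rate(rev_inh, c(A = 0.5, B = 2, I = 2)), 0, tolerance = 1e-15)
})

test_that("rhs is S %*% v and flags non-finite rates", {
  toy <- generate_toy_chain(1, 2, 4)
  # single irreversible reaction bookkeeping: dX1 = k0 - k1*x1, dX2 = k1*x1 - k2*x2
  x <- c(X1 = 0.3, X2 = 0.1)
  f <- model_rhs(toy, x)
  expect_equal(unname(f), c(1 - 2 * 0.3, 2 * 0.3 - 4 * 0.1))
  # toy chain at its analytic steady state
  ss <- c(X1 = 1 / 2, X2 = 1 / 4)
  expect_lt(max(abs(model_rhs(toy, ss))), 1e-10)
  # all vmax zero -> zero vector
  dead <- scale_vmax(toy, c(UPTAKE = 0, CONV = 0, EXPORT = 0))
  expect_identical(unname(model_rhs(dead, x)), c(0, 0))
})

test_that("stoichiometric linearity: rates are proportional to vmax", {
  m <- ref_model_cached()
  all1 <- stats::setNames(rep(1, length(m$reactions)), names(m$reactions))
  set.seed(11)
  for (i in 1:5) {
    x <- stats::runif(21, 0.001, 2)
    cc <- c(0.5, 2, 10)[(i %% 3) + 1]
    scaled <- scale_vmax(m, all1 * cc)
    expect_equal(model_rhs(scaled, x), cc * model_rhs(m, x), tolerance = 1e-12)
  }
})

test_that("every reversible reference rate law vanishes at its equilibrium", {
  m <- ref_model_cached()
  for (r in m$reactions) {
    rl <- r$rate_law
    if (!rl$form %in% c("michaelis_menten_reversible", "mass_action_reversible")) next
    st <- r$stoich
    subs <- names(st)[st < 0]; prods <- names(st)[st > 0]
    if (rl$form == "michaelis_menten_reversible") {
      subs <- intersect(subs, names(rl$km)); prods <- intersect(prods, names(rl$km))
    }
    pool <- stats::setNames(rep(1, length(c(subs, prods))), c(subs, prods))
    # scale one product so the mass-action ratio equals keq
    gamma <- prod(pool[prods]^st[prods]) * prod(pool[subs]^st[subs])
    pool[prods[1]] <- pool[prods[1]] * (rl$keq / gamma)^(1 / st[prods[1]])
    mods <- vapply(rl$modifiers, function(mm) mm$met, "")
    pool <- c(pool, stats::setNames(rep(0.5, length(setdiff(mods, names(pool)))),
                                    setdiff(mods, names(pool))))
    expect_equal(reaction_rate(r, pool), 0, tolerance = 1e-12 * rl$vmax,
                 label = paste0("equilibrium rate of ", r$id))
  }
})

test_that("HK flux is strictly decreasing in 2,3-BPG when the coupling is on", {
  m <- ref_model_cached()
  hk <- m$reactions$HK
  state <- c(Glc = 2, Glc6P = 0.1, `23P2G` = 0)
  clamps <- c(ATP = 2.5, ADP = 0.25)
  prev <- Inf
  for (b in c(0, 0.05, 0.2, 1, 5, 20)) {
    state["23P2G"] <- b
    v <- reaction_rate(hk, state, clamps)
    expect_lt(v, prev)
    prev <- v
  }
  # with the coupling disabled the dependence vanishes
  m_off <- build_reference_model(couplings = list(bpg_hk = FALSE, bpg_pgam = TRUE))
  hk_off <- m_off$reactions$HK
  v1 <- reaction_rate(hk_off, c(Glc = 2, Glc6P = 0.1, `23P2G` = 0), clamps)
  v2 <- reaction_rate(hk_off, c(Glc = 2, Glc6P = 0.1, `23P2G` = 20), clamps)
  expect_identical(v1, v2)
})

test_that("carbon balance residual does boundary bookkeeping", {
  toy <- generate_toy_chain(1, 2, 4)
  # zero fluxes -> zero residual
  expect_identical(carbon_balance_residual(toy, c(UPTAKE = 0, CONV = 0, EXPORT = 0)), 0)
  # at steady state, in = out
  ss <- integrate_to_steady_state(toy)
  expect_lt(abs(carbon_balance_residual(toy, ss$fluxes)), 1e-12)
  # deliberately mis-balanced export (sink species declared with 2 carbons):
  # residual at the same fluxes reports the introduced imbalance, -k0
  mets <- toy$metabolites
  mets$carbon[mets$id == "Snk"] <- 2
  broken <- kinetic_model(mets, toy$reactions, exchange = toy$exchange,
                          validate = FALSE)
  expect_equal(carbon_balance_residual(broken, ss$fluxes), -1, tolerance = 1e-9)
})

test_that("model invariants are enforced at build time", {
  mets <- rbind(metabolite("A", role = "dynamic", carbon = 1, conc = 1),
                metabolite("Orphan", role = "dynamic", carbon = 1, conc = 1),
                metabolite("X", role = "external", carbon = 1, conc = 1))
  rxns <- list(reaction("IN", c(X = -1, A = 1), rate_law("mass_action_irreversible", 1)))
  expect_error(kinetic_model(mets, rxns), "Orphan")
  expect_error(reaction("BAD", c(A = -1, B = -1), rate_law("mass_action_irreversible", 1)),
               "positive")
  expect_error(metabolite("A", role = "dynamic", carbon = 1, conc = 0), "> 0")
  expect_error(rate_law("michaelis_menten_irreversible", vmax = 1, km = c(S = -1)),
               "Km")
})
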