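test_that("isoform intensities are summed into reaction abundances", {
  tab <- tiny_table()
  map <- enzyme_map(list(HK = c("Hk1", "Hk2"), GAPDH = "Gapdh", PFK1 = "Pfk"))
  ab <- aggregate_isoforms(tab, map)
  # hand summation over the 3x3 toy table
  expect_equal(ab["HK", ], c(c1 = 14, c2 = 11, k1 = 9))
  expect_equal(ab["GAPDH", ], c(c1 = 100, c2 = 100, k1 = 100))
  measured <- attr(ab, "measured")
  expect_true(measured[["HK"]])
  expect_false(measured[["PFK1"]])  # no mapped gene present -> flagged, not failed
})

test_that("gene symbols match case-insensitively with a logged fold", {
  m <- matrix(c(4, 6, 2), nrow = 1, dimnames = list("BPGM", c("c1", "c2", "k1")))
  tab <- proteomics_table(m, c(c1 = "control", c2 = "control", k1 = "KO"))
  expect_message(ab <- aggregate_isoforms(tab, enzyme_map(list(BPGM = "Bpgm"))),
                 "case-folded")
  expect_equal(unname(ab["BPGM", ]), c(4, 6, 2))
})

test_that("scaling factors implement the abundance-ratio law", {
  # controls {4, 6}, KO 2 -> control mean 5, KO factor 0.4
  m <- matrix(c(4, 6, 2), nrow = 1, dimnames = list("Bpgm", c("c1", "c2", "k1")))
  tab <- proteomics_table(m, c(c1 = "control", c2 = "control", k1 = "KO"))
  sf <- compute_scaling_factors(tab, enzyme_map(list(BPGM = "Bpgm")))
  expect_equal(unname(sf$factors["BPGM", ]), c(4 / 5, 6 / 5, 0.4))
  expect_identical(unname(sf$e_mean_control[["BPGM"]]), 5)
  # a sample exactly at the control mean has factor exactly 1
  m2 <- matrix(c(5, 5, 10), nrow = 1, dimnames = list("Hk1", c("c1", "c2", "k1")))
  tab2 <- proteomics_table(m2, c(c1 = "control", c2 = "control", k1 = "KO"))
  sf2 <- compute_scaling_factors(tab2, enzyme_map(list(HK = "Hk1")))
  expect_identical(unname(sf2$factors["HK", c("c1", "c2")]), c(1, 1))
  # doubling abundance doubles the factor
  expect_identical(unname(sf2$factors["HK", "k1"]), 2)
})

test_that("unmeasured and zero-control reactions get factor 1 with provenance", {
  m <- matrix(c(0, 0, 3, 1, 2, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("Zero", "Ok"), c("c1", "c2", "k1")))
  tab <- proteomics_table(m, c(c1 = "control", c2 = "control", k1 = "KO"))
  map <- enzyme_map(list(R_ZERO = "Zero", R_OK = "Ok", R_ABSENT = "NotThere"))
  expect_warning(sf <- compute_scaling_factors(tab, map), "zero")
  expect_identical(unname(sf$provenance[c("R_ZERO", "R_ABSENT")]),
                   rep("default_unmeasured", 2))
  expect_identical(unname(sf$provenance[["R_OK"]]), "measured")
  expect_true(all(sf$factors["R_ZERO", ] == 1))
  expect_true(all(sf$factors["R_ABSENT", ] == 1))
})

test_that("zero-noise synthetic tables recover fold changes bitwise", {
  fcs <- c(Bpgm = 0.05, Hk1 = 2, Ldha = 0.25)
  spec <- synth_spec(baseline = c(Bpgm = 2e6, Hk1 = 5e5, Ldha = 1e7, Gapdh = 3e7),
                     n_control = 6, n_ko = 6, fold_changes = fcs,
                     noise_sigma = 0, seed = 3)
  tab <- generate_proteomics(spec)
  map <- enzyme_map(list(BPGM = "Bpgm", HK = "Hk1", LDH = "Ldha", GAPDH = "Gapdh"))
  sf <- compute_scaling_factors(tab, map)
  for (s in paste0("KO_", 1:6)) {
    expect_identical(unname(sf$factors["BPGM", s]), 0.05)
    expect_identical(unname(sf$factors["HK", s]), 2)
    expect_identical(unname(sf$factors["LDH", s]), 0.25)
    expect_identical(unname(sf$factors["GAPDH", s]), 1)
  }
  expect_true(all(sf$factors[, paste0("control_", 1:6)] == 1))
})

test_that("factor clipping is optional, logged and bounded", {
  m <- matrix(c(1, 1, 1000), nrow = 1, dimnames = list("Hk1", c("c1", "c2", "k1")))
  tab <- proteomics_table(m, c(c1 = "control", c2 = "control", k1 = "KO"))
  map <- enzyme_map(list(HK = "Hk1"))
  sf <- compute_scaling_factors(tab, map)
  expect_equal(unname(sf$factors["HK", "k1"]), 1000)
  expect_message(sfc <- compute_scaling_factors(tab, map, clip = c(0.01, 100)),
                 "clipping")
  expect_equal(unname(sfc$factors["HK", "k1"]), 100)
})

test_that("instantiation scales vmax non-destructively and preserves Keq", {
  tg <- toy_glyco_model()
  groups <- c(a = "control", b = "KO")
  sf <- uniform_factors(tg, c(a = 1, b = 2), groups)
  m1 <- instantiate_sample_model(tg, sf, "a")
  ss_base <- integrate_to_steady_state(tg)
  ss1 <- integrate_to_steady_state(m1)
  expect_equal(ss1$fluxes, ss_base$fluxes, tolerance = 1e-9)
  m2 <- instantiate_sample_model(tg, sf, "b")
  ss2 <- integrate_to_steady_state(m2)
  expect_equal(ss2$fluxes, 2 * ss_base$fluxes, tolerance = 1e-6)
  expect_equal(ss2$concentrations, ss_base$concentrations, tolerance = 1e-6)
  # the base model object is untouched
  expect_identical(tg$reactions$UPTAKE$rate_law$vmax, 2)
  # Keq of reversible reactions survives instantiation
  ref <- ref_model_cached()
  sfr <- uniform_factors(ref, c(a = 3), c(a = "control"))
  ref3 <- instantiate_sample_model(ref, sfr, "a")
  for (id in names(ref$reactions)) {
    expect_identical(ref3$reactions[[id]]$rate_law$keq, ref$reactions[[id]]$rate_law$keq)
  }
  # errors: unknown sample, nonpositive factor outside hard-KO mode
  expect_error(instantiate_sample_model(tg, sf, "zz"), "unknown sample")
  sf_bad <- uniform_factors(tg, c(a = 0), c(a = "KO"))
  expect_error(instantiate_sample_model(tg, sf_bad, "a"), "hard-KO")
})

test_that("hard knockout of BPGM silences the shunt", {
  ref <- ref_model_cached()
  groups <- c(ctrl = "control", ko = "KO")
  sf <- hard_ko(uniform_factors(ref, c(ctrl = 1, ko = 1), groups))
  expect_true(attr(sf, "hard_ko"))
  expect_identical(unname(sf$factors["BPGM", "ko"]), 0)
  ko_model <- instantiate_sample_model(ref, sf, "ko")
  ss <- integrate_to_steady_state(ko_model)
  expect_true(ss$converged)
  expect_identical(unname(ss$fluxes[["BPGM"]]), 0)
  # with production dead, 2,3-BPG decays to the phosphatase-drained floor
  expect_lt(ss$concentrations[["23P2G"]], 1e-6)
})
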