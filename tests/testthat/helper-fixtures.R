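# Shared fixtures, all built in code at test time.

# reference model built once per test run (cheap, but no need to repeat)
ref_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_reference_model()
    m
  }
})

# Minimal saturable-entry "glycolysis" toy exposing the Glc/Lac exchange
# interface expected by glucose_sweep: facilitated glucose entry, lumped
# conversion Glc -> 2 Lac, lactate export. Linear in its mass-action part, so
# uniform vmax scaling shifts fluxes exactly proportionally.
toy_glyco_model <- function(v_up = 2, km_up = 5, k_conv = 1, k_exp = 2,
                            lac_ext = 0.5) {
  mets <- rbind(
    metabolite("Glc", role = "dynamic", carbon = 6, conc = 0.5),
    metabolite("Lac", role = "dynamic", carbon = 3, conc = 0.5),
    metabolite("Glc_ext", role = "external", carbon = 6, conc = 5),
    metabolite("Lac_ext", role = "external", carbon = 3, conc = lac_ext)
  )
  rxns <- list(
    reaction("UPTAKE", c(Glc_ext = -1, Glc = 1),
             rate_law("michaelis_menten_irreversible", vmax = v_up,
                      km = c(Glc_ext = km_up))),
    reaction("CONV", c(Glc = -1, Lac = 2),
             rate_law("mass_action_irreversible", vmax = k_conv)),
    reaction("EXPORT", c(Lac = -1, Lac_ext = 1),
             rate_law("mass_action_irreversible", vmax = k_exp))
  )
  ex <- data.frame(species = c("Glc", "Lac"),
                   reaction = c("UPTAKE", "EXPORT"),
                   positive = c("uptake", "release"),
                   stringsAsFactors = FALSE)
  kinetic_model(mets, rxns, exchange = ex, name = "toy_glyco")
}

# tiny proteomics table: 3 genes x (2 control + 1 KO)
tiny_table <- function(vals = NULL) {
  m <- matrix(c(10, 4, 100,
                5, 6, 100,
                7, 2, 100), nrow = 3,
              dimnames = list(c("Hk1", "Hk2", "Gapdh"),
                              c("c1", "c2", "k1")))
  if (!is.null(vals)) m <- vals
  proteomics_table(m, c(c1 = "control", c2 = "control", k1 = "KO"))
}

# uniform-factor scaling_factors object over a model's reactions, for
# constructing ensembles with exactly known per-sample flux scalings
uniform_factors <- function(model, sample_scales, groups) {
  rxns <- names(model$reactions)
  f <- vapply(sample_scales, function(s) rep(s, length(rxns)), numeric(length(rxns)))
  rownames(f) <- rxns
  structure(list(factors = f,
                 e_mean_control = stats::setNames(rep(1, length(rxns)), rxns),
                 provenance = stats::setNames(rep("measured", length(rxns)), rxns),
                 groups = groups),
            class = "scaling_factors")
}
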