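#' Construct a metabolite record
#'
#' @param id short symbol (e.g. `"Glc6P"`, `"23P2G"`); unique within a model.
#' @param name full name.
#' @param role `"dynamic"` (integrated), `"clamped"` (cofactor held fixed) or
#'   `"external"` (boundary species held fixed, may carry exchange flux).
#' @param carbon nonnegative integer; number of tracked skeleton carbons.
#'   Nucleotide/phosphate cofactors carry 0 (only the glucose-derived skeleton
#'   is book-kept).
#' @param conc concentration in mM: initial value for dynamic species
#'   (strictly positive), fixed value for clamped/external species.
#' @return one-row data.frame.
#' @export
metabolite <- function(id, name = id, role = c("dynamic", "clamped", "external"),
                       carbon = 0, conc) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(carbon) || carbon < 0 || carbon != round(carbon)) {
    stop("carbon count of '", id, "' must be a nonnegative integer")
  }
  if (!is.numeric(conc) || !is.finite(conc) || conc < 0) {
    stop("concentration of '", id, "' must be finite and >= 0")
  }
  if (role == "dynamic" && conc <= 0) {
    stop("initial concentration of dynamic metabolite '", id, "' must be > 0")
  }
  data.frame(id = id, name = name, role = role, carbon = as.numeric(carbon),
             conc = as.numeric(conc), stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' @param id short reaction name (e.g. `"HK"`, `"BPGM"`).
#' @param stoich named numeric vector, metabolite id -> signed stoichiometric
#'   coefficient (negative = consumed). Must contain at least one negative and
#'   one positive entry.
#' @param rate_law a [rate_law()] object.
#' @param genes character vector of gene symbols mapped to this activity
#'   (may be empty for non-enzymatic steps).
#' @return a `reaction` list.
#' @export
reaction <- function(id, stoich, rate_law, genes = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoich) || is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("reaction '", id, "': stoich must be a named numeric vector")
  }
  if (anyDuplicated(names(stoich))) stop("reaction '", id, "': duplicated species in stoich")
  if (!any(stoich < 0) || !any(stoich > 0)) {
    stop("reaction '", id, "': stoichiometry needs at least one negative and one positive entry")
  }
  if (!inherits(rate_law, "rate_law")) stop("reaction '", id, "': rate_law must be a rate_law object")
  structure(list(id = id, stoich = stoich, rate_law = rate_law,
                 genes = as.character(genes)),
            class = "reaction")
}

#' Assemble a kinetic model
#'
#' Builds the stoichiometric matrix over dynamic species, validates the network
#' (unique ids, resolvable references, per-reaction carbon balance, Haldane
#' consistency, participation of every dynamic species) and compiles an
#' index-based evaluation plan for fast rate computation.
#'
#' @param metabolites data.frame with columns id, name, role, carbon, conc
#'   (rbind of [metabolite()] rows).
#' @param reactions list of [reaction()] objects.
#' @param exchange data.frame describing boundary exchanges with columns
#'   `species` (dynamic metabolite id), `reaction` (the carrier reaction id) and
#'   `positive` (`"uptake"` or `"release"`): the sign convention under which the
#'   reported exchange flux is positive. Must cover at least Glc and Lac for the
#'   reference model.
#' @param name model name.
#' @param validate if `FALSE`, skip carbon-balance and participation checks
#'   (used to construct deliberately defective models in tests).
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(metabolites, reactions, exchange = NULL,
                          name = "model", validate = TRUE) {
  stopifnot(is.data.frame(metabolites))
  need <- c("id", "name", "role", "carbon", "conc")
  if (!all(need %in% names(metabolites))) {
    stop("metabolites data.frame must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(metabolites$id)) stop("metabolite ids must be unique")
  if (!length(reactions)) stop("model needs at least one reaction")
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxn_ids)) stop("reaction ids must be unique")
  names(reactions) <- rxn_ids

  dyn <- metabolites$id[metabolites$role == "dynamic"]
  bnd <- metabolites$id[metabolites$role != "dynamic"]
  all_ids <- c(dyn, bnd)
  carbon <- stats::setNames(metabolites$carbon, metabolites$id)[all_ids]
  boundary <- stats::setNames(metabolites$conc, metabolites$id)[bnd]
  x0 <- stats::setNames(metabolites$conc, metabolites$id)[dyn]

  # stoichiometric matrix over dynamic species
  S <- matrix(0, nrow = length(dyn), ncol = length(reactions),
              dimnames = list(dyn, rxn_ids))
  for (r in reactions) {
    unknown <- setdiff(names(r$stoich), all_ids)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references unknown species: ",
           paste(unknown, collapse = ", "))
    }
    kmet <- names(r$rate_law$km)
    bad_km <- setdiff(kmet, names(r$stoich))
    if (length(bad_km)) {
      stop("reaction '", r$id, "': Km given for non-participant ",
           paste(bad_km, collapse = ", "))
    }
    for (m in r$rate_law$modifiers) {
      if (!(m$met %in% all_ids)) {
        stop("reaction '", r$id, "': modifier references unknown species '", m$met, "'")
      }
    }
    d <- intersect(names(r$stoich), dyn)
    S[d, r$id] <- r$stoich[d]
  }

  if (validate) {
    orphans <- dyn[rowSums(S != 0) == 0]
    if (length(orphans)) {
      stop("dynamic metabolites not participating in any reaction: ",
           paste(orphans, collapse = ", "))
    }
    for (r in reactions) {
      imbalance <- sum(r$stoich * carbon[names(r$stoich)])
      if (abs(imbalance) > 1e-9) {
        stop("reaction '", r$id, "' is not carbon-balanced (imbalance ",
             format(imbalance), " carbons per turnover)")
      }
    }
  }

  if (!is.null(exchange)) {
    stopifnot(is.data.frame(exchange),
              all(c("species", "reaction", "positive") %in% names(exchange)))
    if (!all(exchange$reaction %in% rxn_ids)) stop("exchange references unknown reaction")
    if (!all(exchange$positive %in% c("uptake", "release"))) {
      stop("exchange$positive must be 'uptake' or 'release'")
    }
  }

  model <- structure(
    list(name = name, metabolites = metabolites, reactions = reactions,
         dynamic_ids = dyn, boundary = boundary, carbon = carbon,
         x0 = x0, S = S, exchange = exchange),
    class = "kinetic_model"
  )
  model$compiled <- compile_model(model)
  model
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", x$name, "\n", sep = "")
  cat("  dynamic species : ", length(x$dynamic_ids), "\n", sep = "")
  cat("  boundary species: ", length(x$boundary), "\n", sep = "")
  cat("  reactions       : ", length(x$reactions), "\n", sep = "")
  if (!is.null(x$exchange)) {
    cat("  exchanges       : ", paste(x$exchange$species, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# ---- compilation ------------------------------------------------------------

# Index-based evaluation plan: the full concentration vector is
# c(state[dynamic_ids], boundary); each reaction stores integer indices into it.
#' @keywords internal
compile_model <- function(model) {
  all_ids <- c(model$dynamic_ids, names(model$boundary))
  idx <- stats::setNames(seq_along(all_ids), all_ids)
  lapply(model$reactions, function(r) compile_reaction(r, idx))
}

#' @keywords internal
compile_reaction <- function(r, idx) {
  rl <- r$rate_law
  st <- r$stoich
  subs <- names(st)[st < 0]
  prods <- names(st)[st > 0]
  form <- rl$form

  cr <- list(id = r$id, form = form, vmax = rl$vmax)

  if (form %in% c("mass_action_irreversible", "mass_action_reversible")) {
    cr$sub_idx <- unname(idx[subs]); cr$sub_n <- unname(abs(st[subs]))
    if (form == "mass_action_reversible") {
      cr$prod_idx <- unname(idx[prods]); cr$prod_n <- unname(st[prods])
      vr <- rl$vmax_reverse
      vr_derived <- if (!is.null(rl$keq)) rl$vmax / rl$keq else NULL
      cr$vmax_reverse <- haldane_pick(r$id, vr, vr_derived)
    }
  } else if (form == "michaelis_menten_irreversible") {
    ks <- intersect(subs, names(rl$km))
    if (!length(ks)) stop("reaction '", r$id, "': no substrate Km supplied")
    cr$sub_idx <- unname(idx[ks]); cr$sub_km <- unname(rl$km[ks])
    cr$sub_n <- unname(abs(st[ks]))
  } else if (form == "michaelis_menten_reversible") {
    ks <- intersect(subs, names(rl$km)); kp <- intersect(prods, names(rl$km))
    if (!length(ks) || !length(kp)) {
      stop("reaction '", r$id, "': reversible MM needs Km on both sides")
    }
    cr$sub_idx <- unname(idx[ks]); cr$sub_km <- unname(rl$km[ks])
    cr$sub_n <- unname(abs(st[ks]))
    cr$prod_idx <- unname(idx[kp]); cr$prod_km <- unname(rl$km[kp])
    cr$prod_n <- unname(st[kp])
    vr_derived <- if (!is.null(rl$keq)) {
      rl$vmax * prod(cr$prod_km^cr$prod_n) / (rl$keq * prod(cr$sub_km^cr$sub_n))
    } else NULL
    cr$vmax_reverse <- haldane_pick(r$id, rl$vmax_reverse, vr_derived)
  } else if (form == "transporter_facilitated") {
    if (length(subs) != 1L || length(prods) != 1L) {
      stop("reaction '", r$id, "': transporter needs exactly one species per side")
    }
    km <- rl$km
    kmv <- if (length(km) == 1L) unname(km) else {
      if (length(unique(km)) != 1L) {
        stop("reaction '", r$id, "': transporter Km must be a single shared value")
      }
      unname(km[1L])
    }
    cr$sub_idx <- unname(idx[subs]); cr$prod_idx <- unname(idx[prods])
    cr$km <- kmv
  }

  mods <- rl$modifiers
  if (length(mods)) {
    cr$mod_idx <- vapply(mods, function(m) unname(idx[m$met]), numeric(1))
    cr$mod_kind <- vapply(mods, function(m) match(m$kind, MODIFIER_KINDS), numeric(1))
    cr$mod_k <- vapply(mods, function(m) m$k, numeric(1))
    cr$mod_hill <- vapply(mods, function(m) m$hill, numeric(1))
    cr$mod_basal <- vapply(mods, function(m) m$basal, numeric(1))
  }
  cr
}

# both given -> validate Haldane at 1e-6 relative, keep the explicit value;
# never silently renormalize.
#' @keywords internal
haldane_pick <- function(id, vr, vr_derived) {
  if (!is.null(vr) && !is.null(vr_derived)) {
    if (abs(vr - vr_derived) > 1e-6 * max(vr_derived, .Machine$double.xmin)) {
      stop("reaction '", id, "': vmax_reverse and keq violate the Haldane relation ",
           "(given ", format(vr), ", implied ", format(vr_derived), ")")
    }
    return(vr)
  }
  if (!is.null(vr_derived)) return(vr_derived)
  if (!is.null(vr)) return(vr)
  stop("reaction '", id, "': reversible form lacks keq/vmax_reverse")
}

# ---- rate evaluation --------------------------------------------------------

#' @keywords internal
eval_compiled_rate <- function(cr, x) {
  den_extra <- 0
  fac <- 1
  if (!is.null(cr$mod_idx)) {
    for (j in seq_along(cr$mod_idx)) {
      term <- (x[cr$mod_idx[j]] / cr$mod_k[j])^cr$mod_hill[j]
      kind <- cr$mod_kind[j]
      if (kind == 1L) {          # competitive_inhibitor
        den_extra <- den_extra + term
      } else if (kind == 2L) {   # allosteric_inhibitor
        fac <- fac / (1 + term)
      } else {                   # allosteric_activator
        fac <- fac * (cr$mod_basal + term) / (1 + term)
      }
    }
  }
  v <- switch(cr$form,
    mass_action_irreversible = {
      cr$vmax * prod(x[cr$sub_idx]^cr$sub_n) / (1 + den_extra)
    },
    mass_action_reversible = {
      (cr$vmax * prod(x[cr$sub_idx]^cr$sub_n) -
         cr$vmax_reverse * prod(x[cr$prod_idx]^cr$prod_n)) / (1 + den_extra)
    },
    michaelis_menten_irreversible = {
      s <- x[cr$sub_idx] / cr$sub_km
      cr$vmax * prod(s^cr$sub_n) /
        (prod((1 + s)^cr$sub_n) + den_extra)
    },
    michaelis_menten_reversible = {
      s <- x[cr$sub_idx] / cr$sub_km
      p <- x[cr$prod_idx] / cr$prod_km
      (cr$vmax * prod(s^cr$sub_n) - cr$vmax_reverse * prod(p^cr$prod_n)) /
        (prod((1 + s)^cr$sub_n) + prod((1 + p)^cr$prod_n) - 1 + den_extra)
    },
    transporter_facilitated = {
      s <- x[cr$sub_idx] / cr$km
      p <- x[cr$prod_idx] / cr$km
      cr$vmax * (s - p) / (1 + s + p + den_extra)
    }
  )
  fac * v
}

#' Evaluate all reaction rates of a model at a state
#'
#' @param model a [kinetic_model()].
#' @param state named (or model-ordered) numeric vector of dynamic
#'   concentrations in mM.
#' @return named numeric vector of fluxes (mM/min), one per reaction.
#' @export
reaction_rates <- function(model, state) {
  x <- c(order_state(model, state), model$boundary)
  v <- vapply(model$compiled, eval_compiled_rate, numeric(1), x = x)
  names(v) <- names(model$reactions)
  v
}

#' Evaluate a single reaction rate
#'
#' Standalone evaluation of one reaction's rate law from named concentration
#' vectors, independent of a compiled model.
#'
#' @param reaction a [reaction()].
#' @param state named numeric vector of dynamic concentrations (mM).
#' @param clamps named numeric vector of clamped/external concentrations (mM).
#' @return flux in mM/min.
#' @export
reaction_rate <- function(reaction, state, clamps = numeric()) {
  refs <- unique(c(names(reaction$stoich),
                   vapply(reaction$rate_law$modifiers, function(m) m$met, character(1))))
  pool <- c(state, clamps)
  missing <- setdiff(refs, names(pool))
  if (length(missing)) {
    stop("reaction '", reaction$id, "': unresolvable metabolite reference: ",
         paste(missing, collapse = ", "))
  }
  idx <- stats::setNames(seq_along(pool), names(pool))
  cr <- compile_reaction(reaction, idx)
  eval_compiled_rate(cr, unname(pool))
}

#' @keywords internal
order_state <- function(model, state) {
  n <- length(model$dynamic_ids)
  if (is.null(names(state))) {
    if (length(state) != n) stop("state length does not match dynamic species count")
    return(as.numeric(state))
  }
  missing <- setdiff(model$dynamic_ids, names(state))
  if (length(missing)) {
    stop("state is missing dynamic species: ", paste(missing, collapse = ", "))
  }
  as.numeric(state[model$dynamic_ids])
}

#' ODE right-hand side
#'
#' Time derivative of every dynamic metabolite, `S %*% v` with `v` the vector
#' of reaction rates at `state`.
#'
#' @inheritParams reaction_rates
#' @return named numeric vector, mM/min per dynamic species.
#' @export
model_rhs <- function(model, state) {
  v <- reaction_rates(model, state)
  if (any(!is.finite(v))) {
    bad <- names(v)[!is.finite(v)][1L]
    stop("non-finite rate in reaction '", bad, "'")
  }
  drop(model$S %*% v)
}

#' Stoichiometric matrix
#'
#' @param model a [kinetic_model()].
#' @return matrix, dynamic species x reactions.
#' @export
stoich_matrix <- function(model) model$S

#' Net boundary carbon balance residual
#'
#' Net rate at which tracked skeleton carbon enters the dynamic pool across the
#' system boundary (carbon entering via uptake minus carbon leaving via
#' release), in mM carbon/min. For a per-reaction carbon-balanced model this
#' equals the rate of change of total dynamic carbon, hence vanishes at any
#' steady state; for a deliberately mis-balanced boundary reaction carrying
#' unit flux it reports the introduced imbalance.
#'
#' @param model a [kinetic_model()].
#' @param fluxes numeric vector of reaction fluxes, ordered/named as
#'   `model$reactions`.
#' @return scalar, mM carbon/min.
#' @export
carbon_balance_residual <- function(model, fluxes) {
  if (!is.null(names(fluxes))) fluxes <- fluxes[names(model$reactions)]
  if (length(fluxes) != length(model$reactions)) {
    stop("fluxes must have one entry per reaction")
  }
  bnd <- names(model$boundary)
  total <- 0
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    b <- intersect(names(st), bnd)
    if (length(b)) {
      # carbon leaving the boundary pool = carbon entering the dynamic pool
      total <- total - sum(st[b] * model$carbon[b]) * fluxes[j]
    }
  }
  unname(total)
}

#' Set a boundary (clamped/external) concentration
#'
#' @param model a [kinetic_model()].
#' @param species boundary species id.
#' @param value new concentration (mM, >= 0).
#' @return modified model.
#' @export
set_boundary <- function(model, species, value) {
  if (!(species %in% names(model$boundary))) {
    stop("'", species, "' is not a boundary species of this model")
  }
  if (!is.finite(value) || value < 0) stop("boundary concentration must be finite and >= 0")
  model$boundary[[species]] <- as.numeric(value)
  model$metabolites$conc[model$metabolites$id == species] <- as.numeric(value)
  model
}

#' Scale maximal activities of selected reactions
#'
#' Multiplies forward (and explicit reverse) maximal rates by per-reaction
#' factors; equilibrium constants are untouched, so reverse rates derived via
#' the Haldane relation scale along with the forward rate and Keq is preserved.
#'
#' @param model a [kinetic_model()].
#' @param factors named numeric vector, reaction id -> factor (>= 0).
#' @return modified model (the input model is not changed).
#' @export
scale_vmax <- function(model, factors) {
  if (is.null(names(factors))) stop("factors must be named by reaction id")
  unknown <- setdiff(names(factors), names(model$reactions))
  if (length(unknown)) stop("unknown reactions in factors: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(factors) | factors < 0)) stop("vmax factors must be finite and >= 0")
  for (id in names(factors)) {
    rl <- model$reactions[[id]]$rate_law
    rl$vmax <- rl$vmax * factors[[id]]
    if (!is.null(rl$vmax_reverse)) rl$vmax_reverse <- rl$vmax_reverse * factors[[id]]
    model$reactions[[id]]$rate_law <- rl
  }
  model$compiled <- compile_model(model)
  model
}
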