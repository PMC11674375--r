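# Structured-text model definition (JSON) and the reference network.

#' @keywords internal
param_value <- function(obj, what, rxn_id) {
  if (is.null(obj)) {
    stop("configuration error in reaction '", rxn_id, "': missing parameter '", what, "'")
  }
  if (is.null(obj$value) || is.null(obj$unit) || !nzchar(obj$unit)) {
    stop("configuration error in reaction '", rxn_id, "': parameter '", what,
         "' must carry explicit 'value' and 'unit' fields")
  }
  as.numeric(obj$value)
}

#' @keywords internal
parse_km <- function(km_obj, rxn_id) {
  if (is.null(km_obj) || !length(km_obj)) return(NULL)
  vals <- vapply(names(km_obj), function(m) {
    v <- param_value(km_obj[[m]], paste0("km[", m, "]"), rxn_id)
    u <- km_obj[[m]]$unit
    if (!identical(u, "mM")) {
      stop("configuration error in reaction '", rxn_id, "': Km of '", m,
           "' must be given in mM (got '", u, "')")
    }
    v
  }, numeric(1))
  stats::setNames(vals, names(km_obj))
}

#' @keywords internal
parse_reaction_json <- function(rx, couplings) {
  id <- rx$id
  if (is.null(id)) stop("configuration error: reaction without id")
  rl <- rx$rate_law
  if (is.null(rl) || is.null(rl$form)) {
    stop("configuration error in reaction '", id, "': missing rate_law/form")
  }
  mods <- list()
  for (m in rl$modifiers) {
    if (!is.null(m$toggle)) {
      on <- couplings[[m$toggle]]
      if (!is.null(on) && !isTRUE(on)) next
    }
    mods[[length(mods) + 1L]] <- rate_modifier(
      met = m$met, kind = m$kind,
      k = param_value(m$k, paste0("modifier[", m$met, "]"), id),
      hill = if (is.null(m$hill)) 1 else m$hill,
      basal = if (is.null(m$basal)) 0.1 else m$basal,
      toggle = m$toggle
    )
  }
  law <- tryCatch(
    rate_law(
      form = rl$form,
      vmax = param_value(rl$vmax, "vmax", id),
      km = parse_km(rl$km, id),
      keq = if (is.null(rl$keq)) NULL else param_value(rl$keq, "keq", id),
      vmax_reverse = if (is.null(rl$vmax_reverse)) NULL else param_value(rl$vmax_reverse, "vmax_reverse", id),
      modifiers = mods
    ),
    error = function(e) {
      stop("configuration error in reaction '", id, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  st <- unlist(rx$stoich)
  reaction(id = id, stoich = st, rate_law = law,
           genes = as.character(unlist(rx$genes)))
}

#' Read a kinetic model from a JSON definition
#'
#' The document lists metabolites (id, role, carbon count, concentration with
#' units), reactions (stoichiometry, rate-law form, parameters with explicit
#' units -- files without units are rejected) and the exchange table. Modifier
#' entries may name a `toggle`; the corresponding entry of `couplings` switches
#' them off (default: all couplings on).
#'
#' @param path path to the JSON model document.
#' @param couplings named list of logical switches for toggled modifiers, e.g.
#'   `list(bpg_hk = TRUE, bpg_pgam = FALSE)`.
#' @param validate passed to [kinetic_model()].
#' @return a [kinetic_model()].
#' @export
read_model_json <- function(path, couplings = list(), validate = TRUE) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("model document must contain 'metabolites' and 'reactions'")
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$unit) || !nzchar(m$unit)) {
      stop("metabolite '", m$id, "' lacks a concentration unit")
    }
    metabolite(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               role = m$role, carbon = if (is.null(m$carbon)) 0 else m$carbon,
               conc = m$conc)
  }))
  rxns <- lapply(doc$reactions, parse_reaction_json, couplings = couplings)
  ex <- NULL
  if (!is.null(doc$exchange)) {
    ex <- do.call(rbind, lapply(doc$exchange, function(e) {
      data.frame(species = e$species, reaction = e$reaction,
                 positive = e$positive, stringsAsFactors = FALSE)
    }))
  }
  kinetic_model(mets, rxns, exchange = ex,
                name = if (is.null(doc$name)) "model" else doc$name,
                validate = validate)
}

#' Serialize a kinetic model to JSON
#'
#' Writes the same schema [read_model_json()] consumes, at full numeric
#' precision, so that write-then-read reproduces the model.
#'
#' @param model a [kinetic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, role = m$role, carbon = m$carbon,
         conc = m$conc, unit = "mM")
  })
  rxns <- lapply(model$reactions, function(r) {
    rl <- r$rate_law
    out <- list(id = r$id, genes = as.list(r$genes),
                stoich = as.list(r$stoich),
                rate_law = list(form = rl$form,
                                vmax = list(value = rl$vmax, unit = "mM/min")))
    if (!is.null(rl$km)) {
      out$rate_law$km <- lapply(as.list(rl$km), function(v) list(value = v, unit = "mM"))
    }
    if (!is.null(rl$keq)) out$rate_law$keq <- list(value = rl$keq, unit = "dimensionless")
    if (!is.null(rl$vmax_reverse)) {
      out$rate_law$vmax_reverse <- list(value = rl$vmax_reverse, unit = "mM/min")
    }
    if (length(rl$modifiers)) {
      out$rate_law$modifiers <- lapply(rl$modifiers, function(m) {
        mm <- list(met = m$met, kind = m$kind,
                   k = list(value = m$k, unit = "mM"),
                   hill = m$hill, basal = m$basal)
        if (!is.null(m$toggle)) mm$toggle <- m$toggle
        mm
      })
    }
    out
  })
  doc <- list(name = model$name, metabolites = mets)
  if (!is.null(model$exchange)) {
    doc$exchange <- lapply(seq_len(nrow(model$exchange)), function(i) {
      as.list(model$exchange[i, ])
    })
  }
  doc$reactions <- unname(rxns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The 21 dynamic metabolites of the reference network
#' @return character vector of metabolite ids.
#' @export
reference_dynamic_species <- function() {
  c("DHAP", "Fru", "Fru1P", "Fru6P", "Fru16P2", "Fru26P2", "GAP", "Glc",
    "Glc6P", "Lac", "Mal", "OA", "P", "PEP", "13P2G", "23P2G", "2PG", "3PG",
    "PP", "Pyr", "Sorb")
}

#' Build the reference model of renal glucose metabolism
#'
#' Loads the packaged parameter file (glycolysis, gluconeogenesis and the
#' polyol pathway; 21 dynamic metabolites; clamped NAD/NADH, ADP/ATP and
#' NADP/NADPH; external glucose, lactate, fructose, phosphate and CO2) and
#' validates it. The 2,3-BPG feedback couplings onto hexokinase (`bpg_hk`) and
#' phosphoglycerate mutase (`bpg_pgam`) are on by default and individually
#' switchable.
#'
#' @param param_source path to a JSON model definition; defaults to the
#'   packaged reference parameter file.
#' @param couplings named list of logical toggles (see [read_model_json()]).
#' @return a [kinetic_model()].
#' @export
build_reference_model <- function(param_source = NULL,
                                  couplings = list(bpg_hk = TRUE, bpg_pgam = TRUE)) {
  if (is.null(param_source)) {
    param_source <- system.file("extdata", "reference_model.json",
                                package = "glycoren", mustWork = TRUE)
  }
  model <- read_model_json(param_source, couplings = couplings)
  dyn <- sort(model$dynamic_ids)
  expected <- sort(reference_dynamic_species())
  if (!identical(dyn, expected)) {
    stop("reference model dynamic species mismatch: got {",
         paste(dyn, collapse = ", "), "}")
  }
  clamped <- model$metabolites$id[model$metabolites$role == "clamped"]
  if (!all(c("NAD", "NADH", "ADP", "ATP") %in% clamped)) {
    stop("reference model must clamp NAD, NADH, ADP and ATP")
  }
  # Pyr sink check: only LDH (-> Lac) and PC may consume pyruvate
  consumers <- names(Filter(function(r) {
    !is.na(r$stoich["Pyr"]) && r$stoich["Pyr"] < 0
  }, model$reactions))
  extra <- setdiff(consumers, c("LDH", "PC"))
  if (length(extra)) {
    stop("unexpected pyruvate-consuming reactions: ", paste(extra, collapse = ", "))
  }
  model
}
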