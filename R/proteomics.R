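# Proteomics tables and Vmax scaling factors.
#
# The scaling law: the maximal activity of an enzyme is taken proportional to
# measured protein abundance, so for each reaction and sample
#   vmax_sample = vmax_mean_control * E_sample / E_mean_control
# where E is the summed intensity of the reaction's mapped gene products and
# E_mean_control the arithmetic mean of E over the control samples.

#' Construct a proteomics intensity table
#'
#' @param intensities numeric matrix, genes x samples; rownames are gene
#'   symbols, colnames sample ids. All values finite and >= 0; no duplicated
#'   gene symbols.
#' @param groups named character vector mapping each sample id to
#'   `"control"` or `"KO"`; at least one control sample is required.
#' @return object of class `proteomics_table`.
#' @export
proteomics_table <- function(intensities, groups) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix")
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensities must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(intensities))) stop("duplicated gene symbols in table")
  if (anyDuplicated(colnames(intensities))) stop("duplicated sample ids in table")
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0")
  }
  samples <- colnames(intensities)
  if (is.null(names(groups))) stop("groups must be named by sample id")
  missing <- setdiff(samples, names(groups))
  if (length(missing)) stop("samples without group label: ", paste(missing, collapse = ", "))
  groups <- groups[samples]
  if (!all(groups %in% c("control", "KO"))) stop("group labels must be 'control' or 'KO'")
  if (!any(groups == "control")) stop("at least one control sample is required")
  structure(list(intensities = intensities, groups = groups),
            class = "proteomics_table")
}

#' @export
print.proteomics_table <- function(x, ...) {
  cat("<proteomics_table> ", nrow(x$intensities), " genes x ",
      ncol(x$intensities), " samples (",
      sum(x$groups == "control"), " control, ", sum(x$groups == "KO"), " KO)\n",
      sep = "")
  invisible(x)
}

#' Enzyme map: reaction id -> gene symbols
#'
#' @param map named list, reaction id -> character vector of gene symbols.
#'   Symbols must be unique within each reaction's list.
#' @return object of class `enzyme_map`.
#' @export
enzyme_map <- function(map) {
  if (!is.list(map) || is.null(names(map)) || any(!nzchar(names(map)))) {
    stop("enzyme map must be a named list of gene vectors")
  }
  map <- lapply(map, as.character)
  for (rid in names(map)) {
    if (anyDuplicated(map[[rid]])) stop("duplicated gene in map entry '", rid, "'")
  }
  structure(map, class = "enzyme_map")
}

#' Derive the enzyme map from a model's gene annotations
#'
#' Reactions without mapped genes are omitted (and therefore never scaled).
#'
#' @param model a [kinetic_model()].
#' @return an [enzyme_map()].
#' @export
enzyme_map_from_model <- function(model) {
  genes <- lapply(model$reactions, function(r) r$genes)
  enzyme_map(Filter(length, genes))
}

#' Aggregate gene isoform intensities into reaction abundances
#'
#' The abundance of a reaction in a sample is the SUM of the intensities of
#' its mapped genes present in the table (isozyme abundances add to total
#' activity). Gene symbols are matched case-insensitively (mouse/human casing
#' differs); case-folded matches are logged. Reactions none of whose genes are
#' present are flagged unmeasured, not failed.
#'
#' @param table a [proteomics_table()].
#' @param map an [enzyme_map()].
#' @return numeric matrix, reactions x samples, with logical attribute
#'   `measured` (per reaction).
#' @export
aggregate_isoforms <- function(table, map) {
  stopifnot(inherits(table, "proteomics_table"), inherits(map, "enzyme_map"))
  genes_lc <- tolower(rownames(table$intensities))
  ab <- matrix(0, nrow = length(map), ncol = ncol(table$intensities),
               dimnames = list(names(map), colnames(table$intensities)))
  measured <- stats::setNames(logical(length(map)), names(map))
  for (rid in names(map)) {
    hit <- match(tolower(map[[rid]]), genes_lc)
    hit <- hit[!is.na(hit)]
    folded <- setdiff(rownames(table$intensities)[hit], map[[rid]])
    if (length(folded)) {
      message("aggregate_isoforms: case-folded gene match for '", rid, "': ",
              paste(folded, collapse = ", "))
    }
    if (length(hit)) {
      ab[rid, ] <- colSums(table$intensities[hit, , drop = FALSE])
      measured[rid] <- TRUE
    }
  }
  attr(ab, "measured") <- measured
  ab
}

#' Compute per-sample, per-reaction Vmax scaling factors
#'
#' For measured reactions, `factor = E_sample / E_mean_control` with
#' `E_mean_control` the mean reaction abundance over control samples.
#' Unmeasured reactions -- and measured reactions whose control-mean abundance
#' is zero (division by zero is never performed; demotion is warned) -- get
#' factor 1 with provenance `"default_unmeasured"`.
#'
#' @param table a [proteomics_table()].
#' @param map an [enzyme_map()].
#' @param clip optional length-2 numeric guard rail `c(lo, hi)`; factors
#'   outside are clipped with a logged message. Off (`NULL`) by default and
#'   never silently applied to headline runs.
#' @return object of class `scaling_factors`: list with `factors`
#'   (reaction x sample matrix), `e_mean_control` (named), `provenance`
#'   (named character, `"measured"`/`"default_unmeasured"`), `groups`.
#' @export
compute_scaling_factors <- function(table, map, clip = NULL) {
  ab <- aggregate_isoforms(table, map)
  measured <- attr(ab, "measured")
  ctrl <- names(table$groups)[table$groups == "control"]
  e_mean <- rowMeans(ab[, ctrl, drop = FALSE])
  provenance <- ifelse(measured, "measured", "default_unmeasured")
  names(provenance) <- names(measured)
  zero_ctrl <- measured & e_mean == 0
  if (any(zero_ctrl)) {
    warning("control-mean abundance is zero for: ",
            paste(names(which(zero_ctrl)), collapse = ", "),
            "; demoted to default_unmeasured (factor 1)")
    provenance[zero_ctrl] <- "default_unmeasured"
  }
  scaled <- provenance == "measured"
  factors <- matrix(1, nrow = nrow(ab), ncol = ncol(ab), dimnames = dimnames(ab))
  if (any(scaled)) {
    factors[scaled, ] <- ab[scaled, , drop = FALSE] / e_mean[scaled]
  }
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2L, clip[1] > 0, clip[2] > clip[1])
    n_clip <- sum(factors[scaled, ] < clip[1] | factors[scaled, ] > clip[2])
    if (n_clip > 0) {
      message("compute_scaling_factors: clipping ", n_clip,
              " factors to [", clip[1], ", ", clip[2], "]")
      factors[scaled, ] <- pmin(pmax(factors[scaled, ], clip[1]), clip[2])
    }
  }
  structure(list(factors = factors, e_mean_control = e_mean,
                 provenance = provenance, groups = table$groups),
            class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat("<scaling_factors> ", nrow(x$factors), " reactions x ",
      ncol(x$factors), " samples; ",
      sum(x$provenance == "measured"), " measured, ",
      sum(x$provenance == "default_unmeasured"), " default_unmeasured\n", sep = "")
  invisible(x)
}

#' Force the BPGM factor to zero (in silico hard knockout)
#'
#' Default ensembles use the measured Bpgm intensities (the knockout is
#' reflected in the data); this explicit mode instead deletes the activity.
#'
#' @param factors a [compute_scaling_factors()] result.
#' @param reactions reaction ids to zero out in KO samples (default `"BPGM"`).
#' @param samples sample ids to affect; default all KO-group samples.
#' @return modified `scaling_factors` with attribute `hard_ko = TRUE`.
#' @export
hard_ko <- function(factors, reactions = "BPGM", samples = NULL) {
  stopifnot(inherits(factors, "scaling_factors"))
  if (is.null(samples)) samples <- names(factors$groups)[factors$groups == "KO"]
  unknown <- setdiff(reactions, rownames(factors$factors))
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))
  factors$factors[reactions, samples] <- 0
  attr(factors, "hard_ko") <- TRUE
  factors
}

#' Instantiate a sample-specific model
#'
#' Multiplies each scalable reaction's forward (and explicit reverse) maximal
#' rate by the sample's factor; equilibrium constants and all other parameters
#' are untouched and the base model is not modified. Reactions absent from the
#' factor table keep their base activity.
#'
#' @param base a [kinetic_model()].
#' @param factors a [compute_scaling_factors()] result.
#' @param sample_id column of `factors$factors` to use.
#' @param allow_zero permit factors of exactly 0 (hard-KO mode); otherwise a
#'   nonpositive factor is a validation error. Defaults to the `hard_ko`
#'   attribute of `factors`.
#' @return a new [kinetic_model()].
#' @export
instantiate_sample_model <- function(base, factors, sample_id,
                                     allow_zero = isTRUE(attr(factors, "hard_ko"))) {
  stopifnot(inherits(base, "kinetic_model"), inherits(factors, "scaling_factors"))
  if (!(sample_id %in% colnames(factors$factors))) {
    stop("unknown sample '", sample_id, "'")
  }
  f <- factors$factors[, sample_id]
  f <- f[names(f) %in% names(base$reactions)]
  if (any(f < 0) || (!allow_zero && any(f == 0))) {
    stop("sample '", sample_id, "': nonpositive scaling factor outside hard-KO mode")
  }
  scale_vmax(base, f)
}
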