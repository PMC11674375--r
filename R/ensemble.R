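# Control-vs-KO ensemble simulation and descriptive comparison.

#' Simulate a per-sample ensemble over the glucose grid
#'
#' Instantiates one model per sample from its scaling factors, sweeps it over
#' the external glucose grid and summarizes the glucose and lactate exchange
#' fluxes per group as mean and standard deviation (sample SD, n-1
#' denominator; a single-sample group reports SD as `NA`, not 0).
#' Non-converged grid points are excluded from group statistics per grid
#' point, with logged counts. The computation is deterministic given its
#' inputs.
#'
#' @param base a [kinetic_model()].
#' @param factors a [compute_scaling_factors()] result with >= 1 sample per
#'   group present.
#' @param grid strictly increasing external glucose grid (mM).
#' @param ... passed to [glucose_sweep()].
#' @return object of class `ensemble_result`: list with `curves` (named list
#'   of per-sample [glucose_sweep()] curves), `groups`, `grid`, `summary`
#'   (data.frame: group, glucose_mM, n, glc_mean, glc_sd, lac_mean, lac_sd)
#'   and `diff` (data.frame: glucose_mM, glc_diff, lac_diff; KO mean minus
#'   control mean).
#' @export
simulate_ensemble <- function(base, factors, grid = default_glucose_grid(), ...) {
  stopifnot(inherits(factors, "scaling_factors"))
  groups <- factors$groups
  samples <- colnames(factors$factors)
  curves <- vector("list", length(samples))
  names(curves) <- samples
  for (s in samples) {
    m <- instantiate_sample_model(base, factors, s)
    curve <- suppressWarnings(glucose_sweep(m, grid = grid, ...))
    if (all(!curve$converged)) {
      stop("sample '", s, "' failed to converge at every grid point")
    }
    n_bad <- sum(!curve$converged)
    if (n_bad > 0) {
      message("simulate_ensemble: sample '", s, "': ", n_bad,
              " non-converged grid points excluded from statistics")
    }
    curves[[s]] <- curve
  }

  summary <- do.call(rbind, lapply(c("control", "KO"), function(g) {
    members <- samples[groups == g]
    if (!length(members)) return(NULL)
    do.call(rbind, lapply(seq_along(grid), function(i) {
      glc <- vapply(members, function(s) curves[[s]]$glc_flux[i], numeric(1))
      lac <- vapply(members, function(s) curves[[s]]$lac_flux[i], numeric(1))
      ok <- vapply(members, function(s) curves[[s]]$converged[i], logical(1))
      glc <- glc[ok]; lac <- lac[ok]
      n <- sum(ok)
      data.frame(group = g, glucose_mM = grid[i], n = n,
                 glc_mean = if (n) mean(glc) else NA_real_,
                 glc_sd = if (n > 1) stats::sd(glc) else NA_real_,
                 lac_mean = if (n) mean(lac) else NA_real_,
                 lac_sd = if (n > 1) stats::sd(lac) else NA_real_)
    }))
  }))
  rownames(summary) <- NULL

  diff <- NULL
  if (all(c("control", "KO") %in% groups)) {
    ctrl <- summary[summary$group == "control", ]
    ko <- summary[summary$group == "KO", ]
    diff <- data.frame(glucose_mM = ctrl$glucose_mM,
                       glc_diff = ko$glc_mean - ctrl$glc_mean,
                       lac_diff = ko$lac_mean - ctrl$lac_mean)
  }

  structure(list(curves = curves, groups = groups, grid = grid,
                 summary = summary, diff = diff),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> ", length(x$curves), " samples (",
      sum(x$groups == "control"), " control, ", sum(x$groups == "KO"),
      " KO) over ", length(x$grid), " glucose grid points\n", sep = "")
  if (!is.null(x$diff)) {
    cat("  mean KO-control difference: glc ",
        format(mean(x$diff$glc_diff, na.rm = TRUE), digits = 4), ", lac ",
        format(mean(x$diff$lac_diff, na.rm = TRUE), digits = 4), " mM/min\n", sep = "")
  }
  invisible(x)
}

#' Descriptive comparison of glycolytic flux between groups
#'
#' Reports, per grid point and overall, the sign of the KO-minus-control
#' difference for glucose consumption and lactate production, and the
#' fraction of (pairwise converged) grid points at which KO exceeds control.
#' Purely descriptive: no hypothesis test is computed.
#'
#' @param ensemble an [simulate_ensemble()] result containing both groups.
#' @return object of class `glycolysis_comparison`: list with `per_point`
#'   (data.frame: glucose_mM, glc_diff, lac_diff, glc_sign, lac_sign),
#'   `fraction_glc_elevated`, `fraction_lac_elevated` and `direction` (one of
#'   `"elevated glycolysis in KO"`, `"reduced glycolysis in KO"`, `"none"`,
#'   `"mixed"`).
#' @export
compare_glycolysis <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  if (is.null(ensemble$diff)) stop("both groups must be present for comparison")
  d <- ensemble$diff[stats::complete.cases(ensemble$diff), ]
  per_point <- data.frame(d,
                          glc_sign = sign(d$glc_diff),
                          lac_sign = sign(d$lac_diff))
  frac_glc <- mean(d$glc_diff > 0)
  frac_lac <- mean(d$lac_diff > 0)
  direction <- if (all(d$glc_diff == 0) && all(d$lac_diff == 0)) {
    "none"
  } else if (all(d$glc_diff > 0) && all(d$lac_diff > 0)) {
    "elevated glycolysis in KO"
  } else if (all(d$glc_diff < 0) && all(d$lac_diff < 0)) {
    "reduced glycolysis in KO"
  } else {
    "mixed"
  }
  structure(list(per_point = per_point,
                 fraction_glc_elevated = frac_glc,
                 fraction_lac_elevated = frac_lac,
                 direction = direction),
            class = "glycolysis_comparison")
}

#' @export
print.glycolysis_comparison <- function(x, ...) {
  cat("<glycolysis_comparison> direction: ", x$direction, "\n",
      "  fraction of grid points with KO > control: glucose ",
      format(x$fraction_glc_elevated, digits = 3), ", lactate ",
      format(x$fraction_lac_elevated, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Plot an ensemble as mean lines with SD bands
#'
#' Two panels (glucose uptake, lactate release) with group mean lines and
#' shaded +/- 1 SD bands, control in blue, KO in red.
#'
#' @param ensemble an [simulate_ensemble()] result.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `ensemble`, invisibly.
#' @export
plot_ensemble <- function(ensemble, ...) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  s <- ensemble$summary
  cols <- c(control = "#2166ac", KO = "#b2182b")
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (what in c("glc", "lac")) {
    mean_col <- paste0(what, "_mean"); sd_col <- paste0(what, "_sd")
    ylab <- if (what == "glc") "glucose uptake (mM/min)" else "lactate release (mM/min)"
    rng <- range(s[[mean_col]] + s[[sd_col]], s[[mean_col]] - s[[sd_col]],
                 s[[mean_col]], na.rm = TRUE)
    graphics::plot(NA, xlim = range(s$glucose_mM), ylim = rng,
                   xlab = "external glucose (mM)", ylab = ylab, ...)
    for (g in unique(s$group)) {
      sg <- s[s$group == g, ]
      sd <- ifelse(is.na(sg[[sd_col]]), 0, sg[[sd_col]])
      graphics::polygon(c(sg$glucose_mM, rev(sg$glucose_mM)),
                        c(sg[[mean_col]] + sd, rev(sg[[mean_col]] - sd)),
                        col = grDevices::adjustcolor(cols[[g]], alpha.f = 0.2),
                        border = NA)
      graphics::lines(sg$glucose_mM, sg[[mean_col]], col = cols[[g]], lwd = 2)
    }
    graphics::legend("topleft", legend = unique(s$group),
                     col = cols[unique(s$group)], lwd = 2, bty = "n")
  }
  invisible(ensemble)
}
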