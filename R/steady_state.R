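# Steady-state integration.
#
# No stiff ODE solver package is assumed: steady states are found by
# pseudo-transient continuation (adaptive backward-Euler steps solved with a
# chord-Newton iteration and a finite-difference Jacobian), followed by a
# damped Newton polish of f(x) = 0 once the transient has flattened out. The
# fixed-step explicit RK4 integrator below serves as the independent oracle on
# non-stiff toy models.

#' @keywords internal
fd_jacobian <- function(model, x) {
  n <- length(x)
  f0 <- model_rhs(model, x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- 1e-7 * max(abs(x[i]), 1e-6)
    xp <- x; xp[i] <- xp[i] + h
    J[, i] <- (model_rhs(model, xp) - f0) / h
  }
  J
}

#' Integrate a kinetic model to steady state
#'
#' Advances the ODE system with adaptive implicit (backward Euler) steps until
#' the right-hand side satisfies `max|dx/dt| < ss_tol * max(1, max|x|)` or the
#' integrated model time exceeds `max_time` (then reported as non-converged,
#' never silently truncated). A final damped Newton iteration polishes the
#' root of the right-hand side to near machine precision when possible.
#' Negative concentrations beyond `-neg_tol` make a step fail (the step size
#' is reduced; trajectories are never projected back to the positive orthant).
#'
#' @param model a [kinetic_model()].
#' @param x0 initial state (named or model-ordered, mM); defaults to the
#'   model's stored initial concentrations.
#' @param ss_tol steady-state tolerance on `max|dx/dt|` relative to
#'   `max(1, max|x|)`; default `1e-9`.
#' @param max_time maximal model time in minutes before giving up (default `1e6`).
#' @param dt0 initial step size (min).
#' @param dt_max largest allowed step size (min).
#' @param neg_tol tolerated negative excursion before a step is rejected.
#' @return object of class `steady_state_result`: list with `concentrations`
#'   (named, mM), `fluxes` (named, mM/min), `exchange_fluxes` (named by
#'   exchange species under the model's sign convention: positive = uptake for
#'   uptake-type exchanges, positive = release for release-type),
#'   `residual_norm`, `converged`, `integration_time`, `steps`.
#' @export
integrate_to_steady_state <- function(model, x0 = NULL, ss_tol = 1e-9,
                                      max_time = 1e6, dt0 = 1e-4,
                                      dt_max = 1e5, neg_tol = 1e-10) {
  x <- if (is.null(x0)) unname(model$x0) else order_state(model, x0)
  if (any(x < 0)) stop("x0 must be nonnegative")
  n <- length(x)
  t <- 0
  dt <- dt0
  steps <- 0L
  I <- diag(n)
  J <- NULL
  A_lu <- NULL
  dt_of_A <- NA_real_

  repeat {
    f <- model_rhs(model, x)
    if (max(abs(f)) < ss_tol * max(1, max(abs(x)))) break
    if (t >= max_time) {
      return(finish_steady_state(model, x, t, steps, converged = FALSE))
    }
    if (is.null(J)) {
      J <- fd_jacobian(model, x)
      A_lu <- NULL
    }
    # chord Newton for g(y) = (y - x)/dt - f(y) = 0
    accepted <- FALSE
    while (!accepted) {
      if (is.null(A_lu) || !identical(dt_of_A, dt)) {
        A <- I / dt - J
        A_lu <- tryCatch(solve(A), error = function(e) NULL)
        dt_of_A <- dt
        if (is.null(A_lu)) { dt <- dt / 4; next }
      }
      y <- x
      ok <- FALSE
      for (it in seq_len(12L)) {
        g <- (y - x) / dt - model_rhs(model, y)
        if (max(abs(g)) < 1e-9 * max(1, max(abs(f)))) { ok <- TRUE; break }
        y <- y + drop(A_lu %*% (-g))
        if (any(!is.finite(y))) break
      }
      if (ok && all(y >= -neg_tol)) {
        y[y < 0] <- 0   # excursions within neg_tol only; larger ones reject the step
        x <- y
        t <- t + dt
        steps <- steps + 1L
        dt <- min(dt * 2, dt_max)
        accepted <- TRUE
        if (steps %% 5L == 0L) { J <- NULL }  # refresh Jacobian periodically
      } else {
        dt <- dt / 4
        J <- fd_jacobian(model, x)
        A_lu <- NULL
        if (dt < 1e-13) {
          worst <- model$dynamic_ids[which.max(abs(f))]
          stop("steady-state integration failed: step size underflow; ",
               "fastest-moving species is '", worst, "'")
        }
      }
    }
  }

  # Newton polish on f(x) = 0
  x <- newton_polish(model, x)
  finish_steady_state(model, x, t, steps, converged = TRUE, ss_tol = ss_tol)
}

#' @keywords internal
newton_polish <- function(model, x, max_iter = 12L) {
  f <- model_rhs(model, x)
  best <- x; best_norm <- max(abs(f))
  for (it in seq_len(max_iter)) {
    if (best_norm < 1e-13 * max(1, max(abs(best)))) break
    J <- fd_jacobian(model, best)
    dx <- tryCatch(solve(J, -model_rhs(model, best)), error = function(e) NULL)
    if (is.null(dx)) break
    lambda <- 1
    improved <- FALSE
    for (k in 1:6) {
      cand <- best + lambda * dx
      if (all(cand >= 0)) {
        fn <- tryCatch(max(abs(model_rhs(model, cand))), error = function(e) Inf)
        if (is.finite(fn) && fn < best_norm) {
          best <- cand; best_norm <- fn; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  best
}

#' @keywords internal
finish_steady_state <- function(model, x, t, steps, converged, ss_tol = 1e-9) {
  f <- model_rhs(model, x)
  v <- reaction_rates(model, x)
  structure(
    list(concentrations = stats::setNames(x, model$dynamic_ids),
         fluxes = v,
         exchange_fluxes = exchange_fluxes(model, v),
         residual_norm = max(abs(f)),
         converged = converged,
         integration_time = t,
         steps = steps),
    class = "steady_state_result"
  )
}

#' @keywords internal
exchange_fluxes <- function(model, v) {
  ex <- model$exchange
  if (is.null(ex)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(v[ex$reaction], ex$species)
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result> converged:", x$converged,
      " residual:", format(x$residual_norm, digits = 3),
      " model time:", format(x$integration_time, digits = 4), "min\n")
  if (length(x$exchange_fluxes)) {
    cat("  exchange fluxes (mM/min):\n")
    print(round(x$exchange_fluxes, 6))
  }
  invisible(x)
}

#' Fixed-step explicit RK4 integrator
#'
#' Brute-force explicit integrator used as the independent oracle against the
#' adaptive implicit solver on non-stiff toy models. Not suitable for the
#' stiff reference network.
#'
#' @param model a [kinetic_model()].
#' @param x0 initial state (named or model-ordered).
#' @param dt fixed step size (min).
#' @param t_end integration horizon (min).
#' @return named state vector at `t_end`.
#' @export
integrate_fixed_step <- function(model, x0 = NULL, dt = 1e-3, t_end = 100) {
  x <- if (is.null(x0)) unname(model$x0) else order_state(model, x0)
  nstep <- ceiling(t_end / dt)
  for (i in seq_len(nstep)) {
    k1 <- model_rhs(model, x)
    k2 <- model_rhs(model, x + dt / 2 * k1)
    k3 <- model_rhs(model, x + dt / 2 * k2)
    k4 <- model_rhs(model, x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::setNames(x, model$dynamic_ids)
}

#' Sweep steady states over a grid of external glucose concentrations
#'
#' Clamps the external glucose species to each grid value in turn (warm-started
#' from the previous converged state) and records the glucose and lactate
#' exchange fluxes. Grid points that fail to converge are flagged and a warning
#' is logged; downstream ensemble statistics exclude them.
#'
#' @param model a [kinetic_model()] whose boundary contains `glc_species`.
#' @param grid strictly increasing vector of external glucose concentrations
#'   (mM, all > 0). Default 2-12 mM in 0.5 mM steps (physiological plasma
#'   glucose range).
#' @param glc_species boundary species id to clamp (default `"Glc_ext"`).
#' @param ... passed to [integrate_to_steady_state()].
#' @return object of class `flux_curve`: data.frame with columns
#'   `glucose_mM`, `glc_flux` (positive = uptake), `lac_flux`
#'   (positive = release), `converged`.
#' @export
glucose_sweep <- function(model, grid = default_glucose_grid(),
                          glc_species = "Glc_ext", ...) {
  validate_grid(grid)
  x0 <- unname(model$x0)
  rows <- vector("list", length(grid))
  flux_mat <- matrix(NA_real_, nrow = length(model$reactions), ncol = length(grid),
                     dimnames = list(names(model$reactions), NULL))
  for (i in seq_along(grid)) {
    m <- set_boundary(model, glc_species, grid[i])
    ss <- tryCatch(integrate_to_steady_state(m, x0 = x0, ...),
                   error = function(e) NULL)
    if (!is.null(ss) && ss$converged) flux_mat[, i] <- ss$fluxes
    if (is.null(ss) || !ss$converged) {
      rows[[i]] <- data.frame(glucose_mM = grid[i], glc_flux = NA_real_,
                              lac_flux = NA_real_, converged = FALSE)
      if (!is.null(ss)) x0 <- unname(ss$concentrations)
    } else {
      ex <- ss$exchange_fluxes
      rows[[i]] <- data.frame(glucose_mM = grid[i],
                              glc_flux = unname(ex[["Glc"]]),
                              lac_flux = unname(ex[["Lac"]]),
                              converged = TRUE)
      x0 <- unname(ss$concentrations)
    }
  }
  curve <- do.call(rbind, rows)
  attr(curve, "flux_matrix") <- flux_mat
  n_bad <- sum(!curve$converged)
  if (n_bad > 0) {
    warning("glucose_sweep: ", n_bad, " of ", length(grid),
            " grid points did not converge and are flagged")
  }
  structure(curve, class = c("flux_curve", "data.frame"))
}

#' Default external glucose grid (mM)
#'
#' 2 to 12 mM in 0.5 mM steps: the physiological plasma glucose range.
#' @return numeric vector.
#' @export
default_glucose_grid <- function() seq(2, 12, by = 0.5)

#' @keywords internal
validate_grid <- function(grid) {
  if (!is.numeric(grid) || !length(grid)) stop("grid must be a nonempty numeric vector")
  if (any(!is.finite(grid)) || any(grid <= 0)) stop("grid values must be finite and > 0")
  if (length(grid) > 1 && any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  invisible(grid)
}
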