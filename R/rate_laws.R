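#' @keywords internal
RATE_LAW_FORMS <- c(
  "mass_action_irreversible",
  "mass_action_reversible",
  "michaelis_menten_irreversible",
  "michaelis_menten_reversible",
  "transporter_facilitated"
)

#' @keywords internal
MODIFIER_KINDS <- c("competitive_inhibitor", "allosteric_inhibitor", "allosteric_activator")

#' Construct a rate-law modifier term
#'
#' A modifier couples an effector metabolite to a reaction without being a
#' stoichiometric participant. Competitive inhibitors add an `(I/Ki)^h` term to
#' the binding denominator (preserving the thermodynamic equilibrium point of
#' reversible laws); allosteric inhibitors multiply the rate by
#' `1 / (1 + (I/Ki)^h)`; allosteric activators multiply it by
#' `(basal + (A/Ka)^h) / (1 + (A/Ka)^h)`, i.e. nonessential activation with a
#' basal activity fraction.
#'
#' @param met metabolite id of the effector.
#' @param kind one of `"competitive_inhibitor"`, `"allosteric_inhibitor"`,
#'   `"allosteric_activator"`.
#' @param k inhibition/activation constant in mM (strictly positive).
#' @param hill Hill coefficient (strictly positive, default 1).
#' @param basal basal activity fraction in `[0, 1)`, activators only.
#' @param toggle optional name of a configuration switch controlling whether
#'   the modifier is active (used for the 2,3-BPG feedback couplings).
#' @return a `rate_modifier` list.
#' @export
rate_modifier <- function(met, kind, k, hill = 1, basal = 0.1, toggle = NULL) {
  kind <- match.arg(kind, MODIFIER_KINDS)
  stopifnot(is.character(met), length(met) == 1L)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("modifier constant for '", met, "' must be a single finite value > 0")
  }
  if (!is.numeric(hill) || hill <= 0) stop("Hill coefficient must be > 0")
  if (kind == "allosteric_activator" && (basal < 0 || basal >= 1)) {
    stop("activator basal fraction must lie in [0, 1)")
  }
  structure(
    list(met = met, kind = kind, k = as.numeric(k), hill = as.numeric(hill),
         basal = as.numeric(basal), toggle = toggle),
    class = "rate_modifier"
  )
}

#' Construct a kinetic rate law
#'
#' Supported forms (all rates in mM/min, concentrations and constants in mM):
#' \describe{
#'   \item{mass_action_irreversible}{`v = vmax * prod(S^n)`; `vmax` acts as the
#'     rate constant (units depend on molecularity).}
#'   \item{mass_action_reversible}{`v = vmax * prod(S^n) - vmax_reverse * prod(P^n)`,
#'     with `vmax_reverse = vmax / keq` when only `keq` is given.}
#'   \item{michaelis_menten_irreversible}{`v = vmax * prod((S/KmS)^n) / D` with
#'     `D = prod((1 + S/KmS)^n) + competitive terms`.}
#'   \item{michaelis_menten_reversible}{generalized reversible Michaelis-Menten
#'     (convenience-kinetics denominator):
#'     `v = (vmax * prod((S/KmS)^n) - vmax_reverse * prod((P/KmP)^n)) / D`,
#'     `D = prod((1 + S/KmS)^n) + prod((1 + P/KmP)^n) - 1 + competitive terms`.
#'     When `keq` is supplied, `vmax_reverse` follows from the Haldane relation
#'     `keq = (vmax/vmax_reverse) * prod(KmP^n) / prod(KmS^n)`, so the rate is
#'     exactly zero at mass-action ratio `keq`.}
#'   \item{transporter_facilitated}{symmetric facilitated carrier between one
#'     substrate-side and one product-side species sharing a single Km:
#'     `v = vmax * (S - P) / Km / (1 + S/Km + P/Km)`; zero at `S == P`.}
#' }
#'
#' @param form rate-law form, one of [RATE_LAW_FORMS].
#' @param vmax forward maximal rate (mM/min), strictly positive unless the
#'   reaction has been knocked out (zero allowed, negative never).
#' @param km named numeric vector of Michaelis constants (mM) keyed by
#'   metabolite id; required for the Michaelis-Menten and transporter forms.
#' @param keq apparent equilibrium constant (mass-action ratio at equilibrium,
#'   products over substrates, concentration units absorbed); reversible forms.
#' @param vmax_reverse explicit reverse maximal rate; if both `keq` and
#'   `vmax_reverse` are given they must satisfy the Haldane relation to 1e-6
#'   relative (validated at model build, never silently renormalized).
#' @param modifiers list of [rate_modifier()] terms.
#' @return a `rate_law` list.
#' @export
rate_law <- function(form, vmax, km = NULL, keq = NULL, vmax_reverse = NULL,
                     modifiers = list()) {
  form <- match.arg(form, RATE_LAW_FORMS)
  if (!is.numeric(vmax) || length(vmax) != 1L || !is.finite(vmax) || vmax < 0) {
    stop("vmax must be a single finite value >= 0")
  }
  reversible <- form %in% c("mass_action_reversible", "michaelis_menten_reversible")
  if (reversible && is.null(keq) && is.null(vmax_reverse)) {
    stop("reversible rate law requires keq and/or vmax_reverse")
  }
  if (!is.null(keq) && (!is.finite(keq) || keq <= 0)) stop("keq must be finite and > 0")
  if (!is.null(vmax_reverse) && (!is.finite(vmax_reverse) || vmax_reverse < 0)) {
    stop("vmax_reverse must be finite and >= 0")
  }
  if (!is.null(km)) {
    if (is.null(names(km)) || any(!nzchar(names(km)))) stop("km entries must be named by metabolite id")
    if (any(!is.finite(km)) || any(km <= 0)) stop("all Km values must be finite and > 0")
  }
  if (form %in% c("michaelis_menten_irreversible", "michaelis_menten_reversible",
                  "transporter_facilitated") && is.null(km)) {
    stop("form '", form, "' requires km")
  }
  if (!is.list(modifiers)) stop("modifiers must be a list")
  modifiers <- lapply(modifiers, function(m) {
    if (!inherits(m, "rate_modifier")) stop("each modifier must be built with rate_modifier()")
    m
  })
  structure(
    list(form = form, vmax = as.numeric(vmax), km = km,
         keq = if (is.null(keq)) NULL else as.numeric(keq),
         vmax_reverse = if (is.null(vmax_reverse)) NULL else as.numeric(vmax_reverse),
         modifiers = modifiers),
    class = "rate_law"
  )
}
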