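#' Effective monomer length as a function of salt concentration
#'
#' For a short polyelectrolyte (e.g. an ssDNA oligomer) in aqueous NaCl, the
#' effective monomer length grows slowly with ionic strength as charge
#' screening relaxes the backbone. The empirical interpolation used here is
#' linear in the decadic log of the salt concentration,
#' \deqn{A_0(s) = 11/4 + y/4, \qquad y = \log_{10}(s / 1\,\mathrm{mM}).}
#'
#' Because measured \eqn{A_0} values scatter strongly from one salt
#' concentration to the next, qualitative work normalizes \eqn{A_0} to 1 so
#' that scaling-law radii are expressed in monomer lengths; `normalized = TRUE`
#' applies that convention.
#'
#' @param s Salt concentration in mM (positive; vectorized).
#' @param normalized If `TRUE`, return 1 regardless of `s` (monomer-length
#'   units).
#' @return Effective monomer length in Angstrom (or 1 if normalized).
#' @seealso [scaling_exponent()], [rg_scaling()]
#' @examples
#' monomer_length(1)    # 2.75
#' monomer_length(1000) # 3.5
#' @export
monomer_length <- function(s, normalized = FALSE) {
  check_salt(s)
  if (normalized) {
    return(rep(1, length(s)))
  }
  11 / 4 + log10(s) / 4
}

#' Salt-dependent scaling (Flory) exponent
#'
#' Exponent \eqn{\nu(s)} in the scaling law \eqn{R_g = A_0 N^{\nu}},
#' interpolated from experimental data as
#' \deqn{\nu(s) = 0.794 - 0.0674\, \log_{10}(s / 1\,\mathrm{mM}).}
#' Low salt leaves the backbone charges unscreened and the chain stiff
#' (\eqn{\nu} close to 1, rod-like); high salt screens the repulsion and the
#' chain softens toward globular statistics (\eqn{\nu \to 1/3}).
#'
#' The interpolation is accepted for any positive `s`; outside the idealized
#' physical window the result is clamped to \eqn{[1/3, 1]} (poor-solvent
#' globule to rigid rope) with a warning.
#'
#' @param s Salt concentration in mM (positive; vectorized).
#' @param clamp Clamp the result to \eqn{[1/3, 1]}? Default `TRUE`.
#' @return Dimensionless scaling exponent.
#' @examples
#' scaling_exponent(1)     # 0.794
#' scaling_exponent(12.5)  # 0.720
#' @export
scaling_exponent <- function(s, clamp = TRUE) {
  check_salt(s)
  nu <- 0.794 - 0.0674 * log10(s)
  if (clamp) {
    out_of_range <- nu < 1 / 3 | nu > 1
    if (any(out_of_range)) {
      warning("scaling exponent clamped to the physical range [1/3, 1]")
      nu <- pmin(pmax(nu, 1 / 3), 1)
    }
  }
  nu
}

#' Bundle salt conditions and their derived scaling parameters
#'
#' @param s Salt concentration in mM (positive scalar).
#' @param normalized Use monomer-length units (\eqn{A_0 = 1})? Default `TRUE`,
#'   the convention under which all scaling-law radii in this package are
#'   reported.
#' @return An object of class `salt_conditions`: a list with fields `s`, `y`
#'   (\eqn{\log_{10} s}), `A0`, `nu` and `normalized`.
#' @examples
#' salt_conditions(125)
#' @export
salt_conditions <- function(s, normalized = TRUE) {
  stopifnot(length(s) == 1)
  check_salt(s)
  structure(
    list(
      s = s,
      y = log10(s),
      A0 = monomer_length(s, normalized = normalized),
      nu = scaling_exponent(s),
      normalized = normalized
    ),
    class = "salt_conditions"
  )
}

#' @export
print.salt_conditions <- function(x, ...) {
  cat(sprintf(
    "Salt conditions: s = %g mM (y = %.3f)\n  A0 = %.3f%s   nu = %.3f\n",
    x$s, x$y, x$A0, if (x$normalized) " (normalized)" else " Angstrom", x$nu
  ))
  invisible(x)
}

#' Scaling-law radius of gyration with a crowding deformation factor
#'
#' \deqn{R_g(s, N, P) = A_0(s)\, N^{\nu(s)}\, F(s, N, P)}
#' where `F` is the crowding deformation factor. Without crowding
#' (`P = 0`) the boundary condition \eqn{F \equiv 1} is enforced, so the
#' dilute scaling law \eqn{R_g = A_0 N^{\nu}} is recovered. No functional form
#' of `F` is imposed for `P > 0`: the caller supplies either a constant or a
#' function of `(s, N, P)`. A physically motivated choice built from the
#' effective-potential compression factor is available via
#' [deformation_from_potential()].
#'
#' @param s Salt concentration in mM, or a [salt_conditions()] object.
#' @param N Number of monomers (>= 1; vectorized).
#' @param P Crowder percentage in `[0, 100]` (mass or volume percent).
#' @param F Deformation factor: a positive number or a `function(s, N, P)`.
#'   Ignored (forced to 1) when `P = 0`. Default 1.
#' @param normalized Use \eqn{A_0 = 1}? Default `TRUE`. Ignored when `s` is a
#'   `salt_conditions` object.
#' @return Radius of gyration, in monomer lengths when normalized (otherwise
#'   Angstrom).
#' @examples
#' rg_scaling(125, N = 40)        # ~11.1 monomer lengths
#' rg_scaling(1, N = 60)          # ~25.8
#' @export
rg_scaling <- function(s, N, P = 0, F = 1, normalized = TRUE) {
  if (inherits(s, "salt_conditions")) {
    cond <- s
  } else {
    cond <- salt_conditions(s, normalized = normalized)
  }
  if (any(N < 1)) {
    stop("N must be >= 1")
  }
  if (length(P) != 1 || P < 0 || P > 100) {
    stop("P must be a single percentage in [0, 100]")
  }
  f <- if (P == 0) {
    1
  } else if (is.function(F)) {
    F(cond$s, N, P)
  } else {
    F
  }
  if (any(f <= 0)) {
    stop("deformation factor F must be positive")
  }
  cond$A0 * N^cond$nu * f
}

#' Crowding deformation factor derived from the effective potential
#'
#' Returns a deformation-factor function suitable for [rg_scaling()]'s `F`
#' argument. The compression factor \eqn{\beta = (m/n)^{1/(m-n)}} of the
#' generalized Lennard-Jones potential measures how much crowding shrinks the
#' chain (equilibrium size without crowding = \eqn{\beta \times} compressed
#' size), so under crowding the dilute radius is divided by \eqn{\beta}:
#' \eqn{F = 1/\beta} for any `P > 0`, and `F = 1` at `P = 0`.
#'
#' @param m Short-range exponent of the potential (`m > n`).
#' @param n Long-range exponent.
#' @return A `function(s, N, P)` usable as the `F` argument of [rg_scaling()].
#' @examples
#' f <- deformation_from_potential(12, 6)
#' rg_scaling(125, N = 40, P = 20, F = f)
#' @export
deformation_from_potential <- function(m, n) {
  beta <- compression_factor(m, n)
  function(s, N, P) ifelse(P > 0, 1 / beta, 1)
}

#' Fit the scaling law to (N, Rg) pairs
#'
#' Least-squares fit of \eqn{\log R_g = \log A_0 + \nu \log N}, the inverse
#' problem of the dilute scaling law. Useful for recovering an effective
#' scaling exponent from measured or simulated radii.
#'
#' @param N Monomer counts (>= 2 distinct values).
#' @param Rg Radii of gyration (positive, same length as `N`).
#' @return A list with `A0_hat`, `nu_hat` and the underlying `stats::lm` fit.
#' @examples
#' N <- c(20, 30, 40, 50, 60)
#' fit_scaling(N, N^0.653)$nu_hat  # 0.653
#' @export
fit_scaling <- function(N, Rg) {
  if (length(N) != length(Rg)) {
    stop("N and Rg must have the same length")
  }
  if (length(unique(N)) < 2) {
    stop("need at least two distinct N values to fit the scaling law")
  }
  if (any(Rg <= 0) || any(N < 1)) {
    stop("all Rg must be positive and all N >= 1")
  }
  fit <- stats::lm(log(Rg) ~ log(N))
  coefs <- stats::coef(fit)
  list(
    A0_hat = unname(exp(coefs[1])),
    nu_hat = unname(coefs[2]),
    fit = fit
  )
}

check_salt <- function(s) {
  if (!is.numeric(s) || length(s) == 0 || any(!is.finite(s)) || any(s <= 0)) {
    stop("salt concentration s must be positive (mM)")
  }
  invisible(s)
}
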