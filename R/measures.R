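#' Hydrodynamic radius from the radius of gyration
#'
#' Two conventions are provided. The default `"sqrt"` rule,
#' \eqn{R_h = (5 R_g / 3)^{1/2}}, is the rule used to generate the reference
#' grids reproduced by [build_table()]; it is dimensionally inconsistent (it
#' only makes sense with both radii in monomer lengths) but is kept as the
#' default because it is what the reference tables encode. The `"linear"`
#' rule reads the good-solvent proportionality \eqn{R_g \approx (5/3) R_h} the
#' dimensionally sane way: \eqn{R_h = (3/5) R_g}.
#'
#' @param rg Radius of gyration (>= 0; vectorized), in monomer lengths.
#' @param convention `"sqrt"` (default, table rule) or `"linear"`.
#' @return The hydrodynamic radius.
#' @examples
#' rh_from_rg(20^0.72)  # 3.8
#' @export
rh_from_rg <- function(rg, convention = c("sqrt", "linear")) {
  convention <- match.arg(convention)
  if (any(rg < 0)) stop("Rg must be non-negative")
  switch(convention,
    sqrt = sqrt(5 * rg / 3),
    linear = 3 / 5 * rg
  )
}

#' End-to-end distance from the hydrodynamic radius
#'
#' Standard-conditions proportionality \eqn{R_{e\mbox{-}e} \approx 3.1 R_h}.
#'
#' @param rh Hydrodynamic radius (>= 0; vectorized).
#' @return The end-to-end distance.
#' @examples
#' ree_from_rh(1)  # 3.1
#' @export
ree_from_rh <- function(rh) {
  if (any(rh < 0)) stop("Rh must be non-negative")
  3.1 * rh
}

#' End-to-end distance of the compact-sphere configuration
#'
#' A chain of `N` unit-radius monomers compacted into a solid sphere has
#' radius \eqn{R \approx N^{1/3}} (equal total monomer volume). With the
#' chain ends at diametrically opposite poles,
#' \eqn{R_{e\mbox{-}e} \approx 2R = 2N^{1/3}}, and with the solid-sphere rule
#' \eqn{R_g = (6/5)^{1/2} R} the ratio is
#' \eqn{R_{e\mbox{-}e}/R_g = 2\sqrt{5/6} \approx 1.8}, independent of `N`.
#'
#' @param N Number of monomers (>= 1; vectorized).
#' @return A list with `R` (sphere radius), `ree` and the constant `ratio`
#'   \eqn{R_{e\mbox{-}e}/R_g}.
#' @examples
#' sphere_ree(20)$ree    # 5.4
#' sphere_ree(20)$ratio  # 1.83
#' @export
sphere_ree <- function(N) {
  if (any(N < 1)) stop("N must be >= 1")
  R <- N^(1 / 3)
  list(R = R, ree = 2 * R, ratio = 2 * sqrt(5 / 6))
}

#' Shape factor alpha = Rg / Re-e
#'
#' The proportionality factor between the radius of gyration and the
#' end-to-end distance. Freely jointed chains give
#' \eqn{\alpha = 1/\sqrt{6} \approx 0.408}; a compact sphere gives
#' \eqn{\alpha = 1/1.8 \approx 0.55}. Departures from 0.408 measure how far a
#' configuration is from ideal-chain statistics.
#'
#' @param rg Radius of gyration (>= 0; vectorized).
#' @param ree End-to-end distance (> 0).
#' @return The dimensionless ratio.
#' @examples
#' alpha_factor(1, sqrt(6))  # 0.408
#' @export
alpha_factor <- function(rg, ree) {
  if (any(ree <= 0)) stop("Re-e must be positive")
  if (any(rg < 0)) stop("Rg must be non-negative")
  rg / ree
}

# Named regime anchors for the scaling exponent.
regime_anchors <- c(sphere = 1 / 3, theta = 0.5, saw = 0.588,
                    good = 0.6, rope = 1)

#' Classify the conformational regime from the scaling exponent
#'
#' Maps a scaling exponent to the nearest named regime anchor:
#' compact sphere (\eqn{\nu \approx 0.33}), theta solvent (0.5),
#' self-avoiding walk (0.588), good solvent (0.6), and rigid rope (1).
#' Interval boundaries are the midpoints between neighboring anchors, with
#' ties broken toward the stiffer (larger-\eqn{\nu}) regime. The anchors are
#' physical; the midpoint boundaries are an implementation convention.
#'
#' @param nu Scaling exponent(s) in `(0, 1.2]`.
#' @return Character vector of regime labels in
#'   `c("sphere", "theta", "saw", "good", "rope")`.
#' @examples
#' classify_regime(0.5)    # "theta"
#' classify_regime(0.794)  # "good"
#' @export
classify_regime <- function(nu) {
  if (any(!is.finite(nu)) || any(nu <= 0) || any(nu > 1.2)) {
    stop("nu must lie in (0, 1.2]")
  }
  anchors <- regime_anchors
  vapply(nu, function(v) {
    d <- abs(anchors - v)
    # which.max on the reversed tie test picks the stiffer anchor on ties
    idx <- max(which(d == min(d)))
    names(anchors)[idx]
  }, character(1))
}

#' Full measure set for given salt conditions and chain length
#'
#' Chains the dilute scaling law through the measurement conversions:
#' \eqn{R_g = N^{\nu(s)}} (normalized \eqn{A_0}), \eqn{R_h} from [rh_from_rg()],
#' \eqn{R_{e\mbox{-}e}} from [ree_from_rh()], the shape factor
#' \eqn{\alpha = R_g/R_{e\mbox{-}e}}, and the regime label of \eqn{\nu(s)}.
#'
#' @param s Salt concentration in mM.
#' @param N Number of monomers (>= 1).
#' @param P Crowder percentage; default 0 (dilute).
#' @param F Deformation factor for `P > 0`; see [rg_scaling()].
#' @param convention Rh conversion rule; see [rh_from_rg()].
#' @param normalized Use monomer-length units? Default `TRUE`.
#' @return An object of class `measure_set` with fields `s`, `N`, `nu`, `rg`,
#'   `rh`, `ree`, `alpha`, `regime`, `convention`.
#' @examples
#' measure_set(12.5, 20)
#' @export
measure_set <- function(s, N, P = 0, F = 1,
                        convention = c("sqrt", "linear"), normalized = TRUE) {
  convention <- match.arg(convention)
  cond <- salt_conditions(s, normalized = normalized)
  rg <- rg_scaling(cond, N = N, P = P, F = F)
  rh <- rh_from_rg(rg, convention = convention)
  ree <- ree_from_rh(rh)
  structure(
    list(
      s = s, N = N, nu = cond$nu, rg = rg, rh = rh, ree = ree,
      alpha = alpha_factor(rg, ree), regime = classify_regime(cond$nu),
      convention = convention
    ),
    class = "measure_set"
  )
}

#' @export
print.measure_set <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Measures at s = %g mM, N = %d (nu = %.3f, regime: %s)\n",
      "  Rg = %.2f  Rh = %.2f (%s rule)  Re-e = %.2f  alpha = %.3f\n"
    ),
    x$s, x$N, x$nu, x$regime, x$rg, x$rh, x$convention, x$ree, x$alpha
  ))
  invisible(x)
}
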