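#' Parameters of the generalized Lennard-Jones effective potential
#'
#' The competition between the short-range electrostatic stretching force F1
#' and the long-range entropic compressing force F2 acting on a small
#' polyelectrolyte is represented by a generalized Lennard-Jones potential
#' \deqn{V(r) = a\,\varepsilon\left[(\sigma/r)^m - (\sigma/r)^n\right],}
#' where `r` is interpreted as the end-to-end size of the chain rather than a
#' particle-particle distance: \eqn{\sigma = R_{e\mbox{-}e}} is the size of the
#' compressed chain and the potential minimum \eqn{r_m = \beta\sigma} is its
#' size without crowding, with \eqn{\beta = (m/n)^{1/(m-n)}} the compression
#' factor. The exponents satisfy `m > n > 0` (short- vs long-range) and need
#' not be integers.
#'
#' The prefactor uses the standard depth normalization of the generalized
#' (Mie) potential, \eqn{a = \frac{m}{m-n}\,\beta^n}, so that
#' \eqn{V(\sigma) = 0} and \eqn{V(r_m) = -\varepsilon} for every valid
#' `(m, n)`: \eqn{\varepsilon} is always the well depth. On the `m = 2n`
#' family (including the classic 12-6, where a = 4 and b = 2) this
#' coincides with the power-of-\eqn{\beta} prefactors \eqn{\beta^m} and
#' \eqn{\beta^{m-n}} sometimes quoted for this potential; away from
#' `m = 2n` those powers would make the well depth \eqn{(m/n - 1)\varepsilon}
#' instead of \eqn{\varepsilon}, so the depth normalization is used. `b`
#' is the long-range prefactor of the \eqn{r_m}-based form (see
#' [lj_potential()]), \eqn{b = m/(m-n)}.
#'
#' @param epsilon Well depth (energy units, positive). Default 1.
#' @param sigma Zero-crossing separation (length units, positive). Default 1.
#' @param m Short-range exponent (> n). Default 12.
#' @param n Long-range exponent (> 0). Default 6.
#' @return An object of class `potential_params` with fields `epsilon`,
#'   `sigma`, `m`, `n` and derived `beta`, `a`, `b`, `r_m`.
#' @examples
#' p <- potential_params()
#' p$r_m   # 2^(1/6)
#' @export
potential_params <- function(epsilon = 1, sigma = 1, m = 12, n = 6) {
  stopifnot(length(epsilon) == 1, length(sigma) == 1,
            length(m) == 1, length(n) == 1)
  if (epsilon <= 0 || sigma <= 0) {
    stop("epsilon and sigma must be positive")
  }
  if (!(m > n && n > 0)) {
    stop("exponents must satisfy m > n > 0")
  }
  beta <- compression_factor(m, n)
  structure(
    list(
      epsilon = epsilon, sigma = sigma, m = m, n = n,
      beta = beta, a = m / (m - n) * beta^n, b = m / (m - n),
      r_m = beta * sigma
    ),
    class = "potential_params"
  )
}

#' @export
print.potential_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Generalized Lennard-Jones potential (m = %g, n = %g)\n",
      "  epsilon = %g, sigma = %g\n",
      "  beta = %.6f, a = %.6f, b = %.6f, r_m = %.6f\n"
    ),
    x$m, x$n, x$epsilon, x$sigma, x$beta, x$a, x$b, x$r_m
  ))
  invisible(x)
}

#' Evaluate the effective potential
#'
#' Two algebraically equivalent parameterizations are available: the
#' `"sigma"` form \eqn{a\varepsilon[(\sigma/r)^m - (\sigma/r)^n]} and the
#' `"rm"` form written on the reduced separation \eqn{r_m/r},
#' \eqn{\varepsilon[\frac{n}{m-n}(r_m/r)^m - b\,(r_m/r)^n]} with
#' \eqn{b = m/(m-n)} (for 12-6: \eqn{\varepsilon[(r_m/r)^{12} - 2 (r_m/r)^6]}).
#' They agree pointwise for every valid parameter set.
#'
#' @param params A [potential_params()] object.
#' @param r Separation(s), positive (vectorized). Interpreted as the chain's
#'   end-to-end size.
#' @param form `"sigma"` (default) or `"rm"`.
#' @return Potential energy at each `r`.
#' @examples
#' p <- potential_params()
#' lj_potential(p, p$sigma)  # 0 at the zero crossing
#' lj_potential(p, p$r_m)    # -epsilon at the minimum
#' @export
lj_potential <- function(params, r, form = c("sigma", "rm")) {
  form <- match.arg(form)
  check_separation(r)
  with(params, switch(form,
    sigma = a * epsilon * ((sigma / r)^m - (sigma / r)^n),
    rm = epsilon * (n / (m - n) * (r_m / r)^m - b * (r_m / r)^n)
  ))
}

#' Equilibrium separation of the effective potential
#'
#' The minimum of the potential sits at
#' \deqn{r_m = (m/n)^{1/(m-n)}\, \sigma,}
#' the size the chain relaxes to when the stretching and compressing forces
#' balance.
#'
#' @param params A [potential_params()] object.
#' @return The equilibrium separation \eqn{r_m}.
#' @examples
#' equilibrium_separation(potential_params())  # 2^(1/6)
#' @export
equilibrium_separation <- function(params) {
  params$r_m
}

#' Compression factor of the crowded chain
#'
#' \deqn{\beta = (m/n)^{1/(m-n)}}
#' relates the chain size without crowding (\eqn{r_m = \beta\sigma}) to its
#' compressed size (\eqn{\sigma}). Since `m > n`, always \eqn{\beta > 1}: the
#' chain under osmotic pressure from crowders is compressed relative to its
#' free size. In the limit \eqn{m \to n^+} the factor tends continuously to
#' \eqn{e^{1/n}}.
#'
#' @param m Short-range exponent (> n; vectorized).
#' @param n Long-range exponent (> 0).
#' @return The dimensionless compression factor.
#' @examples
#' compression_factor(12, 6)  # 2^(1/6)
#' @export
compression_factor <- function(m, n) {
  if (any(!(m > n)) || any(n <= 0)) {
    stop("exponents must satisfy m > n > 0")
  }
  (m / n)^(1 / (m - n))
}

#' Decompose the net force on the chain into stretching and compressing parts
#'
#' The derivative of the effective potential splits into the short-range
#' repulsive (stretching) component and the long-range attractive
#' (compressing) component:
#' \deqn{F_1 = -\,a\varepsilon m \sigma^m / r^{m+1} \quad (<0,\ \mathrm{stretching}),}
#' \deqn{F_2 = +\,a\varepsilon n \sigma^n / r^{n+1} \quad (>0,\ \mathrm{compressing}).}
#' The sign convention is the model's: negative = repulsive (expands the
#' chain), positive = attractive (compresses it). The net `F1 + F2` equals the
#' analytic derivative \eqn{dV/dr}; it vanishes at \eqn{r_m}, is negative for
#' \eqn{r < r_m} (net expansion) and positive for \eqn{r > r_m} (net
#' compression).
#'
#' @param params A [potential_params()] object.
#' @param r Separation(s), positive (vectorized).
#' @return A data frame with columns `r`, `F1`, `F2`, `net`.
#' @examples
#' p <- potential_params()
#' force_decomposition(p, p$r_m)$net  # ~0 at equilibrium
#' @export
force_decomposition <- function(params, r) {
  check_separation(r)
  F1 <- with(params, -a * epsilon * m * sigma^m / r^(m + 1))
  F2 <- with(params, a * epsilon * n * sigma^n / r^(n + 1))
  data.frame(r = r, F1 = F1, F2 = F2, net = F1 + F2)
}

#' Force ratio for an ellipsoidal chain envelope
#'
#' For a chain whose envelope is a prolate spheroid with long semi-axis `d`
#' and two equal short semi-axes `c`, the stretching and compressing forces
#' must balance in the approximate ratio
#' \deqn{F_1/F_2 = 1 - 2d/\sqrt{d^2 + c^2}.}
#' For a sphere (`c = d`) this gives \eqn{1 - \sqrt{2} \approx -0.41}; for
#' `c = d/2` it gives \eqn{1 - 2/\sqrt{1.25} \approx -0.79}. The ratio lies in
#' (-1, 0) for valid axes and is invariant under joint rescaling of the axes.
#'
#' The non-scale-invariant variant \eqn{1 - 2d/(d^2 + c^2)} (dimensionally
#' inconsistent, reproducing the printed anchors only at unit axes) is kept
#' behind `literal = TRUE` for auditability.
#'
#' @param d Long semi-axis (> 0).
#' @param c Short semi-axis (0 < c <= d).
#' @param literal Use the non-scale-invariant variant? Default `FALSE`.
#' @return The dimensionless ratio F1/F2.
#' @examples
#' ellipsoid_force_ratio(1, 1)    # -0.414: sphere
#' ellipsoid_force_ratio(2, 1)    # -0.789: 2:1 prolate spheroid
#' @export
ellipsoid_force_ratio <- function(d, c, literal = FALSE) {
  if (any(d <= 0) || any(c <= 0)) {
    stop("semi-axes must be positive")
  }
  if (any(c > d)) {
    stop("require c <= d (d is the long semi-axis)")
  }
  if (literal) {
    1 - 2 * d / (d^2 + c^2)
  } else {
    1 - 2 * d / sqrt(d^2 + c^2)
  }
}

check_separation <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("separation r must be positive")
  }
  invisible(r)
}
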