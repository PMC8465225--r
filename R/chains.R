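#' Wormlike-chain radius of gyration
#'
#' The Benoit-Doty expression for the radius of gyration of a wormlike chain
#' of contour length `l` and persistence length `lp`:
#' \deqn{R_g^2 = \frac{l L_p}{3} - L_p^2 + \frac{2 L_p^3}{l}
#'   - \frac{2 L_p^4}{l^2}\left(1 - e^{-l/L_p}\right).}
#' With the effective monomer length normalized to unity the contour length
#' is the monomer count, `l = N`. Two classic limits: at minimum stiffness
#' (`lp = 1`, `l` large) \eqn{R_g \to (l/3)^{1/2}}; at maximum stiffness
#' (`lp = l`, large) \eqn{R_g \to 0.263\, l \approx l/4}.
#'
#' @param l Contour length in monomer lengths (positive; vectorized).
#' @param lp Persistence length, same units (positive; recycled against `l`).
#'   Stiffness cannot exceed the contour length; `lp > l` is rejected.
#' @return The radius of gyration in monomer lengths.
#' @examples
#' wormlike_rg(20, 1)  # 2.4
#' wormlike_rg(40, 5)  # 6.9
#' @export
wormlike_rg <- function(l, lp) {
  if (any(l <= 0) || any(lp <= 0)) {
    stop("contour length l and persistence length lp must be positive")
  }
  if (any(lp > l)) {
    stop("persistence length cannot exceed the contour length (lp <= l)")
  }
  rg2 <- l * lp / 3 - lp^2 + 2 * lp^3 / l - 2 * lp^4 / l^2 * (1 - exp(-l / lp))
  if (any(rg2 <= 0)) {
    stop("wormlike-chain Rg^2 is non-positive; check l and lp")
  }
  sqrt(rg2)
}

#' Freely jointed chain end-to-end distance
#'
#' For an ideal (freely jointed) chain with scaling exponent 1/2 the
#' end-to-end distance and the radius of gyration are tied by
#' \eqn{R_{e\mbox{-}e} = \sqrt{6}\, R_g = A_0 \sqrt{6N}}, so the shape factor
#' \eqn{\alpha = R_g / R_{e\mbox{-}e} = 1/\sqrt{6} \approx 0.408} for any `N`.
#'
#' @param N Number of monomers (>= 1; vectorized).
#' @param A0 Effective monomer length. Default 1 (monomer-length units).
#' @return A list with `ree`, the companion `rg = ree / sqrt(6)`, and `alpha`.
#' @examples
#' freely_jointed_ree(6)$ree  # 6
#' @export
freely_jointed_ree <- function(N, A0 = 1) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(A0 <= 0)) stop("A0 must be positive")
  ree <- A0 * sqrt(6 * N)
  list(ree = ree, rg = ree / sqrt(6), alpha = 1 / sqrt(6))
}
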