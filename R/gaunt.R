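#' Real spherical harmonic Gaunt coefficients
#'
#' \code{gaunt} returns \eqn{\int Y_{l_1 m_1} Y_{l_2 m_2} Y_{LM}\,
#' d\Omega} for real spherical harmonics.  The coefficient vanishes
#' unless \eqn{|l_1-l_2| \le L \le l_1+l_2} and \eqn{l_1+l_2+L} is even
#' (parity).  Evaluation uses an exact tensor quadrature: the azimuthal
#' integral of the trigonometric factors on a uniform grid (trapezoid on
#' a periodic trig polynomial is exact given enough nodes) and a
#' Gauss-Legendre rule in \eqn{\cos\theta} complete for the polynomial
#' degree of the associated-Legendre product.  Results are cached.
#'
#' @param l1,m1,l2,m2,L,M integer quantum numbers with \code{|m| <= l}.
#' @return the Gaunt coefficient (numeric scalar).
#' @examples
#' gaunt(0, 0, 0, 0, 0, 0)          # 1/sqrt(4*pi)
#' gaunt(1, 0, 1, 0, 1, 0)          # 0 by parity
#' pair_weight(1, 1, 0)             # 3/(4*pi)
#' @export
gaunt <- function(l1, m1, l2, m2, L, M) {
  if (abs(m1) > l1 || abs(m2) > l2 || abs(M) > L) return(0)
  if (L < abs(l1 - l2) || L > l1 + l2) return(0)
  if ((l1 + l2 + L) %% 2 != 0) return(0)
  key <- paste(l1, m1, l2, m2, L, M)
  hit <- .gaunt_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- gaunt_quadrature(l1, m1, l2, m2, L, M)
  .gaunt_cache[[key]] <- val
  val
}

.gaunt_cache <- new.env(parent = emptyenv())

gaunt_quadrature <- function(l1, m1, l2, m2, L, M) {
  # azimuthal part: product of the three trig factors, exact trapezoid
  nphi <- 2 * (abs(m1) + abs(m2) + abs(M)) + 4
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi
  trig <- function(m) {
    if (m > 0) sqrt(2) * cos(m * phi)
    else if (m < 0) sqrt(2) * sin(-m * phi)
    else rep(1, nphi)
  }
  phi_int <- sum(trig(m1) * trig(m2) * trig(M)) * 2 * pi / nphi
  if (abs(phi_int) < 1e-14) return(0)
  # polar part: Gauss-Legendre in x = cos(theta), degree-complete
  ng <- l1 + l2 + L + 2
  gl <- pracma::gaussLegendre(ng, -1, 1)
  th <- assoc_legendre(l1, abs(m1), gl$x) * assoc_legendre(l2, abs(m2), gl$x) *
    assoc_legendre(L, abs(M), gl$x)
  theta_int <- sum(gl$w * th)
  norm3 <- ylm_norm(l1, m1) * ylm_norm(l2, m2) * ylm_norm(L, M)
  norm3 * theta_int * phi_int
}

# sqrt((2l+1)/(4 pi) * (l-|m|)!/(l+|m|)!), the theta-part normalization
# of the real spherical harmonic (the sqrt(2) for m != 0 lives in the
# trig factor).
ylm_norm <- function(l, m) {
  m <- abs(m)
  sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
}

# Unnormalized associated Legendre P_l^m(x), m >= 0, Condon-Shortley
# phase included; stable three-term recurrence, adequate for l <= ~30.
assoc_legendre <- function(l, m, x) {
  if (m > l) return(rep(0, length(x)))
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    pmm <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * somx2^m
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    p <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- p
  }
  pmmp1
}

#' Angular pair weight of a shell-pair product
#'
#' \code{pair_weight(l1, l2, L)} is \eqn{\sum_{m_1 m_2} G(l_1 m_1, l_2
#' m_2; L M)^2}, the total angular weight with which products of shells
#' \eqn{l_1} and \eqn{l_2} couple to multipole \eqn{L}.  The sum is
#' independent of \code{M}; the closed-form sum rule
#' \eqn{(2l_1+1)(2l_2+1)/(4\pi)\,\cdot 3j(l_1 l_2 L;000)^2} provides an
#' independent check.
#'
#' @param l1,l2,L integer angular momenta.
#' @param M fixed projection of the multipole component (any value gives
#'   the same sum; default 0).
#' @return numeric scalar, zero outside the coupling/parity window.
#' @export
pair_weight <- function(l1, l2, L, M = 0) {
  if (L < abs(l1 - l2) || L > l1 + l2 || (l1 + l2 + L) %% 2 != 0) return(0)
  key <- paste("w", l1, l2, L, M)
  hit <- .gaunt_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- 0
  for (m1 in -l1:l1) for (m2 in -l2:l2)
    s <- s + gaunt(l1, m1, l2, m2, L, M)^2
  .gaunt_cache[[key]] <- s
  s
}
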