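#' One-center Coulomb-metric integrals
#'
#' Coulomb interaction of two one-center densities \eqn{f(r) Y_{LM}} and
#' \eqn{g(r) Y_{LM}} sharing the real spherical harmonic \eqn{Y_{LM}}:
#' \deqn{(f Y_{LM} | g Y_{LM}) = \frac{4\pi}{2L+1}
#'   \int_0^\infty\!\!\int_0^\infty f(r_1) g(r_2)
#'   \frac{r_<^L}{r_>^{L+1}} r_1^2 r_2^2 \, dr_1 dr_2.}
#' The production path performs adaptive outer quadrature with the inner
#' cumulative integrals evaluated in closed form through (log-scaled)
#' incomplete gamma functions, which keeps the engine agnostic of the
#' radial representation.  For pure-power Gaussian terms the fully
#' analytic route \code{\link{radial_coulomb_analytic}} is available as an
#' independent cross-check and as a fast path for large Gram matrices.
#'
#' @param f,g \code{\link{radial_function}} objects.
#' @param L multipole order (non-negative integer).
#' @param rel.tol requested relative accuracy of the outer quadrature.
#' @return the Coulomb overlap, a scalar.
#' @examples
#' # self-repulsion of a unit s-type Gaussian charge, alpha = 1:
#' f <- coulomb_normalize(radial_function(1, 0, 1), 0)
#' radial_coulomb(f, f, 0)   # 1 by construction
#' @export
radial_coulomb <- function(f, g, L, rel.tol = 1e-12) {
  stopifnot(L >= 0)
  if (length(f$coef) == 0 || length(g$coef) == 0) return(0)
  integrand <- function(r) {
    out <- numeric(length(r))
    pos <- r > 0
    r <- r[pos]
    lr <- log(r)
    br2 <- outer(r^2, g$alpha)          # n_r x n_terms
    # inner integral over r2 < r1 :  A(r)/r^(L+1)
    low <- 0
    for (j in seq_along(g$coef)) {
      s <- (g$power[j] + L + 3) / 2
      lg <- log(0.5) - s * log(g$alpha[j]) + lgamma(s) +
        stats::pgamma(br2[, j], s, log.p = TRUE)
      low <- low + g$coef[j] * exp(lg - (L + 1) * lr)
    }
    # inner integral over r2 > r1 :  B(r)*r^L
    up <- 0
    for (j in seq_along(g$coef)) {
      tt <- (g$power[j] + 2 - L) / 2
      if (tt > 0) {
        lg <- log(0.5) - tt * log(g$alpha[j]) + lgamma(tt) +
          stats::pgamma(br2[, j], tt, lower.tail = FALSE, log.p = TRUE)
        up <- up + g$coef[j] * exp(lg + L * lr)
      } else {
        # generalized upper incomplete gamma for t <= 0 by recurrence
        up <- up + g$coef[j] * 0.5 * g$alpha[j]^(-tt) *
          uigamma(tt, br2[, j]) * r^L
      }
    }
    fr2 <- 0
    for (k in seq_along(f$coef))
      fr2 <- fr2 + f$coef[k] * r^(f$power[k] + 2) * exp(-f$alpha[k] * r^2)
    out[pos] <- fr2 * (low + up)
    out
  }
  # panel the radial axis at the Gaussian length scales so that adaptive
  # quadrature resolves widely separated exponents
  scales <- sort(unique(1 / sqrt(c(f$alpha, g$alpha))))
  breaks <- c(sort(unique(c(0, scales))), Inf)
  value <- 0
  abserr <- 0
  for (i in seq_len(length(breaks) - 1)) {
    res <- tryCatch(
      stats::integrate(integrand, breaks[i], breaks[i + 1],
                       rel.tol = rel.tol, abs.tol = 0,
                       subdivisions = 400L, stop.on.error = TRUE),
      error = function(e) stop("radial Coulomb quadrature failed on [",
                               signif(breaks[i], 4), ", ",
                               signif(breaks[i + 1], 4), "]: ",
                               conditionMessage(e)))
    value <- value + res$value
    abserr <- abserr + res$abs.error
  }
  val <- 4 * pi / (2 * L + 1) * value
  if (abserr > 1e-11 * max(abs(value), 1e-300) && abserr > 1e-280)
    stop(sprintf(
      "radial Coulomb quadrature did not converge: estimated relative error %.3e",
      abserr / max(abs(value), .Machine$double.xmin)))
  val
}

# Upper incomplete gamma Gamma(t, z), valid for any real t and z > 0:
# Gamma(0, z) is the exponential integral E1(z); non-positive t by
# upward recurrence.
uigamma <- function(t, z) {
  if (t > 0) return(gamma(t) * stats::pgamma(z, t, lower.tail = FALSE))
  if (t == 0) return(pracma::expint(z))
  (uigamma(t + 1, z) - z^t * exp(-z)) / t
}

#' Analytic Coulomb integral for pure-power Gaussian terms
#'
#' Closed form of the multipole-\code{L} Coulomb interaction for radial
#' functions whose terms are \eqn{c\, r^p e^{-\alpha r^2}} with
#' \eqn{p - L} even and non-negative (the case arising from products of
#' spherical Gaussian shells).  Used as the independent oracle for the
#' quadrature engine and as a fast path for large Gram matrices.
#'
#' @inheritParams radial_coulomb
#' @return the Coulomb overlap, a scalar.
#' @export
radial_coulomb_analytic <- function(f, g, L) {
  stopifnot(L >= 0)
  if (length(f$coef) == 0 || length(g$coef) == 0) return(0)
  chk <- c(f$power, g$power) - L
  if (any(chk < 0) || any(chk %% 2 != 0))
    stop("analytic form requires term powers p with p - L even and >= 0")
  tot <- 0
  for (k in seq_along(f$coef)) for (j in seq_along(g$coef)) {
    tot <- tot + f$coef[k] * g$coef[j] *
      (gto_halfspace(f$power[k], f$alpha[k], g$power[j], g$alpha[j], L) +
       gto_halfspace(g$power[j], g$alpha[j], f$power[k], f$alpha[k], L))
  }
  4 * pi / (2 * L + 1) * tot
}

# T(p,a; q,b) = int_0^inf r1^(p+1-L) e^(-a r1^2) [int_0^r1 r2^(q+L+2)
# e^(-b r2^2) dr2] dr1, evaluated exactly: the hypergeometric factor
# terminates because (p - L)/2 is a non-negative integer.
gto_halfspace <- function(p, a, q, b, L) {
  s <- (q + L + 3) / 2
  mu <- (p - L) / 2 + 1          # positive integer
  z <- b / (a + b)
  k <- 0:(mu - 1)
  poly <- sum(s / (s + k) * choose(mu - 1, k) * (-z)^k)
  0.25 * exp(lgamma(s + mu) - lgamma(s)) * gamma(s) / s /
    (a + b)^(s + mu) * (1 - z)^(-mu) * poly
}

#' Normalize a radial function in the Coulomb metric
#'
#' Scales \code{f} so its Coulomb self-overlap at multipole order \code{L}
#' equals one.
#'
#' @inheritParams radial_coulomb
#' @param method \code{"quadrature"} (production) or \code{"analytic"}.
#' @return the normalized \code{radial_function}.
#' @export
coulomb_normalize <- function(f, L, method = c("quadrature", "analytic")) {
  method <- match.arg(method)
  n2 <- if (method == "analytic") radial_coulomb_analytic(f, f, L)
        else radial_coulomb(f, f, L)
  if (!is.finite(n2) || n2 <= 0)
    stop("degenerate radial function: Coulomb self-overlap is not positive")
  radial_scale(f, 1 / sqrt(n2))
}

#' Coulomb-metric Gram matrix
#'
#' Symmetric matrix of pairwise Coulomb overlaps of radial functions at a
#' common multipole order \code{L}.  If the inputs are Coulomb-normalized
#' the diagonal is unity.
#'
#' @param functions list of \code{\link{radial_function}} objects.
#' @param L multipole order.
#' @param method integral route, see \code{\link{coulomb_normalize}}.
#' @return a symmetric positive-semidefinite matrix.
#' @export
coulomb_gram <- function(functions, L, method = c("quadrature", "analytic")) {
  method <- match.arg(method)
  n <- length(functions)
  ip <- if (method == "analytic") radial_coulomb_analytic else radial_coulomb
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    v <- ip(functions[[i]], functions[[j]], L)
    if (!is.finite(v))
      stop("numerical consistency error: non-finite Coulomb overlap at (",
           i, ",", j, ")")
    G[i, j] <- v
    G[j, i] <- v
  }
  G
}
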