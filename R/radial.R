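#' One-center radial functions
#'
#' A radial function is stored as a sum of Gaussian-type terms
#' \deqn{f(r) = \sum_k c_k \, r^{p_k} \, e^{-\alpha_k r^2},}
#' with integer powers \eqn{p_k \ge 0} and exponents \eqn{\alpha_k > 0}
#' (in bohr^-2).  This covers primitive GTOs (\eqn{p = l}), contractions,
#' and products of contracted shells (\eqn{p = l_1 + l_2}).  The nominal
#' angular momentum \code{L} fixes the multipole order used in the
#' Coulomb metric.
#'
#' @param coef numeric vector of term coefficients.
#' @param power integer vector of radial powers (same length).
#' @param alpha numeric vector of positive Gaussian exponents (same length).
#' @param L nominal angular momentum for Coulomb-metric purposes.
#' @return an object of class \code{radial_function}.
#' @examples
#' f <- radial_function(1, 0, 1.0, L = 0)   # s primitive, alpha = 1
#' radial_eval(f, c(0, 0.5, 1))
#' @export
radial_function <- function(coef, power, alpha, L = 0L) {
  coef <- as.numeric(coef)
  power <- as.integer(power)
  alpha <- as.numeric(alpha)
  n <- length(coef)
  if (length(power) != n || length(alpha) != n)
    stop("coef, power and alpha must have equal length")
  if (n > 0 && (any(!is.finite(alpha)) || any(alpha <= 0)))
    stop("all Gaussian exponents must be positive and finite")
  if (n > 0 && any(power < 0L))
    stop("radial powers must be non-negative integers")
  structure(list(coef = coef, power = power, alpha = alpha, L = as.integer(L)),
            class = "radial_function")
}

#' @export
print.radial_function <- function(x, ...) {
  if (length(x$coef) == 0) {
    cat("<radial_function: zero function, L =", x$L, ">\n")
    return(invisible(x))
  }
  cat("<radial_function: ", length(x$coef), " term(s), L = ", x$L, ">\n", sep = "")
  for (k in seq_along(x$coef))
    cat(sprintf("  %+.8g * r^%d * exp(-%.8g r^2)\n",
                x$coef[k], x$power[k], x$alpha[k]))
  invisible(x)
}

#' Evaluate a radial function on a grid
#'
#' @param f a \code{radial_function}.
#' @param r numeric vector of radii (bohr).
#' @return numeric vector \code{f(r)}.
#' @export
radial_eval <- function(f, r) {
  out <- numeric(length(r))
  for (k in seq_along(f$coef))
    out <- out + f$coef[k] * r^f$power[k] * exp(-f$alpha[k] * r^2)
  out
}

#' Pointwise product of two radial functions
#'
#' Term-wise product; powers add, exponents add.  The product of shells
#' with angular momenta l1 and l2 couples to total angular momentum L in
#' \code{seq(abs(l1 - l2), l1 + l2, by = 2)}; set \code{L} accordingly.
#'
#' @param f,g \code{radial_function} objects.
#' @param L nominal angular momentum for the product.
#' @return a \code{radial_function} with collected terms.
#' @export
radial_product <- function(f, g, L = 0L) {
  if (length(f$coef) == 0 || length(g$coef) == 0)
    return(radial_function(numeric(0), integer(0), numeric(0), L))
  coef <- as.vector(outer(f$coef, g$coef))
  power <- as.vector(outer(f$power, g$power, `+`))
  alpha <- as.vector(outer(f$alpha, g$alpha, `+`))
  radial_collect(radial_function(coef, power, alpha, L))
}

# Merge duplicate (power, alpha) terms; drop exact-zero coefficients.
radial_collect <- function(f) {
  if (length(f$coef) < 2) return(f)
  key <- paste(f$power, signif(f$alpha, 15))
  coef <- tapply(f$coef, key, sum)
  idx <- match(names(coef), key)
  keep <- coef != 0
  radial_function(as.numeric(coef[keep]), f$power[idx][keep],
                  f$alpha[idx][keep], f$L)
}

# Scale a radial function by a constant.
radial_scale <- function(f, s) {
  radial_function(f$coef * s, f$power, f$alpha, f$L)
}

# A single primitive r^l exp(-alpha r^2), unit coefficient.
radial_primitive <- function(alpha, l) {
  radial_function(1, l, alpha, L = l)
}

# Contraction column -> radial function: sum_k c_k N_k r^l exp(-a_k r^2)
# where N_k is the overlap normalization of the primitive (tabulation
# convention: coefficients refer to overlap-normalized primitives).
radial_contraction <- function(exponents, coefs, l) {
  nrm <- overlap_norm_primitive(exponents, l)
  radial_collect(radial_function(coefs * nrm, rep(l, length(exponents)),
                                 exponents, L = l))
}

# Overlap self-norm of r^l exp(-a r^2): <g|g> = int r^{2l+2} e^{-2ar^2} dr
#  = Gamma(l + 3/2) / (2 (2a)^{l + 3/2}); returns 1/sqrt of that.
overlap_norm_primitive <- function(alpha, l) {
  n2 <- gamma(l + 1.5) / (2 * (2 * alpha)^(l + 1.5))
  1 / sqrt(n2)
}

# Radial overlap matrix between primitives r^l e^{-a r^2} of equal l,
# for OVERLAP-NORMALIZED primitives: S_ij = (2 sqrt(ai aj)/(ai+aj))^{l+3/2}.
primitive_overlap_matrix <- function(alpha, l) {
  s <- outer(alpha, alpha, function(a, b) (2 * sqrt(a * b) / (a + b))^(l + 1.5))
  (s + t(s)) / 2
}
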