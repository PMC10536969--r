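# Independent oracles used across the suite.  These deliberately avoid
# the package's production code paths.

# Wigner 3j symbol at m1 = m2 = m3 = 0 (closed form via factorials).
w3j000 <- function(l1, l2, l3) {
  J <- l1 + l2 + l3
  if (J %% 2 != 0) return(0)
  if (l3 < abs(l1 - l2) || l3 > l1 + l2) return(0)
  g <- J / 2
  exp(0.5 * (lfactorial(J - 2 * l1) + lfactorial(J - 2 * l2) +
             lfactorial(J - 2 * l3) - lfactorial(J + 1))) *
    (-1)^g * exp(lfactorial(g) - lfactorial(g - l1) -
                 lfactorial(g - l2) - lfactorial(g - l3))
}

# Angular pair-weight sum rule for real (and complex) spherical
# harmonics: sum_{m1 m2} G^2 = (2l1+1)(2l2+1)/(4 pi) * 3j(l1 l2 L;000)^2.
pair_weight_3j <- function(l1, l2, L) {
  (2 * l1 + 1) * (2 * l2 + 1) / (4 * pi) * w3j000(l1, l2, L)^2
}

# Brute-force projection residual of column idx of a Gram matrix onto
# the span of the selected indices (full-matrix projector).
projection_residual <- function(G, selected, idx) {
  if (length(selected) == 0) return(G[idx, idx])
  Gs <- G[selected, selected, drop = FALSE]
  gv <- G[selected, idx]
  x <- solve(Gs + diag(1e-14 * max(diag(Gs)), nrow(Gs)), gv)
  as.numeric(G[idx, idx] - 2 * sum(x * gv) + t(x) %*% Gs %*% x)
}

# Largest brute-force residual over all non-selected columns.
max_rejected_residual <- function(G, selected) {
  rej <- setdiff(seq_len(nrow(G)), selected)
  if (length(rej) == 0) return(0)
  max(vapply(rej, function(i) projection_residual(G, selected, i),
             numeric(1)))
}

# Coulomb interaction of two unit-charge concentric Gaussian s
# distributions, from the standard plain-Gaussian integral
# (e^{-a r^2} | e^{-b r^2}) = 2 pi^{5/2} / (a b sqrt(a + b)) scaled by
# the (a/pi)^{3/2} charge normalizations: (2/sqrt(pi)) sqrt(ab/(a+b)).
gaussian_charge_interaction <- function(a, b) {
  2 / sqrt(pi) * sqrt(a * b / (a + b))
}

# Shell counts per l of an element basis, as a plain named vector,
# derived by brute enumeration of (shell, column) tuples.
shell_counts <- function(basis) {
  out <- integer(0)
  for (sh in basis$shells) {
    key <- as.character(sh$l)
    out[key] <- (if (is.na(out[key])) 0L else out[key]) +
      ncol(sh$coefficients)
  }
  out[order(as.integer(names(out)))]
}

# Per-l count comparison: TRUE when a's counts are <= b's for every l.
counts_nested <- function(a, b) {
  ca <- shell_counts(a); cb <- shell_counts(b)
  all(vapply(names(ca), function(k) {
    cbk <- cb[k]
    !is.na(cbk) && ca[k] <= cbk
  }, logical(1)))
}

# A small deterministic random PSD matrix of given size and rank.
random_psd <- function(n, rank, seed) {
  set.seed(seed)
  B <- matrix(rnorm(n * rank), n, rank)
  G <- B %*% t(B)
  (G + t(G)) / 2
}

analytic_config <- function(...) generation_config(method = "analytic", ...)
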