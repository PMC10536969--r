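#' Pivoted Cholesky decomposition with a stopping threshold
#'
#' Diagonal-pivoted Cholesky factorization of a symmetric
#' positive-semidefinite Gram matrix, stopped when the largest remaining
#' (residual) diagonal element falls below \code{tau}.  The selected
#' pivots span the matrix to \code{tau}: every non-selected function has
#' projection residual (residual Coulomb self-overlap, for a Coulomb
#' Gram) at most \code{tau} onto the selected span.
#'
#' Optional \code{weights} reorder the pivoting by importance: the pivot
#' chosen at each step maximizes \code{weights * diag}, while the
#' stopping test uses the unweighted residual diagonal, so the
#' \code{tau} fidelity guarantee is independent of the weighting.
#'
#' @param gram symmetric PSD matrix.
#' @param tau positive stopping threshold on the residual diagonal.
#' @param weights optional positive per-function pivot priorities.
#' @return integer vector of selected pivot indices, in pivot order,
#'   with attribute \code{"residual"} holding the final residual
#'   diagonal.
#' @examples
#' G <- diag(3)
#' pivoted_cholesky(G, 0.5)        # all three selected
#' pivoted_cholesky(matrix(1, 2, 2), 1e-7)   # rank one: one pivot
#' @export
pivoted_cholesky <- function(gram, tau, weights = NULL) {
  stopifnot(tau > 0)
  n <- nrow(gram)
  if (n == 0) return(integer(0))
  if (max(abs(gram - t(gram))) > 1e-10 * max(abs(gram), 1))
    stop("Gram matrix is not symmetric")
  d <- diag(gram)
  if (any(d < -1e-10 * max(d, 0)))
    stop("PSD violation: negative diagonal in Gram matrix")
  if (is.null(weights)) weights <- rep(1, n)
  Lfac <- matrix(0, n, n)
  piv <- integer(0)
  avail <- rep(TRUE, n)
  d0max <- max(d, 0)
  for (step in seq_len(n)) {
    if (any(d[avail] < -1e-10 * max(d0max, 1)))
      stop("PSD violation: negative residual diagonal during factorization")
    d_av <- ifelse(avail, d, -Inf)
    if (max(d_av) < tau) break
    # pivot by weighted importance among candidates still above threshold
    score <- ifelse(avail & d >= 0, weights * pmax(d, 0), -Inf)
    smax <- max(score)
    # tie-break: lowest index within 1e-14 of the maximum score
    j <- which(score >= smax - 1e-14 * max(smax, 1))[1]
    if (d[j] < tau) {
      # the top-priority candidate is converged; fall back to the raw
      # residual so the stopping guarantee stays unweighted
      j <- which(avail & d >= max(d_av) - 1e-14 * max(d_av, 1))[1]
    }
    piv <- c(piv, j)
    avail[j] <- FALSE
    ell <- sqrt(d[j])
    row <- (gram[, j] - Lfac %*% Lfac[j, ]) / ell
    Lfac[, step] <- ifelse(avail, row, 0)
    Lfac[j, step] <- 0
    d[avail] <- d[avail] - Lfac[avail, step]^2
    d[j] <- 0
  }
  res <- diag(gram)
  res[piv] <- 0
  if (length(piv) > 0) {
    sel_rows <- Lfac[, seq_along(piv), drop = FALSE]
    res <- diag(gram) - rowSums(sel_rows^2)
    res[piv] <- 0
  }
  attr(piv, "residual") <- pmax(res, 0)
  piv
}
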