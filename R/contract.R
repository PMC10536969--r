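#' Canonical inverse square root of a Coulomb metric
#'
#' Symmetric \eqn{V^{-1/2}} over the eigenspace with eigenvalues at
#' least \code{lindep} times the largest eigenvalue.  On a
#' rank-deficient metric the result satisfies \eqn{V^{-1/2} V V^{-1/2} =
#' P}, the orthogonal projector onto the retained space.
#'
#' @param V symmetric positive-semidefinite matrix.
#' @param lindep relative linear-dependence cutoff (default \code{1e-7}).
#' @return matrix of the same dimension as \code{V}.
#' @export
orthogonalizer <- function(V, lindep = 1e-7) {
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  keep <- max(eg$values) > 0 & eg$values >= lindep * max(eg$values)
  if (!any(keep))
    stop("degenerate metric: all eigenvalues below the linear-dependence cutoff")
  U <- eg$vectors[, keep, drop = FALSE]
  U %*% (t(U) / sqrt(eg$values[keep]))
}

# Coulomb-normalized radial functions of the ABS shells at angular
# momentum l (one per contraction column), plus their raw exponents for
# primitive sets.
aux_radial_at_l <- function(abs_basis, l, method = "quadrature") {
  shells <- Filter(function(s) s$l == l, abs_basis$shells)
  if (length(shells) == 0)
    stop("angular momentum ", l, " not present in the auxiliary basis")
  fns <- list(); expo <- numeric(0); prim <- TRUE
  for (sh in shells) {
    for (j in seq_len(ncol(sh$coefficients))) {
      f <- radial_contraction(sh$exponents, sh$coefficients[, j], sh$l)
      fns[[length(fns) + 1L]] <- coulomb_normalize(f, l, method = method)
      if (length(sh$exponents) == 1 && ncol(sh$coefficients) == 1) {
        expo <- c(expo, sh$exponents)
      } else prim <- FALSE
    }
  }
  list(fns = fns, exponents = if (prim) expo else NULL)
}

# Ordered-pair product records of the contracted OBS functions coupling
# to angular momentum l: product radial function, angular pair weight
# and ordered-pair multiplicity.
obs_product_records <- function(obs, l) {
  fns <- basis_radial_functions(obs)
  recs <- list()
  for (i in seq_along(fns)) for (j in i:length(fns)) {
    l1 <- fns[[i]]$l; l2 <- fns[[j]]$l
    if (l < abs(l1 - l2) || l > l1 + l2 || (l1 + l2 + l) %% 2 != 0) next
    w <- pair_weight(l1, l2, l)
    if (w == 0) next
    recs[[length(recs) + 1L]] <- list(
      fn = radial_product(fns[[i]]$fn, fns[[j]]$fn, l),
      weight = w, mult = if (i == j) 1 else 2)
  }
  recs
}

#' Importance subblock L of the three-index integral matrix W
#'
#' The importance matrix \eqn{W = J^T J} (with \eqn{J = I V^{-1/2}} the
#' orthogonalized three-index integrals over all one-center orbital
#' products) is block diagonal in the angular momentum and projection of
#' the auxiliary functions, with identical blocks across \eqn{m}.  This
#' routine computes the \eqn{m = 0} subblock \eqn{L} for one auxiliary
#' angular momentum radially: products of contracted orbital functions
#' enter with their angular \code{\link{pair_weight}} and ordered-pair
#' multiplicity, summed over all ordered \eqn{m}-component pairs.  The
#' explicit all-\eqn{m} construction \code{\link{build_importance_full}}
#' is the brute-force cross-check.
#'
#' @param obs orbital \code{\link{element_basis}}.
#' @param abs_basis auxiliary \code{\link{element_basis}} (primitive).
#' @param l auxiliary angular momentum, present in \code{abs_basis}.
#' @param lindep linear-dependence cutoff for the metric.
#' @param method integral route (\code{"quadrature"} or
#'   \code{"analytic"}).
#' @return list with the subblock \code{L}, the radial metric \code{V},
#'   the orthogonalized weighted integrals \code{J} (rows scaled by the
#'   square root of weight times multiplicity), and the auxiliary
#'   exponents when the set is primitive.
#' @export
build_importance_subblock <- function(obs, abs_basis, l, lindep = 1e-7,
                                      method = c("quadrature", "analytic")) {
  method <- match.arg(method)
  aux <- aux_radial_at_l(abs_basis, l, method = method)
  recs <- obs_product_records(obs, l)
  na <- length(aux$fns)
  V <- coulomb_gram(aux$fns, l, method = method)
  X <- orthogonalizer(V, lindep)
  ip <- if (method == "analytic") radial_coulomb_analytic else radial_coulomb
  if (length(recs) == 0) {
    J <- matrix(0, 0, na)
  } else {
    I3 <- t(vapply(recs, function(rec)
      vapply(aux$fns, function(a) ip(rec$fn, a, l), numeric(1)),
      numeric(na)))
    I3 <- matrix(I3, nrow = length(recs), ncol = na)
    d <- vapply(recs, function(r) r$mult * r$weight, numeric(1))
    J <- sqrt(d) * (I3 %*% X)
  }
  Lmat <- crossprod(J)
  Lmat <- (Lmat + t(Lmat)) / 2
  list(L = Lmat, V = V, J = J, exponents = aux$exponents)
}

#' Explicit all-m importance matrix (brute-force path)
#'
#' Builds the full \eqn{W = J^T J} over every orbital component pair
#' \eqn{(\mu m_\mu, \nu m_\nu)} (ordered) and every auxiliary component
#' \eqn{(A, l, m)}, with real-harmonic Gaunt angular factors.  Intended
#' for small systems: it verifies the angular block structure of
#' \eqn{W} and the radial fast path of
#' \code{\link{build_importance_subblock}}.
#'
#' @inheritParams build_importance_subblock
#' @return list with \code{W}, column labels \code{l} and \code{m}, and
#'   the block-deviation diagnostic \code{offblock} (largest magnitude
#'   of an element between different \eqn{(l, m)} blocks).
#' @export
build_importance_full <- function(obs, abs_basis, lindep = 1e-7,
                                  method = c("quadrature", "analytic")) {
  method <- match.arg(method)
  ip <- if (method == "analytic") radial_coulomb_analytic else radial_coulomb
  obs_fns <- basis_radial_functions(obs)
  # auxiliary components across all l present
  ls <- sort(unique(vapply(abs_basis$shells, `[[`, integer(1), "l")))
  aux_l <- integer(0); aux_m <- integer(0); aux_rad <- integer(0)
  rad_fns <- list(); rad_l <- integer(0)
  for (l in ls) {
    aux <- aux_radial_at_l(abs_basis, l, method = method)
    for (k in seq_along(aux$fns)) {
      rad_fns[[length(rad_fns) + 1L]] <- aux$fns[[k]]
      rad_l <- c(rad_l, l)
      for (m in -l:l) {
        aux_l <- c(aux_l, l); aux_m <- c(aux_m, m)
        aux_rad <- c(aux_rad, length(rad_fns))
      }
    }
  }
  ncomp <- length(aux_l)
  # radial metric blocks and orthogonalizer, replicated across m
  Vfull <- matrix(0, ncomp, ncomp)
  for (a in seq_len(ncomp)) for (b in seq_len(ncomp)) {
    if (aux_l[a] == aux_l[b] && aux_m[a] == aux_m[b])
      Vfull[a, b] <- ip(rad_fns[[aux_rad[a]]], rad_fns[[aux_rad[b]]],
                        aux_l[a])
  }
  X <- orthogonalizer(Vfull, lindep)
  # ordered orbital component pairs
  comp <- list()
  for (i in seq_along(obs_fns)) for (m in -obs_fns[[i]]$l:obs_fns[[i]]$l)
    comp[[length(comp) + 1L]] <- list(i = i, l = obs_fns[[i]]$l, m = m)
  I3 <- matrix(0, length(comp)^2, ncomp)
  row <- 0L
  radint <- new.env(parent = emptyenv())
  for (c1 in comp) for (c2 in comp) {
    row <- row + 1L
    for (a in seq_len(ncomp)) {
      g <- gaunt(c1$l, c1$m, c2$l, c2$m, aux_l[a], aux_m[a])
      if (g == 0) next
      key <- paste(min(c1$i, c2$i), max(c1$i, c2$i), aux_rad[a], aux_l[a])
      r <- radint[[key]]
      if (is.null(r)) {
        prod_fn <- radial_product(obs_fns[[c1$i]]$fn, obs_fns[[c2$i]]$fn,
                                  aux_l[a])
        r <- ip(prod_fn, rad_fns[[aux_rad[a]]], aux_l[a])
        radint[[key]] <- r
      }
      I3[row, a] <- g * r
    }
  }
  J <- I3 %*% X
  W <- crossprod(J)
  same <- outer(aux_l, aux_l, `==`) & outer(aux_m, aux_m, `==`)
  offblock <- if (all(same)) 0 else max(abs(W[!same]))
  list(W = W, l = aux_l, m = aux_m, offblock = offblock)
}

#' Contract one angular block by eigendecomposition of L
#'
#' Eigendecomposition \eqn{L = U \Lambda U^T}; eigenvectors with
#' \eqn{\lambda_i \ge \epsilon} are kept (the threshold is absolute) and
#' back-transformed to the non-orthogonal auxiliary basis as
#' \eqn{C = V^{-1/2} U}.  Dropping the rest changes the orthogonalized
#' three-index integrals by exactly \eqn{\|J - J U U^T\|_F^2 =
#' \sum_{dropped} \lambda_i}, so \code{epsilon} bounds the integral
#' reproduction error.  Within eigenvalue clusters degenerate to
#' \code{1e-12} relative, the whole cluster is kept if any member
#' passes, avoiding orientation dependence of the eigenvectors.
#'
#' @param block output of \code{\link{build_importance_subblock}} (or a
#'   list with elements \code{L} and \code{V}).
#' @param epsilon absolute eigenvalue threshold.
#' @param lindep linear-dependence cutoff for \eqn{V^{-1/2}}.
#' @return list of class \code{contraction_block}: \code{values} (all
#'   eigenvalues, descending), \code{kept} (indices kept), \code{U},
#'   \code{C}, and \code{epsilon}.
#' @export
contract_block <- function(block, epsilon, lindep = 1e-7) {
  stopifnot(epsilon >= 0)
  eg <- eigen(block$L, symmetric = TRUE)
  vals <- eg$values
  keep <- vals >= epsilon
  if (any(keep) && !all(keep)) {
    # degenerate-cluster closure
    vmax <- max(vals)
    for (i in seq_len(length(vals) - 1)) {
      if (keep[i] && !keep[i + 1] &&
          abs(vals[i] - vals[i + 1]) < 1e-12 * vmax)
        keep[i + 1] <- TRUE
    }
  }
  if (!any(keep)) {
    warning("no eigenvalue reaches epsilon = ", epsilon,
            "; block dropped")
    return(structure(list(values = vals, kept = integer(0),
                          U = eg$vectors[, 0, drop = FALSE],
                          C = matrix(0, nrow(block$L), 0),
                          epsilon = epsilon),
                     class = "contraction_block"))
  }
  kept <- which(keep)
  U <- eg$vectors[, kept, drop = FALSE]
  C <- orthogonalizer(block$V, lindep) %*% U
  structure(list(values = vals, kept = kept, U = U, C = C,
                 epsilon = epsilon),
            class = "contraction_block")
}

#' Rescale contraction coefficients to the tabulation convention
#'
#' Columns of \code{C} are Coulomb-orthonormal combinations of
#' Coulomb-normalized primitives.  Basis-set files tabulate coefficients
#' against overlap-normalized primitives, which amounts to scaling
#' \eqn{C_{\mu i}} by the square root of the Gaussian exponent
#' \eqn{\sqrt{\alpha_\mu}} and renormalizing every column to unit
#' overlap-metric self-norm.  Either normalization spans the same
#' fitting space; the tabulation normalization is what the file formats
#' expect.
#'
#' @param C coefficient matrix (primitives x contractions).
#' @param exponents primitive Gaussian exponents (rows of \code{C}).
#' @param l angular momentum of the shell.
#' @return rescaled coefficient matrix.
#' @export
rescale_to_overlap_convention <- function(C, exponents, l) {
  stopifnot(nrow(C) == length(exponents))
  Cp <- C * sqrt(exponents)
  S <- primitive_overlap_matrix(exponents, l)
  nrm <- sqrt(pmax(colSums(Cp * (S %*% Cp)), .Machine$double.xmin))
  sweep(Cp, 2, nrm, "/")
}

#' Contract a primitive auxiliary basis
#'
#' Runs \code{\link{build_importance_subblock}} and
#' \code{\link{contract_block}} for every angular momentum of the
#' auxiliary basis and assembles the contracted
#' \code{\link{element_basis}} in the tabulation convention.
#'
#' @param obs orbital basis.
#' @param abs_basis primitive auxiliary basis.
#' @param epsilon eigenvalue threshold.
#' @param lindep linear-dependence cutoff.
#' @param method integral route.
#' @return list: \code{basis} (contracted ABS) and \code{spectra}
#'   (per-l eigenvalues and kept counts).
#' @export
contract_abs <- function(obs, abs_basis, epsilon, lindep = 1e-7,
                         method = c("quadrature", "analytic")) {
  method <- match.arg(method)
  ls <- sort(unique(vapply(abs_basis$shells, `[[`, integer(1), "l")))
  shells <- list()
  spectra <- list()
  for (l in ls) {
    blk <- build_importance_subblock(obs, abs_basis, l, lindep = lindep,
                                     method = method)
    if (is.null(blk$exponents))
      stop("contract_abs requires a primitive auxiliary basis")
    cb <- contract_block(blk, epsilon, lindep = lindep)
    spectra[[as.character(l)]] <- list(l = l, values = cb$values,
                                       kept = length(cb$kept))
    if (length(cb$kept) == 0) next
    coef <- rescale_to_overlap_convention(cb$C, blk$exponents, l)
    shells[[length(shells) + 1L]] <- gaussian_shell(l, blk$exponents, coef)
  }
  list(basis = element_basis(abs_basis$symbol, shells, role = "ABS",
                             Z = abs_basis$Z),
       spectra = spectra)
}
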