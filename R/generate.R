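#' Generation controls for the primitive auxiliary basis
#'
#' @param tau pivoted-Cholesky selection threshold (default \code{1e-7}).
#' @param prescreen prescreen the product pool with a pivoted Cholesky
#'   of the (angularly weighted) product Coulomb Gram (default
#'   \code{TRUE}).
#' @param dedup_tol relative tolerance for merging near-identical
#'   candidate exponents within an angular momentum (default
#'   \code{1e-6}).
#' @param lindep linear-dependence threshold for metric
#'   orthogonalization (default \code{1e-7}).
#' @param method integral route for Gram construction:
#'   \code{"quadrature"} (radial-representation-agnostic production
#'   engine) or \code{"analytic"} (closed-form GTO fast path).
#' @return a list of class \code{generation_config}.
#' @export
generation_config <- function(tau = 1e-7, prescreen = TRUE,
                              dedup_tol = 1e-6, lindep = 1e-7,
                              method = c("quadrature", "analytic")) {
  stopifnot(tau > 0, dedup_tol > 0, lindep > 0)
  structure(list(tau = tau, prescreen = prescreen, dedup_tol = dedup_tol,
                 lindep = lindep, method = match.arg(method)),
            class = "generation_config")
}

#' Enumerate candidate auxiliary radial functions from orbital products
#'
#' Products of contracted orbital shells with angular momenta
#' \eqn{l_1, l_2} couple to every \eqn{L} with \eqn{|l_1-l_2| \le L \le
#' l_1+l_2} and \eqn{l_1+l_2+L} even.  In the primitive-sum
#' representation (the default) each primitive exponent pair
#' \eqn{\alpha_i + \alpha_j} becomes a candidate \eqn{r^L
#' e^{-(\alpha_i+\alpha_j) r^2}}, deduplicated per \eqn{L} within
#' \code{dedup_tol}; the exact contracted products (which carry
#' \eqn{r^{l_1+l_2}} prefactors) are available with
#' \code{representation = "product"} for metric studies.  Candidate
#' angular weights accumulate \code{\link{pair_weight}} over the
#' contributing shell pairs (doubled for distinct shells, matching the
#' ordered-product count).
#'
#' @param obs an \code{\link{element_basis}} with role \code{"OBS"}.
#' @param config a \code{\link{generation_config}}.
#' @param representation \code{"primitive-sum"} or \code{"product"}.
#' @return named list mapping \code{L} (as character) to a data frame
#'   with columns \code{exponent} (NA for product representation),
#'   \code{weight}, and a list column \code{fn} of Coulomb-normalized
#'   \code{\link{radial_function}}s.
#' @export
enumerate_candidates <- function(obs, config = generation_config(),
                                 representation = c("primitive-sum",
                                                    "product")) {
  representation <- match.arg(representation)
  if (length(obs$shells) == 0) stop("empty orbital basis")
  shells <- obs$shells
  cand <- list()   # per L: list(exponent=..., weight=..., fn=...)
  add <- function(L, exponent, weight, fn) {
    key <- as.character(L)
    cand[[key]][[length(cand[[key]]) + 1L]] <<-
      list(exponent = exponent, weight = weight, fn = fn)
  }
  for (i in seq_along(shells)) for (j in i:length(shells)) {
    l1 <- shells[[i]]$l; l2 <- shells[[j]]$l
    mult <- if (i == j) 1 else 2
    for (L in seq(abs(l1 - l2), l1 + l2, by = 2)) {
      w <- mult * pair_weight(l1, l2, L)
      if (w == 0) next
      if (representation == "primitive-sum") {
        sums <- unique(as.vector(outer(shells[[i]]$exponents,
                                       shells[[j]]$exponents, `+`)))
        for (a in sums) add(L, a, w, NULL)
      } else {
        ci <- shells[[i]]$coefficients; cj <- shells[[j]]$coefficients
        for (u in seq_len(ncol(ci))) {
          vs <- if (i == j) u:ncol(cj) else seq_len(ncol(cj))
          for (v in vs) {
            fi <- radial_contraction(shells[[i]]$exponents, ci[, u], l1)
            fj <- radial_contraction(shells[[j]]$exponents, cj[, v], l2)
            add(L, NA_real_, w, radial_product(fi, fj, L))
          }
        }
      }
    }
  }
  out <- list()
  for (key in as.character(sort(as.integer(names(cand))))) {
    recs <- cand[[key]]
    L <- as.integer(key)
    expo <- vapply(recs, function(r) r$exponent, numeric(1))
    wt <- vapply(recs, function(r) r$weight, numeric(1))
    if (representation == "primitive-sum") {
      ord <- order(expo)
      expo <- expo[ord]; wt <- wt[ord]
      keep_e <- numeric(0); keep_w <- numeric(0)
      for (k in seq_along(expo)) {
        if (length(keep_e) > 0 &&
            abs(expo[k] - keep_e[length(keep_e)]) <=
              config$dedup_tol * keep_e[length(keep_e)]) {
          keep_w[length(keep_w)] <- keep_w[length(keep_w)] + wt[k]
        } else {
          keep_e <- c(keep_e, expo[k]); keep_w <- c(keep_w, wt[k])
        }
      }
      fns <- lapply(keep_e, function(a)
        coulomb_normalize(radial_primitive(a, L), L, method = "analytic"))
      out[[key]] <- data.frame(exponent = keep_e, weight = keep_w)
      out[[key]]$fn <- fns
    } else {
      fns <- lapply(recs, function(r)
        coulomb_normalize(r$fn, L, method = "analytic"))
      out[[key]] <- data.frame(exponent = expo, weight = wt)
      out[[key]]$fn <- fns
    }
  }
  out
}

#' Prescreen the candidate pool by pivoted Cholesky of the product Gram
#'
#' Per angular momentum, the Coulomb Gram of the normalized candidates
#' is decomposed with \code{\link{pivoted_cholesky}}; the angular pair
#' weights act as pivot priorities while the stopping test retains the
#' unweighted fidelity guarantee, so the surviving pool spans every
#' candidate to within \code{tau} in the Coulomb metric.
#'
#' @param candidates output of \code{\link{enumerate_candidates}}.
#' @param config a \code{\link{generation_config}}; with
#'   \code{prescreen = FALSE} the input is returned unchanged.
#' @return a candidate map of the same shape with reduced rows.
#' @export
prescreen_products <- function(candidates, config = generation_config()) {
  if (!config$prescreen) return(candidates)
  out <- list()
  for (key in names(candidates)) {
    df <- candidates[[key]]
    L <- as.integer(key)
    G <- coulomb_gram(df$fn, L, method = config$method)
    piv <- pivoted_cholesky(G, config$tau, weights = df$weight)
    out[[key]] <- df[sort(piv), , drop = FALSE]
  }
  out
}

#' Select the primitive auxiliary basis by pivoted Cholesky
#'
#' Per angular momentum \eqn{L}, the Coulomb Gram of the normalized
#' candidate radial functions is decomposed by
#' \code{\link{pivoted_cholesky}} to \code{tau}; the selected candidates
#' become primitive shells of that \eqn{L}.  Every rejected candidate is
#' reproduced by the selected span with residual Coulomb self-overlap at
#' most \code{tau}.
#'
#' @param candidates output of \code{\link{enumerate_candidates}} (or of
#'   \code{\link{prescreen_products}}).
#' @param config a \code{\link{generation_config}}.
#' @param symbol,Z element identity for the returned basis.
#' @return an \code{\link{element_basis}} with role \code{"ABS"},
#'   one single-primitive shell per selected exponent.
#' @export
select_primitive_abs <- function(candidates, config = generation_config(),
                                 symbol = "X", Z = 1L) {
  if (length(candidates) == 0) stop("empty candidate map")
  shells <- list()
  for (key in names(candidates)) {
    df <- candidates[[key]]
    L <- as.integer(key)
    G <- coulomb_gram(df$fn, L, method = config$method)
    piv <- pivoted_cholesky(G, config$tau)
    if (length(piv) == 0) {
      warning("no candidate at L = ", L, " survives tau = ", config$tau,
              "; shell omitted")
      next
    }
    if (anyNA(df$exponent[piv]))
      stop("primitive shell emission requires the primitive-sum representation")
    for (a in sort(df$exponent[piv], decreasing = TRUE))
      shells[[length(shells) + 1L]] <- gaussian_shell(L, a, 1)
  }
  element_basis(symbol, shells, role = "ABS", Z = Z)
}
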