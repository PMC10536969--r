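#' Occupied-shell maximum angular momentum of an element
#'
#' Two tabulated conventions for the maximum angular momentum occupied
#' in the atomic ground state: \code{"yang"} assigns 0, 1, 2, 3 for
#' \eqn{Z \le 2}, \eqn{3 \le Z \le 18}, \eqn{19 \le Z \le 54} and
#' \eqn{Z \ge 55}; \code{"stoychev"} uses the ranges \eqn{Z \le 2},
#' \eqn{3 \le Z \le 20}, \eqn{21 \le Z \le 56} and \eqn{Z \ge 57}.  The
#' conventions differ at K/Ca and Cs/Ba, where \code{"yang"} already
#' counts the d and f shells.  Default \code{"yang"}.
#'
#' @param Z atomic number (>= 1).
#' @param convention \code{"yang"} or \code{"stoychev"}.
#' @return integer in 0..3.
#' @export
l_occ_max <- function(Z, convention = c("yang", "stoychev")) {
  convention <- match.arg(convention)
  if (Z < 1) stop("atomic number must be at least 1")
  breaks <- if (convention == "yang") c(2, 18, 54) else c(2, 20, 56)
  sum(Z > breaks)
}

#' Angular-momentum cutoff for pruning the auxiliary basis
#'
#' The first-principles rule keeps auxiliary functions able to expand
#' (i) products of occupied atomic orbitals with each other and (ii)
#' products of occupied orbitals with any orbital-basis function:
#' \deqn{l_{keep}^{max} = \max(2 l_{occ}^{max},\; l_{occ}^{max} +
#'   l_{OBS}^{max}) + l_{inc}.}
#' The comparator rule used by earlier automated generators ignores the
#' atomic angular momentum: \eqn{l_{keep}^{max} = l_{OBS}^{max} +
#' l_{inc}}.  The first rule never cuts lower than the second at equal
#' \code{l_inc}.
#'
#' @param l_occ occupied-shell maximum angular momentum.
#' @param l_obs orbital-basis maximum angular momentum.
#' @param l_inc non-negative safety increment.
#' @param scheme \code{"eq9"} (first-principles, default) or
#'   \code{"eq10"} (comparator).
#' @return integer cutoff.
#' @export
l_keep_max <- function(l_occ, l_obs, l_inc = 0L,
                       scheme = c("eq9", "eq10")) {
  scheme <- match.arg(scheme)
  stopifnot(l_occ >= 0, l_obs >= 0, l_inc >= 0)
  base <- switch(scheme,
                 eq9 = max(2L * l_occ, l_occ + l_obs),
                 eq10 = l_obs)
  as.integer(base + l_inc)
}

#' Prune high-angular-momentum auxiliary shells
#'
#' Removes every shell with angular momentum above
#' \code{\link{l_keep_max}}; other shells are untouched.  Idempotent.
#'
#' @param abs_basis auxiliary \code{\link{element_basis}}.
#' @param Z atomic number of the element.
#' @param l_obs maximum angular momentum of the orbital basis.
#' @param l_inc safety increment.
#' @param scheme pruning rule, see \code{\link{l_keep_max}}.
#' @param convention occupied-shell convention, see
#'   \code{\link{l_occ_max}}.
#' @return the pruned \code{element_basis}.
#' @export
prune_abs <- function(abs_basis, Z, l_obs, l_inc = 0L,
                      scheme = c("eq9", "eq10"),
                      convention = c("yang", "stoychev")) {
  scheme <- match.arg(scheme)
  convention <- match.arg(convention)
  cutoff <- l_keep_max(l_occ_max(Z, convention), l_obs, l_inc, scheme)
  keep <- Filter(function(s) s$l <= cutoff, abs_basis$shells)
  if (length(keep) == 0)
    warning("pruning removed every auxiliary shell (cutoff l = ", cutoff, ")")
  element_basis(abs_basis$symbol, keep, role = abs_basis$role,
                Z = abs_basis$Z)
}
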