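#' Contracted spherical Gaussian shells and element basis sets
#'
#' A \code{gaussian_shell} holds one angular momentum block: a vector of
#' positive exponents (bohr^-2, sorted decreasing) and an
#' \code{n_prim x n_contr} coefficient matrix.  Coefficients refer to
#' overlap-normalized primitives, the convention in which Gaussian basis
#' sets are tabulated.  An \code{element_basis} is a list of shells for
#' one element together with its symbol, atomic number and role
#' (orbital basis, \code{"OBS"}, or auxiliary basis, \code{"ABS"}).
#'
#' @param l angular momentum, integer >= 0.
#' @param exponents positive Gaussian exponents.
#' @param coefficients numeric matrix (n_prim x n_contr) or vector
#'   (taken as one contraction column).
#' @return a \code{gaussian_shell}.
#' @export
gaussian_shell <- function(l, exponents, coefficients) {
  l <- as.integer(l)
  if (l < 0) stop("angular momentum must be non-negative")
  exponents <- as.numeric(exponents)
  if (length(exponents) == 0) stop("shell needs at least one primitive")
  if (any(!is.finite(exponents)) || any(exponents <= 0))
    stop("all exponents must be positive and finite")
  if (is.null(dim(coefficients)))
    coefficients <- matrix(as.numeric(coefficients), ncol = 1)
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != length(exponents))
    stop("coefficient rows must match the number of primitives")
  if (ncol(coefficients) < 1) stop("shell needs at least one contraction")
  if (any(apply(coefficients, 2, function(cc) all(cc == 0))))
    stop("all-zero coefficient column")
  ord <- order(exponents, decreasing = TRUE)
  structure(list(l = l, exponents = exponents[ord],
                 coefficients = coefficients[ord, , drop = FALSE]),
            class = "gaussian_shell")
}

#' @rdname gaussian_shell
#' @param symbol element symbol, e.g. \code{"O"}.
#' @param shells list of \code{gaussian_shell} objects.
#' @param role \code{"OBS"} or \code{"ABS"}.
#' @param Z atomic number; inferred from \code{symbol} when missing.
#' @export
element_basis <- function(symbol, shells, role = c("OBS", "ABS"), Z = NULL) {
  role <- match.arg(role)
  if (is.null(Z)) Z <- atomic_number(symbol)
  if (!all(vapply(shells, inherits, logical(1), "gaussian_shell")))
    stop("shells must be gaussian_shell objects")
  lv <- vapply(shells, `[[`, integer(1), "l")
  shells <- shells[order(lv)]
  structure(list(symbol = symbol, Z = as.integer(Z), shells = shells,
                 role = role),
            class = "element_basis")
}

#' @export
print.element_basis <- function(x, ...) {
  cat(sprintf("<element_basis %s (Z=%d), role %s: %s, %d spherical functions>\n",
              x$symbol, x$Z, x$role, composition(x), count_spherical(x)))
  invisible(x)
}

# Gaussian'94 angular-momentum letters: the letter J for l = 7 is NOT
# skipped, unlike the spectroscopic convention.
.am_letters <- c("s", "p", "d", "f", "g", "h", "i", "j", "k", "l",
                 "m", "n", "o", "q", "r", "t", "u", "v", "w")

am_letter <- function(l) {
  if (l + 1 > length(.am_letters))
    stop("angular momentum ", l, " beyond the letter table")
  .am_letters[l + 1]
}

am_from_letter <- function(ch) {
  idx <- match(tolower(ch), .am_letters)
  if (is.na(idx)) stop("unknown angular-momentum letter '", ch, "'")
  idx - 1L
}

#' Shell counts, spherical function counts and composition strings
#'
#' \code{composition} renders the number of contracted shells per
#' angular momentum as e.g. \code{"9s7p6d3f1g"} (ascending l, zero
#' counts omitted); \code{parse_composition} inverts it to a named
#' integer vector; \code{count_spherical} is
#' \eqn{\sum_{shells} n_{contr} (2l+1)}.
#'
#' @param basis an \code{element_basis}.
#' @return \code{composition}: a string; \code{count_spherical}: an
#'   integer; \code{parse_composition}: named integer vector of counts.
#' @examples
#' b <- element_basis("H", list(gaussian_shell(0, c(13, 1.96, 0.444),
#'                                             c(0.33, 0.57, 0.26))))
#' composition(b)        # "1s"
#' count_spherical(b)    # 1
#' @export
composition <- function(basis) {
  if (length(basis$shells) == 0) return("")
  lv <- vapply(basis$shells, `[[`, integer(1), "l")
  nc <- vapply(basis$shells, function(s) ncol(s$coefficients), integer(1))
  counts <- tapply(nc, lv, sum)
  ls <- as.integer(names(counts))
  paste0(counts, vapply(ls, am_letter, character(1)), collapse = "")
}

#' @rdname composition
#' @param text a composition string such as \code{"12s10p10d8f6g3h1i"}.
#' @export
parse_composition <- function(text) {
  if (!nzchar(text)) return(integer(0))
  m <- gregexpr("[0-9]+[a-z]", text)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(text))
    stop("malformed composition string: '", text, "'")
  parts <- regmatches(text, gregexpr("[0-9]+[a-z]", text))[[1]]
  counts <- as.integer(sub("[a-z]$", "", parts))
  ls <- vapply(sub("^[0-9]+", "", parts), am_from_letter, integer(1))
  stats::setNames(counts, ls)
}

#' @rdname composition
#' @export
count_spherical <- function(basis) {
  if (length(basis$shells) == 0) return(0L)
  sum(vapply(basis$shells, function(s)
    ncol(s$coefficients) * (2L * s$l + 1L), integer(1)))
}

#' Maximum angular momentum of a basis
#' @param basis an \code{element_basis}.
#' @return integer, \code{-1L} for an empty basis.
#' @export
l_max <- function(basis) {
  if (length(basis$shells) == 0) return(-1L)
  max(vapply(basis$shells, `[[`, integer(1), "l"))
}

# Periodic table symbols in Z order (1..103).
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
  "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr",
  "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br",
  "Kr", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd",
  "Ag", "Cd", "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La",
  "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er",
  "Tm", "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au",
  "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm", "Md",
  "No", "Lr")

#' Atomic number from an element symbol
#' @param symbol element symbol (case sensitive, e.g. \code{"Na"}).
#' @return integer atomic number.
#' @export
atomic_number <- function(symbol) {
  z <- match(symbol, .element_symbols)
  if (is.na(z)) stop("unknown element symbol '", symbol, "'")
  z
}

# Split every multi-column shell into single-column shells (the
# segmented normal form used for round-trip comparisons and file output).
segment_basis <- function(basis) {
  out <- list()
  for (sh in basis$shells) {
    for (j in seq_len(ncol(sh$coefficients))) {
      cc <- sh$coefficients[, j]
      keep <- cc != 0
      out[[length(out) + 1L]] <-
        gaussian_shell(sh$l, sh$exponents[keep], cc[keep])
    }
  }
  element_basis(basis$symbol, out, role = basis$role, Z = basis$Z)
}

# Radial functions of all contracted functions of a basis, as a list of
# records (l, shell index, column index, radial_function).
basis_radial_functions <- function(basis) {
  recs <- list()
  for (i in seq_along(basis$shells)) {
    sh <- basis$shells[[i]]
    for (j in seq_len(ncol(sh$coefficients))) {
      recs[[length(recs) + 1L]] <- list(
        l = sh$l, shell = i, col = j,
        fn = radial_contraction(sh$exponents, sh$coefficients[, j], sh$l))
    }
  }
  recs
}
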