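#' Auxiliary-basis presets
#'
#' Named \eqn{(\epsilon, l_{inc})} combinations balancing contraction
#' and pruning: \code{"small"} \eqn{(10^{-4}, 0)}, \code{"large"}
#' \eqn{(10^{-5}, 1)}, \code{"verylarge"} \eqn{(10^{-6}, 1)};
#' \code{"full"} disables both contraction and pruning, returning the
#' primitive auxiliary basis.
#'
#' @param name preset name.
#' @return list with \code{epsilon} and \code{l_inc} (\code{NA} for
#'   \code{"full"}).
#' @export
abs_preset <- function(name = c("small", "large", "verylarge", "full")) {
  name <- match.arg(name)
  switch(name,
         small = list(name = name, epsilon = 1e-4, l_inc = 0L),
         large = list(name = name, epsilon = 1e-5, l_inc = 1L),
         verylarge = list(name = name, epsilon = 1e-6, l_inc = 1L),
         full = list(name = name, epsilon = NA_real_, l_inc = NA_integer_))
}

#' Auxiliary-to-orbital size ratio
#'
#' \eqn{\gamma = N_{bf}^{ABS} / N_{bf}^{OBS}}, the ratio of spherical
#' function counts; density-fitting cost is linear in it.
#'
#' @param obs,abs_basis \code{\link{element_basis}} objects.
#' @return numeric ratio.
#' @export
abs_gamma <- function(obs, abs_basis) {
  nobs <- count_spherical(obs)
  if (nobs == 0) stop("orbital basis has no functions")
  count_spherical(abs_basis) / nobs
}

#' Generate a pruned, contracted auxiliary basis for one element
#'
#' End-to-end driver: enumerate candidate products of the contracted
#' orbital shells, optionally prescreen them, select the primitive
#' auxiliary set per angular momentum by pivoted Cholesky to \code{tau},
#' prune high-angular-momentum shells, and contract each angular block
#' to \code{epsilon}.  Pruning precedes contraction; the two commute
#' because contraction acts within each angular momentum.
#'
#' @param obs orbital \code{\link{element_basis}}.
#' @param Z atomic number (default: from \code{obs}).
#' @param config a \code{\link{generation_config}}.
#' @param preset preset name (see \code{\link{abs_preset}}) or
#'   \code{NULL} to use \code{epsilon} / \code{l_inc} directly.
#' @param epsilon contraction threshold (ignored when a preset is
#'   given); \code{NA} disables contraction.
#' @param l_inc pruning increment (ignored when a preset is given);
#'   \code{NA} disables pruning.
#' @param scheme pruning rule (\code{"eq9"}, \code{"eq10"} or
#'   \code{"none"}).
#' @param convention occupied-shell convention.
#' @return list: \code{basis} (the auxiliary \code{element_basis}),
#'   \code{primitive} (the unpruned primitive ABS), \code{report} (a
#'   \code{\link{size_report}}), and \code{spectra} (per-l eigenvalue
#'   diagnostics, \code{NULL} when uncontracted).
#' @export
generate_abs <- function(obs, Z = obs$Z, config = generation_config(),
                         preset = NULL, epsilon = 1e-5, l_inc = 1L,
                         scheme = c("eq9", "eq10", "none"),
                         convention = c("yang", "stoychev")) {
  scheme <- match.arg(scheme)
  convention <- match.arg(convention)
  if (!is.null(preset)) {
    p <- abs_preset(preset)
    epsilon <- p$epsilon
    l_inc <- p$l_inc
    if (p$name == "full") scheme <- "none"
  }
  cands <- enumerate_candidates(obs, config)
  cands <- prescreen_products(cands, config)
  prim <- select_primitive_abs(cands, config, symbol = obs$symbol, Z = Z)
  ab <- prim
  if (scheme != "none" && !is.na(l_inc))
    ab <- prune_abs(ab, Z, l_max(obs), l_inc, scheme, convention)
  spectra <- NULL
  if (!is.na(epsilon)) {
    cr <- contract_abs(obs, ab, epsilon, lindep = config$lindep,
                       method = config$method)
    ab <- cr$basis
    spectra <- cr$spectra
  }
  list(basis = ab, primitive = prim,
       report = size_report(obs, ab, primitive = prim),
       spectra = spectra)
}

#' Size and composition report
#'
#' @param obs orbital basis.
#' @param abs_basis final auxiliary basis.
#' @param primitive optional primitive auxiliary basis for the
#'   primitive-composition field.
#' @return list of class \code{size_report} with element, spherical
#'   counts, \eqn{\gamma} (exact and rounded half-even to one decimal
#'   for table comparisons), and composition strings.
#' @export
size_report <- function(obs, abs_basis, primitive = NULL) {
  g <- abs_gamma(obs, abs_basis)
  structure(list(
    element = obs$symbol,
    n_obs = count_spherical(obs),
    n_abs = count_spherical(abs_basis),
    gamma = g,
    gamma_1dp = round(g, 1),
    composition_obs = composition(obs),
    composition_abs = composition(abs_basis),
    composition_primitive = if (is.null(primitive)) NULL
                            else composition(primitive)),
    class = "size_report")
}

#' @export
print.size_report <- function(x, ...) {
  cat(sprintf("element %s: N_obs = %d (%s), N_abs = %d (%s), gamma = %.1f\n",
              x$element, x$n_obs, x$composition_obs, x$n_abs,
              x$composition_abs, x$gamma_1dp))
  if (!is.null(x$composition_primitive))
    cat("  primitive ABS:", x$composition_primitive, "\n")
  invisible(x)
}

#' Write a size/diagnostics report as JSON
#'
#' Serializes a \code{\link{size_report}} (and optional eigenvalue
#' spectra) to a JSON file.
#'
#' @param report a \code{size_report}.
#' @param path output file.
#' @param spectra optional per-l spectra from \code{\link{contract_abs}}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, spectra = NULL) {
  obj <- unclass(report)
  if (!is.null(spectra)) obj$spectra <- spectra
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reproducible orbital-basis fixtures
#'
#' \code{"toy-H"} is a fixed three-primitive contracted s shell
#' (exponents 13.0, 1.96, 0.444); \code{"toy-sp"} adds a p shell to a
#' two-primitive s contraction; \code{"random"} draws 2-4 shells with
#' \eqn{l \le 2}, 1-3 primitives each and log-uniform exponents, fully
#' determined by \code{seed}.
#'
#' @param kind fixture name.
#' @param seed integer seed for \code{"random"}.
#' @return an \code{\link{element_basis}} with role \code{"OBS"}.
#' @export
make_fixture <- function(kind = c("toy-H", "toy-sp", "random"), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "toy-H") {
    return(element_basis("H", list(
      gaussian_shell(0, c(13.0, 1.96, 0.444),
                     c(0.0334946, 0.23472695, 0.81375733)))))
  }
  if (kind == "toy-sp") {
    return(element_basis("He", list(
      gaussian_shell(0, c(2.0, 0.5), c(0.6, 0.5)),
      gaussian_shell(1, 0.8, 1.0))))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nsh <- sample(2:4, 1)
  ls <- sort(sample(0:2, nsh, replace = TRUE))
  shells <- lapply(ls, function(l) {
    np <- sample(1:3, 1)
    ex <- sort(10^stats::runif(np, -1.5, 2.5), decreasing = TRUE)
    cc <- matrix(stats::runif(np, 0.1, 1), np, 1)
    gaussian_shell(l, ex, cc)
  })
  element_basis("C", shells)
}
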