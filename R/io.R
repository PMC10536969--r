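#' Read an element basis set from a file
#'
#' Supports the Gaussian94 text format and Basis Set Exchange JSON
#' (element-keyed \code{electron_shells} with \code{exponents} /
#' \code{coefficients}).  Shells are assumed spherical; Cartesian-only
#' declarations raise an error.  Combined-angular-momentum blocks
#' (e.g. SP) are split into one shell per angular momentum.
#'
#' @param path file to read.
#' @param format \code{"gaussian94"} or \code{"bse-json"}; guessed from
#'   the file extension when missing.
#' @param element element symbol (Gaussian94) or atomic number key
#'   (BSE JSON) to extract; defaults to the first element in the file.
#' @param role basis role to record, \code{"OBS"} (default) or
#'   \code{"ABS"}.
#' @return an \code{\link{element_basis}}.
#' @export
read_basis <- function(path, format = c("gaussian94", "bse-json"),
                       element = NULL, role = "OBS") {
  if (missing(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "bse-json"
              else "gaussian94"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "gaussian94" = read_gaussian94(path, element, role),
         "bse-json" = read_bse_json(path, element, role))
}

read_gaussian94 <- function(path, element = NULL, role = "OBS") {
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("!.*$", "", lines)
  if (any(grepl("^\\s*cartesian\\s*$", stripped, ignore.case = TRUE)))
    stop("Cartesian-only basis declarations are not supported")
  blocks <- list()
  i <- 1L
  n <- length(stripped)
  skip_blank <- function(i) {
    while (i <= n && !nzchar(trimws(stripped[i]))) i <- i + 1L
    i
  }
  parse_err <- function(i, msg)
    stop(sprintf("parse error at line %d of %s: %s", i, path, msg))
  i <- skip_blank(i)
  while (i <= n && grepl("^\\*\\*\\*\\*", trimws(stripped[i])))
    i <- skip_blank(i + 1L)
  while (i <= n) {
    tok <- strsplit(trimws(stripped[i]), "\\s+")[[1]]
    if (length(tok) < 1 || !grepl("^[A-Za-z]{1,2}$", tok[1]))
      parse_err(i, "expected an element line 'Symbol 0'")
    sym <- paste0(toupper(substr(tok[1], 1, 1)),
                  tolower(substr(tok[1], 2, 3)))
    i <- skip_blank(i + 1L)
    shells <- list()
    while (i <= n && !grepl("^\\*\\*\\*\\*", trimws(stripped[i]))) {
      hdr <- strsplit(trimws(stripped[i]), "\\s+")[[1]]
      if (length(hdr) < 2 || !grepl("^[A-Za-z]+$", hdr[1]))
        parse_err(i, "expected a shell header 'L nprim scale'")
      letters_v <- strsplit(tolower(hdr[1]), "")[[1]]
      ls <- vapply(letters_v, am_from_letter, integer(1))
      nprim <- suppressWarnings(as.integer(hdr[2]))
      if (is.na(nprim) || nprim < 1) parse_err(i, "bad primitive count")
      hdr_line <- i
      i <- i + 1L
      rows <- matrix(NA_real_, nprim, 1 + length(ls))
      for (r in seq_len(nprim)) {
        i <- skip_blank(i)
        if (i > n) parse_err(hdr_line, "unexpected end of shell block")
        num <- suppressWarnings(as.numeric(
          gsub("[DdEe]([+-]?[0-9])", "e\\1",
               strsplit(trimws(stripped[i]), "\\s+")[[1]])))
        if (length(num) != 1 + length(ls) || any(is.na(num)))
          parse_err(i, "expected one exponent and one coefficient per shell letter")
        rows[r, ] <- num
        i <- i + 1L
      }
      if (any(rows[, 1] <= 0))
        parse_err(hdr_line, "non-positive exponent in shell block")
      for (k in seq_along(ls))
        shells[[length(shells) + 1L]] <-
          gaussian_shell(ls[k], rows[, 1], rows[, 1 + k])
      i <- skip_blank(i)
    }
    blocks[[sym]] <- shells
    i <- skip_blank(i + 1L)
  }
  if (length(blocks) == 0) stop("no basis blocks found in ", path)
  sym <- if (is.null(element)) names(blocks)[1] else element
  if (is.null(blocks[[sym]])) stop("element ", sym, " not present in ", path)
  element_basis(sym, merge_segmented(blocks[[sym]]), role = role)
}

# Re-merge consecutive single-column shells sharing l and exponents into
# one generally-contracted shell (inverse of segmented output).
merge_segmented <- function(shells) {
  if (length(shells) < 2) return(shells)
  out <- list()
  for (sh in shells) {
    last <- if (length(out)) out[[length(out)]] else NULL
    if (!is.null(last) && last$l == sh$l &&
        length(last$exponents) == length(sh$exponents) &&
        isTRUE(all.equal(last$exponents, sh$exponents, tolerance = 1e-14))) {
      out[[length(out)]] <- gaussian_shell(
        sh$l, last$exponents, cbind(last$coefficients, sh$coefficients))
    } else out[[length(out) + 1L]] <- sh
  }
  out
}

read_bse_json <- function(path, element = NULL, role = "OBS") {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  els <- js$elements
  if (is.null(els)) stop("no 'elements' key in BSE JSON file ", path)
  key <- if (is.null(element)) names(els)[1] else as.character(element)
  if (!is.null(element) && !key %in% names(els)) {
    # allow an element symbol as well as a Z key
    key <- as.character(atomic_number(element))
  }
  el <- els[[key]]
  if (is.null(el)) stop("element ", key, " not present in ", path)
  shells <- list()
  for (sh in el$electron_shells) {
    ft <- sh$function_type
    if (!is.null(ft) && grepl("cartesian", ft, ignore.case = TRUE))
      stop("Cartesian-only basis declarations are not supported")
    ex <- as.numeric(unlist(sh$exponents))
    ls <- as.integer(unlist(sh$angular_momentum))
    cols <- lapply(sh$coefficients, function(cc) as.numeric(unlist(cc)))
    if (length(ls) == 1) {
      mat <- do.call(cbind, cols)
      shells[[length(shells) + 1L]] <- gaussian_shell(ls, ex, mat)
    } else {
      if (length(cols) != length(ls))
        stop("BSE JSON shell: ", length(cols), " coefficient columns for ",
             length(ls), " angular momenta")
      for (k in seq_along(ls)) {
        keep <- cols[[k]] != 0
        shells[[length(shells) + 1L]] <-
          gaussian_shell(ls[k], ex[keep], cols[[k]][keep])
      }
    }
  }
  sym <- .element_symbols[as.integer(key)]
  element_basis(sym, shells, role = role, Z = as.integer(key))
}

#' Write an element basis set in Gaussian94 format
#'
#' Generally-contracted shells are written segmented, one block per
#' contraction column.  Numbers carry 12 significant digits so that
#' \code{read_basis(write_basis(b))} reproduces \code{b} (in segmented
#' normal form) to that precision.
#'
#' @param basis an \code{\link{element_basis}}.
#' @param path output file.
#' @param format only \code{"gaussian94"}.
#' @return \code{path}, invisibly.
#' @export
write_basis <- function(basis, path, format = "gaussian94") {
  format <- match.arg(format, "gaussian94")
  seg <- segment_basis(basis)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("****", con)
  writeLines(sprintf("%-2s    0", basis$symbol), con)
  for (sh in seg$shells) {
    writeLines(sprintf("%s   %d   1.00", toupper(am_letter(sh$l)),
                       length(sh$exponents)), con)
    for (r in seq_along(sh$exponents))
      writeLines(sprintf("  %20.11E  %20.11E", sh$exponents[r],
                         sh$coefficients[r, 1]), con)
  }
  writeLines("****", con)
  invisible(path)
}
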