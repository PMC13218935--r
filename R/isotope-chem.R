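#' Supported element symbols
#'
#' Elements for which natural isotope abundances are packaged and formulas
#' are accepted. Nitrogen is the default tracer element.
#' @keywords internal
SUPPORTED_ELEMENTS <- c("C", "H", "N", "O", "P", "S")

#' Parse a molecular formula string
#'
#' Parses a Hill-notation-like formula (e.g. `"C9H13N2O9P"` for UMP) into a
#' named integer vector of atom counts. Only C, H, N, O, P and S are
#' supported; any other element symbol is an error.
#'
#' @param text Formula string, e.g. `"C5H10N2O3"` (glutamine).
#' @return Named integer vector of atom counts, one entry per element present.
#' @examples
#' parse_formula("C9H13N2O9P")
#' parse_formula("NO3")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (length(matched) == 0L || sum(nchar(matched)) != nchar(text)) {
    stop(sprintf("malformed formula: '%s'", text), call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", matched)
  counts <- sub("^[A-Za-z]+", "", matched)
  counts <- ifelse(nzchar(counts), suppressWarnings(as.integer(counts)), 1L)
  bad <- setdiff(elements, SUPPORTED_ELEMENTS)
  if (length(bad) > 0L) {
    stop(sprintf("unsupported element(s) in '%s': %s", text,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0L)) {
    stop(sprintf("malformed atom count in formula '%s'", text), call. = FALSE)
  }
  out <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  out <- setNames(as.integer(out), names(out))
  if (sum(out) < 1L) stop("formula contains no atoms", call. = FALSE)
  out
}

#' Natural isotope abundance table
#'
#' Returns the packaged table of natural isotope abundances as a tibble with
#' columns `element`, `shift` (integer nominal mass shift relative to the
#' most abundant isotope) and `abundance` (fraction, summing to 1 per
#' element). Standard IUPAC values are packaged as an editable CSV
#' (`system.file("extdata", "isotope_abundances.csv", package = "azotrace")`).
#'
#' @param tracer_element Element carrying the tracer label; default `"N"`.
#' @param path Optional path to an alternative abundance CSV.
#' @return Tibble with attribute `tracer_element`.
#' @export
isotope_abundances <- function(tracer_element = "N", path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "isotope_abundances.csv", package = "azotrace")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           element = readr::col_character(),
                           shift = readr::col_integer(),
                           abundance = readr::col_double()))
  validate_abundance_table(tab, tracer_element)
  attr(tab, "tracer_element") <- tracer_element
  tab
}

validate_abundance_table <- function(tab, tracer_element) {
  stopifnot(all(c("element", "shift", "abundance") %in% names(tab)))
  if (any(tab$shift < 0) || any(tab$abundance < 0) || any(tab$abundance > 1)) {
    stop("abundance table entries out of range", call. = FALSE)
  }
  sums <- tapply(tab$abundance, tab$element, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop(sprintf("abundances do not sum to 1 for element(s): %s",
                 paste(names(sums)[abs(sums - 1) > 1e-9], collapse = ", ")),
         call. = FALSE)
  }
  zero_present <- tapply(tab$shift, tab$element, function(s) any(s == 0L))
  if (!all(zero_present)) stop("shift-0 entry missing for some element", call. = FALSE)
  if (!tracer_element %in% tab$element) {
    stop(sprintf("tracer element '%s' absent from abundance table", tracer_element),
         call. = FALSE)
  }
  invisible(tab)
}

# per-atom shift distribution for one element, as a dense vector over 0..max
atom_distribution <- function(tab, element) {
  rows <- tab[tab$element == element, ]
  v <- numeric(max(rows$shift) + 1L)
  v[rows$shift + 1L] <- rows$abundance
  v
}

# heavy-isotope abundance (summed over shifts >= 1) of the tracer element
tracer_heavy_abundance <- function(tab, tracer_element) {
  rows <- tab[tab$element == tracer_element, ]
  sum(rows$abundance[rows$shift >= 1L])
}

# discrete convolution of two shift distributions, optionally truncated
convolve_shift <- function(a, b, max_len = NULL) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  if (!is.null(max_len) && length(out) > max_len) out <- out[seq_len(max_len)]
  out
}

# natural shift distribution of all non-tracer atoms in a formula, truncated
non_tracer_distribution <- function(formula, tab, tracer_element, max_len) {
  dist <- 1
  for (el in names(formula)) {
    if (el == tracer_element || formula[[el]] == 0L) next
    base <- atom_distribution(tab, el)
    for (i in seq_len(formula[[el]])) {
      dist <- convolve_shift(dist, base, max_len = max_len)
    }
  }
  if (length(dist) < max_len) dist <- c(dist, numeric(max_len - length(dist)))
  dist
}

#' Theoretical isotopologue distribution of a labelled molecule
#'
#' Computes the probability distribution over nominal mass shifts
#' M+0 ... M+n for a molecule in which exactly `j` of its `n` tracer-element
#' atoms carry the heavy label. In `"resolved"` mode (spectra acquired at
#' resolving power where tracer isotopologues separate from heavy-isotope
#' interference of other elements) only the `n - j` unlabelled tracer-element
#' positions contribute natural heavy signal, giving a binomial distribution
#' shifted by `j`. In `"unresolved"` mode the natural heavy-isotope
#' distributions of all non-tracer elements are additionally convolved in and
#' the result is truncated at `max_shift` (default `n`, keeping the
#' correction matrix square).
#'
#' @param formula Named atom-count vector from [parse_formula()], or a
#'   formula string.
#' @param j Number of labelled tracer atoms, `0 <= j <= n`.
#' @param table Abundance table from [isotope_abundances()]; `NULL` uses
#'   the packaged defaults.
#' @param mode `"resolved"` (default) or `"unresolved"`.
#' @param max_shift Truncation shift for unresolved mode; default `n`.
#' @return Numeric vector of probabilities over shifts `0..max_shift`.
#' @examples
#' gln <- parse_formula("C5H10N2O3")
#' labelled_distribution(gln, j = 0)
#' labelled_distribution(gln, j = 2) # all tracer atoms labelled
#' @export
labelled_distribution <- function(formula, j, table = NULL,
                                  mode = c("resolved", "unresolved"),
                                  max_shift = NULL) {
  mode <- match.arg(mode)
  if (is.null(table)) table <- default_abundances()
  if (is.character(formula)) formula <- parse_formula(formula)
  tracer <- attr(table, "tracer_element") %||% "N"
  n <- if (tracer %in% names(formula)) formula[[tracer]] else 0L
  if (n < 1L) {
    stop(sprintf("formula lacks tracer element '%s'", tracer), call. = FALSE)
  }
  if (!is.numeric(j) || length(j) != 1L || j < 0 || j > n || j != round(j)) {
    stop(sprintf("labelled-atom count j = %s outside 0..%d", format(j), n),
         call. = FALSE)
  }
  if (is.null(max_shift)) max_shift <- n
  a <- tracer_heavy_abundance(table, tracer)
  # unlabelled tracer positions: Binomial(n - j, a), placed at shifts j..n
  probs <- numeric(n + 1L)
  k <- 0:(n - j)
  probs[j + k + 1L] <- dbinom(k, size = n - j, prob = a)
  if (mode == "unresolved") {
    nat <- non_tracer_distribution(formula, table, tracer, max_len = max_shift + 1L)
    probs <- convolve_shift(probs, nat, max_len = max_shift + 1L)
  } else if (max_shift != n) {
    probs <- if (max_shift > n) c(probs, numeric(max_shift - n)) else probs[seq_len(max_shift + 1L)]
  }
  probs
}

#' Natural-abundance correction matrix
#'
#' Builds the (n+1) x (n+1) matrix whose column `j+1` is the theoretical
#' isotopologue distribution of the molecule with `j` labelled tracer atoms
#' (see [labelled_distribution()]). In resolved mode the matrix is lower
#' triangular with strictly positive diagonal (hence invertible) and each
#' column sums to 1. Observed isotopologue vectors are modelled as
#' `C %*% x` where `x` holds the true labelled fractions; correction solves
#' the inverse problem (see [correct_vector()]).
#'
#' @inheritParams labelled_distribution
#' @return Numeric matrix with dimnames `M+0 ... M+n` on both margins.
#' @examples
#' correction_matrix("C5H10N2O3") # glutamine, 2 tracer atoms -> 3 x 3
#' @export
correction_matrix <- function(formula, table = NULL,
                              mode = c("resolved", "unresolved")) {
  mode <- match.arg(mode)
  if (is.null(table)) table <- default_abundances()
  if (is.character(formula)) formula <- parse_formula(formula)
  tracer <- attr(table, "tracer_element") %||% "N"
  n <- if (tracer %in% names(formula)) formula[[tracer]] else 0L
  if (n < 1L) {
    stop(sprintf("formula lacks tracer element '%s'", tracer), call. = FALSE)
  }
  cols <- vapply(0:n, function(j) {
    labelled_distribution(formula, j, table = table, mode = mode, max_shift = n)
  }, numeric(n + 1L))
  dimnames(cols) <- list(paste0("M+", 0:n), paste0("M+", 0:n))
  cols
}

`%||%` <- function(a, b) if (is.null(a)) b else a
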