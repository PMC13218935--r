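#' Forward-convolve true enrichment fractions into observed intensities
#'
#' Applies the generative model of isotopologue measurement: given the true
#' labelled fractions `x` (summing to 1) and the correction matrix `C`, the
#' expected observed isotopologue pattern is `C %*% x`. This is the
#' simulation counterpart of [correct_vector()] and the model used by the
#' synthetic-data generator.
#'
#' @param fractions Non-negative numeric vector summing to 1 over M+0..M+n.
#' @param cmat Correction matrix from [correction_matrix()].
#' @return Numeric vector of expected observed intensities (unit total in
#'   resolved mode).
#' @examples
#' cm <- correction_matrix("C5H10N2O3")
#' forward_convolve(c(0.7, 0.3, 0), cm)
#' @export
forward_convolve <- function(fractions, cmat) {
  if (any(fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
  if (length(fractions) != ncol(cmat)) {
    stop(sprintf("fraction vector length %d does not match matrix size %d",
                 length(fractions), ncol(cmat)), call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  drop(cmat %*% fractions)
}

#' Correct an observed isotopologue vector for natural abundance
#'
#' Solves the inverse of the measurement model: finds non-negative labelled
#' fractions `x` minimising `||C x - m||^2` (non-negative least squares),
#' then renormalizes `x` to sum to 1. For the square, invertible
#' resolved-mode matrix the exact linear solve is attempted first and
#' accepted when already non-negative (it is then the zero-residual NNLS
#' optimum); otherwise the active-set NNLS solver is used. Noiseless inputs
#' produced by [forward_convolve()] are recovered to machine precision.
#'
#' @param observed Numeric vector of observed intensities over M+0..M+n
#'   (arbitrary units; at least one positive entry).
#' @param cmat Correction matrix from [correction_matrix()].
#' @return List of class `enrichment_vector` with elements `fractions`
#'   (corrected fractional enrichments summing to 1), `total_labelling`
#'   (`1 - fractions[1]`) and `residual` (relative residual norm, a QC
#'   measure).
#' @examples
#' cm <- correction_matrix("C5H10N2O3")
#' obs <- forward_convolve(c(0.7, 0.2, 0.1), cm)
#' correct_vector(obs, cm)$fractions
#' @export
correct_vector <- function(observed, cmat) {
  if (length(observed) != nrow(cmat)) {
    stop(sprintf("observed vector length %d does not match matrix rows %d",
                 length(observed), nrow(cmat)), call. = FALSE)
  }
  if (any(is.na(observed)) || any(observed < 0)) {
    stop("observed intensities must be non-negative and non-missing", call. = FALSE)
  }
  total <- sum(observed)
  if (total <= 0) stop("all-zero observed vector cannot be corrected", call. = FALSE)
  m <- observed / total  # scale invariance: work on the unit-total pattern
  x <- solve_nnls(cmat, m)
  resid <- sqrt(sum((cmat %*% x - m)^2))
  s <- sum(x)
  if (s <= 0) stop("degenerate correction: non-negative solution is zero", call. = FALSE)
  fr <- unname(x / s)
  structure(list(fractions = fr,
                 total_labelling = 1 - fr[1L],
                 residual = resid),
            class = "enrichment_vector")
}

# exact solve fast path, NNLS fallback
solve_nnls <- function(cmat, m) {
  x <- tryCatch(solve(cmat, m), error = function(e) NULL)
  if (!is.null(x) && all(x >= -1e-12)) {
    return(pmax(x, 0))
  }
  pracma::lsqnonneg(cmat, m)$x
}

#' Fractional enrichment of an isotopologue vector
#'
#' Normalizes an intensity vector to fractions of the total pool; no
#' natural-abundance correction is applied (use [correct_vector()] for
#' that). `total_labelling` is `1 - FE(M+0)`, the fraction of the pool
#' carrying at least one heavy atom.
#'
#' @param intensities Non-negative numeric vector over M+0..M+n with at
#'   least one positive entry.
#' @return List of class `enrichment_vector` with `fractions` and
#'   `total_labelling`.
#' @examples
#' fractional_enrichment(c(90, 8, 2))
#' @export
fractional_enrichment <- function(intensities) {
  if (length(intensities) == 0L) stop("empty intensity vector", call. = FALSE)
  if (any(is.na(intensities)) || any(intensities < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  total <- sum(intensities)
  if (total <= 0) stop("all-zero intensity vector", call. = FALSE)
  fr <- intensities / total
  structure(list(fractions = fr, total_labelling = 1 - fr[1L], residual = 0),
            class = "enrichment_vector")
}

#' @export
print.enrichment_vector <- function(x, ...) {
  cat("<enrichment_vector>\n")
  cat("  FE:", paste(sprintf("M+%d %.4f", seq_along(x$fractions) - 1L, x$fractions),
                     collapse = ", "), "\n")
  cat(sprintf("  total labelling: %.4f\n", x$total_labelling))
  invisible(x)
}

#' Construct a pixel grid of isotopologue vectors
#'
#' A pixel grid holds one metabolite's isotopologue intensities for every
#' pixel of a mass spectrometry imaging acquisition, in row-major order with
#' 0-based `x` (column) and `y` (row) coordinates.
#'
#' @param intensities Numeric matrix, `width * height` rows (pixels,
#'   row-major) by `n + 1` columns (M+0..M+n).
#' @param width,height Grid dimensions in pixels.
#' @param metabolite Metabolite identifier.
#' @return Object of class `pixel_grid`.
#' @export
pixel_grid <- function(intensities, width, height, metabolite = "metabolite") {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != width * height) {
    stop("intensity matrix rows must equal width * height", call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("pixel intensities must be non-negative", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 metabolite = metabolite, intensities = intensities),
            class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %s: %d x %d pixels, M+0..M+%d\n",
              x$metabolite, x$width, x$height, ncol(x$intensities) - 1L))
  invisible(x)
}

#' Read / write a pixel grid as CSV
#'
#' CSV layout: columns `x`, `y` (0-based pixel coordinates) and `m0..mn`
#' isotopologue intensity columns, one row per pixel.
#'
#' @param path CSV file path.
#' @param metabolite Metabolite identifier to attach.
#' @return [pixel_grid()] object.
#' @export
read_pixel_grid <- function(path, metabolite = "metabolite") {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x", "y") %in% names(tab))) stop("pixel CSV needs x and y columns", call. = FALSE)
  mcols <- grep("^m[0-9]+$", names(tab), value = TRUE)
  if (length(mcols) == 0L) stop("pixel CSV needs m0..mn intensity columns", call. = FALSE)
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  width <- max(tab$x) + 1L
  height <- max(tab$y) + 1L
  ord <- order(tab$y, tab$x)
  pixel_grid(as.matrix(tab[ord, mcols]), width, height, metabolite)
}

#' @rdname read_pixel_grid
#' @param grid A [pixel_grid()] object.
#' @export
write_pixel_grid <- function(grid, path) {
  n <- ncol(grid$intensities)
  coords <- expand.grid(x = 0:(grid$width - 1L), y = 0:(grid$height - 1L))
  tab <- cbind(coords, as.data.frame(grid$intensities))
  names(tab) <- c("x", "y", paste0("m", 0:(n - 1L)))
  readr::write_csv(tibble::as_tibble(tab), path)
  invisible(path)
}

#' Per-pixel natural-abundance correction of a pixel grid
#'
#' Corrects every pixel of a grid independently with [correct_vector()] and
#' returns per-isotopologue fractional-enrichment images. Pixels whose
#' intensity vector is all zero (no signal, e.g. off-tissue) are marked `NA`
#' rather than raising an error. A warning is logged when fewer than 1% of
#' pixels carry signal.
#'
#' @param grid A [pixel_grid()].
#' @param cmat Correction matrix for the grid's metabolite.
#' @return List with `images` (array `height x width x (n+1)` of fractional
#'   enrichments), `total_labelling` (matrix `height x width`) and
#'   `n_missing` (count of all-zero pixels).
#' @export
correct_pixel_grid <- function(grid, cmat) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (ncol(grid$intensities) != nrow(cmat)) {
    stop("pixel vector length does not match correction matrix", call. = FALSE)
  }
  npix <- nrow(grid$intensities)
  nk <- ncol(grid$intensities)
  totals <- rowSums(grid$intensities)
  nonzero <- which(totals > 0 & !is.na(totals))
  if (length(nonzero) < 0.01 * npix) {
    warning(sprintf("pixel grid for %s has <1%% nonzero pixels (%d of %d)",
                    grid$metabolite, length(nonzero), npix))
  }
  fr <- matrix(NA_real_, nrow = npix, ncol = nk)
  if (length(nonzero) > 0L) {
    # exact solve across all nonzero pixels at once, NNLS only where needed
    M <- t(grid$intensities[nonzero, , drop = FALSE] / totals[nonzero])
    X <- tryCatch(solve(cmat, M), error = function(e) matrix(-1, nk, length(nonzero)))
    bad <- which(apply(X, 2L, function(col) any(col < -1e-12)))
    for (i in bad) X[, i] <- pracma::lsqnonneg(cmat, M[, i])$x
    X <- pmax(X, 0)
    X <- sweep(X, 2L, colSums(X), "/")
    fr[nonzero, ] <- t(X)
  }
  images <- array(NA_real_, dim = c(grid$height, grid$width, nk),
                  dimnames = list(NULL, NULL, paste0("M+", 0:(nk - 1L))))
  for (k in seq_len(nk)) {
    images[, , k] <- matrix(fr[, k], nrow = grid$height, ncol = grid$width,
                            byrow = TRUE)
  }
  list(images = images,
       total_labelling = 1 - images[, , 1L],
       n_missing = npix - length(nonzero))
}
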