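#' Probabilistic quotient normalization
#'
#' Normalizes a samples x metabolites intensity matrix by the median
#' quotient to a reference spectrum. The reference is the per-metabolite
#' median across all samples; each sample's dilution factor is the median
#' over metabolites of (sample value / reference value); normalized values
#' are sample values divided by that factor. Metabolites quantified
#' (value > 0) in at most half of the samples are excluded from quotient
#' computation to guard against zero-inflated quotients (they are still
#' normalized in the output).
#'
#' @param mat Numeric matrix or data frame, samples in rows, metabolites in
#'   columns. Missing values are allowed and ignored in medians.
#' @param reference Optional reference spectrum (numeric vector over the
#'   usable metabolite columns, or over all columns). By default the
#'   per-metabolite median across the samples of `mat` is used. Given a
#'   fixed reference, the quotient step is exactly scale invariant per
#'   sample: scaling a sample by `c > 0` scales its factor by `c` and
#'   leaves its normalized values unchanged. The data-derived default
#'   reference is itself only insensitive to single-sample dilution in
#'   large runs (the median spectrum moves by at most one order statistic).
#' @return List with `normalized` (matrix of the same shape), `factors`
#'   (per-sample dilution factors, for QC) and `reference` (the reference
#'   spectrum used, named by metabolite column).
#' @examples
#' m <- rbind(S1 = c(1, 2, 4), S2 = c(2, 4, 8))
#' pqn_normalize(m)$factors  # 2/3 and 4/3
#' @export
pqn_normalize <- function(mat, reference = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("PQN requires at least 2 samples", call. = FALSE)
  if (any(rowSums(!is.na(mat) & mat > 0) == 0L)) {
    stop("PQN: sample with no positive intensities", call. = FALSE)
  }
  quantified <- colSums(!is.na(mat) & mat > 0)
  usable <- quantified > nrow(mat) / 2
  if (!any(usable)) {
    stop("PQN: no metabolite quantified in more than half of the samples",
         call. = FALSE)
  }
  if (!all(usable)) {
    message(sprintf("PQN: excluding %d metabolite(s) absent from >50%% of samples",
                    sum(!usable)))
  }
  sub <- mat[, usable, drop = FALSE]
  if (is.null(reference)) {
    reference <- apply(sub, 2L, median, na.rm = TRUE)
  } else {
    if (length(reference) == ncol(mat)) reference <- reference[usable]
    if (length(reference) != ncol(sub)) {
      stop("reference length must match the metabolite columns", call. = FALSE)
    }
  }
  ok <- !is.na(reference) & reference > 0
  if (!any(ok)) stop("PQN: reference spectrum has no positive entries", call. = FALSE)
  factors <- apply(sub, 1L, function(row) {
    median(row[ok] / reference[ok], na.rm = TRUE)
  })
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("PQN: non-positive or undefined dilution factor", call. = FALSE)
  }
  list(normalized = mat / factors, factors = factors, reference = reference)
}

#' Pool sizes per (sample, metabolite)
#'
#' Sums isotopologue intensities into total pool sizes. Metabolites absent
#' from a sample are absent from the table (not treated as zero); the
#' per-metabolite mean is taken over samples in which the metabolite was
#' quantified.
#'
#' @param records Validated peak records (see [read_peak_table()]).
#' @return List with `samples` (tibble: sample, condition, tracer,
#'   metabolite, pool) and `metabolites` (tibble: metabolite, mean_pool,
#'   n_quantified).
#' @export
pool_sizes <- function(records) {
  if (nrow(records) == 0L) {
    return(list(samples = tibble::tibble(sample = character(),
                                         condition = character(),
                                         tracer = character(),
                                         metabolite = character(),
                                         pool = double()),
                metabolites = tibble::tibble(metabolite = character(),
                                             mean_pool = double(),
                                             n_quantified = integer())))
  }
  key <- paste(records$sample, records$condition, records$tracer,
               records$metabolite, sep = "\r")
  first <- !duplicated(key)
  f <- factor(key, levels = key[first])
  samples <- tibble::tibble(sample = records$sample[first],
                            condition = records$condition[first],
                            tracer = records$tracer[first],
                            metabolite = records$metabolite[first],
                            pool = unname(rowsum(records$intensity, f,
                                                 reorder = FALSE)[, 1L]))
  q <- samples[samples$pool > 0, ]
  mfirst <- !duplicated(samples$metabolite)
  mf <- factor(q$metabolite, levels = samples$metabolite[mfirst])
  nq <- as.integer(tabulate(mf, nbins = nlevels(mf)))
  mp <- rowsum(q$pool, mf, reorder = FALSE)
  mean_pool <- rep(NA_real_, nlevels(mf))
  mean_pool[match(rownames(mp), levels(mf))] <- mp[, 1L]
  mean_pool <- ifelse(nq > 0L, mean_pool / nq, NA_real_)
  metabolites <- tibble::tibble(metabolite = levels(mf),
                                mean_pool = mean_pool,
                                n_quantified = nq)
  list(samples = samples, metabolites = metabolites)
}

#' Two-condition contrast of metabolite pool sizes
#'
#' Per-metabolite unpaired two-tailed t-test of pool sizes between two
#' conditions, with the variance-gated form choice: an F test of variance
#' equality is run first, and Welch's correction is applied when the
#' variances differ significantly (F test P < 0.05); otherwise the
#' pooled-variance Student form is used. The fold change is
#' `log2(mean_A / mean_B)`. P values are not adjusted for multiple
#' comparisons.
#'
#' @param pools Per-sample pool table (`samples` element of [pool_sizes()]).
#' @param condition_a,condition_b Condition labels to contrast (A vs B).
#' @param f_alpha Significance level of the variance-equality F test.
#' @param incomplete `"error"` (default) to fail when a metabolite has fewer
#'   than 2 quantified samples in either condition; `"drop"` to skip such
#'   metabolites with a message.
#' @return Tibble: metabolite, log2fc, t, p, test_form (`"student"` or
#'   `"welch"`), n_a, n_b.
#' @export
pool_contrast <- function(pools, condition_a, condition_b, f_alpha = 0.05,
                          incomplete = c("error", "drop")) {
  incomplete <- match.arg(incomplete)
  a <- pools[pools$condition == condition_a & pools$pool > 0, ]
  b <- pools[pools$condition == condition_b & pools$pool > 0, ]
  mets <- intersect(unique(a$metabolite), unique(b$metabolite))
  if (length(mets) == 0L) stop("no metabolite quantified in both conditions", call. = FALSE)
  rows <- lapply(mets, function(m) {
    xa <- a$pool[a$metabolite == m]
    xb <- b$pool[b$metabolite == m]
    if (length(xa) < 2L || length(xb) < 2L) {
      if (incomplete == "error") {
        stop(sprintf("pool_contrast: metabolite '%s' has n < 2 in a condition", m),
             call. = FALSE)
      }
      return(NULL)
    }
    welch <- FALSE
    if (sd(xa) > 0 && sd(xb) > 0) {
      welch <- var.test(xa, xb)$p.value < f_alpha
    }
    tt <- if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb)) {
      list(statistic = c(t = 0), p.value = 1)  # identical constant groups
    } else {
      t.test(xa, xb, var.equal = !welch)
    }
    tibble::tibble(metabolite = m,
                   log2fc = log2(mean(xa) / mean(xb)),
                   t = unname(tt$statistic),
                   p = tt$p.value,
                   test_form = if (welch) "welch" else "student",
                   n_a = length(xa), n_b = length(xb))
  })
  dropped <- sum(vapply(rows, is.null, logical(1L)))
  if (dropped > 0L) {
    message(sprintf("pool_contrast: dropped %d metabolite(s) with n < 2", dropped))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no metabolite with n >= 2 in both conditions", call. = FALSE)
  out
}
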