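#' Construct an enrichment table object
#'
#' Container for condition x tracer x metabolite fractional enrichments.
#' Normally produced by [build_enrichment_table()]; the constructor is
#' exported so that enrichment tables can also be assembled directly (e.g.
#' from planted ground-truth fractions when exercising the filter cascade
#' or Sankey construction in isolation).
#'
#' @param totals Tibble with columns `condition`, `tracer`, `metabolite`,
#'   `total_mean` (replicate-mean total labelling, fraction in 0..1), `n`
#'   (replicate count) and optionally `total_sem`. Tracer-free control rows
#'   carry `tracer == "unlabelled"`.
#' @param samples Optional per-sample tibble (`sample`, `condition`,
#'   `tracer`, `metabolite`, `total_labelling`); defaults to one pseudo
#'   sample per `totals` row.
#' @param fractions Optional per-isotopologue tibble (`condition`,
#'   `tracer`, `metabolite`, `k`, `FE_mean`, `FE_sem`, `n`).
#' @return Object of class `enrichment_table`.
#' @export
enrichment_table <- function(totals, samples = NULL, fractions = NULL) {
  req <- c("condition", "tracer", "metabolite", "total_mean", "n")
  missing <- setdiff(req, names(totals))
  if (length(missing) > 0L) {
    stop(sprintf("totals missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  totals <- tibble::as_tibble(totals)
  if (!"total_sem" %in% names(totals)) totals$total_sem <- NA_real_
  totals$is_control <- totals$tracer == UNLABELLED
  key <- paste(totals$condition, totals$tracer, totals$metabolite, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (condition, tracer, metabolite) rows", call. = FALSE)
  if (is.null(samples)) {
    samples <- tibble::tibble(
      sample = paste(totals$condition, totals$tracer, "r1", sep = "_"),
      condition = totals$condition, tracer = totals$tracer,
      metabolite = totals$metabolite, total_labelling = totals$total_mean)
  }
  structure(list(totals = totals, samples = tibble::as_tibble(samples),
                 fractions = fractions), class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> %d (condition, tracer, metabolite) rows; %d conditions, %d tracers, %d metabolites\n",
              nrow(x$totals), length(unique(x$totals$condition)),
              length(unique(x$totals$tracer)), length(unique(x$totals$metabolite))))
  invisible(x)
}

#' Build the enrichment table from peak records
#'
#' For every (sample, metabolite) the observed isotopologue vector is
#' corrected for natural abundance ([correct_vector()]) and converted to
#' fractional enrichments; per (condition, tracer, metabolite) key the
#' per-sample enrichments are then replicate-averaged (arithmetic mean of
#' per-sample FEs with s.e.m., not FE of summed intensities). Samples in
#' which a metabolite has zero total intensity are excluded from that
#' metabolite's average and the replicate count decremented. Metabolites
#' whose formula lacks the tracer element carry total labelling 0.
#'
#' @param records Validated peak records (see [read_peak_table()]).
#' @param catalog Metabolite catalog ([read_catalog()]).
#' @param registry Tracer registry ([read_tracer_registry()]).
#' @param mode Correction mode, `"resolved"` (default) or `"unresolved"`.
#' @param table Isotope abundance table ([isotope_abundances()]).
#' @return An [enrichment_table()] with per-isotopologue `fractions`,
#'   per-key `totals` and per-sample `samples` components.
#' @export
build_enrichment_table <- function(records, catalog,
                                   registry = read_tracer_registry(catalog = catalog),
                                   mode = c("resolved", "unresolved"),
                                   table = NULL) {
  mode <- match.arg(mode)
  use_cache <- is.null(table)
  if (use_cache) table <- default_abundances()
  records <- validate_peak_records(records, catalog, registry,
                                   tracer_element = attr(table, "tracer_element") %||% "N")
  n_atoms <- metabolite_atom_counts(catalog, attr(table, "tracer_element") %||% "N")
  sample_meta <- unique(records[, c("sample", "condition", "tracer")])

  per_met <- split(seq_len(nrow(records)), records$metabolite)
  sample_rows <- list()
  frac_rows <- list()
  for (met in names(per_met)) {
    idx <- per_met[[met]]
    n <- n_atoms[[met]]
    sub <- records[idx, ]
    samp <- unique(sub$sample)
    X <- matrix(0, nrow = n + 1L, ncol = length(samp),
                dimnames = list(NULL, samp))
    X[cbind(sub$k + 1L, match(sub$sample, samp))] <- sub$intensity
    totals_obs <- colSums(X)
    keep <- totals_obs > 0
    if (!any(keep)) next
    X <- X[, keep, drop = FALSE]
    samp <- samp[keep]
    if (n == 0L) {
      FR <- matrix(1, nrow = 1L, ncol = length(samp))
    } else {
      fml <- catalog$formula[match(met, catalog$metabolite)]
      cmat <- if (use_cache) {
        cached_correction_matrix(fml, mode)
      } else {
        correction_matrix(parse_formula(fml), table = table, mode = mode)
      }
      M <- sweep(X, 2L, colSums(X), "/")
      FR <- tryCatch(solve(cmat, M),
                     error = function(e) matrix(-1, n + 1L, ncol(M)))
      bad <- which(apply(FR, 2L, function(col) any(col < -1e-12)))
      for (i in bad) FR[, i] <- pracma::lsqnonneg(cmat, M[, i])$x
      FR <- pmax(FR, 0)
      FR <- sweep(FR, 2L, colSums(FR), "/")
    }
    sample_rows[[met]] <- tibble::tibble(
      sample = samp, metabolite = met,
      total_labelling = 1 - FR[1L, ])
    frac_rows[[met]] <- tibble::tibble(
      sample = rep(samp, each = nrow(FR)),
      metabolite = met,
      k = rep(0:(nrow(FR) - 1L), times = length(samp)),
      fe = as.vector(FR))
  }
  if (length(sample_rows) == 0L) stop("no quantifiable (sample, metabolite) pairs", call. = FALSE)

  cond_of <- setNames(sample_meta$condition, sample_meta$sample)
  trac_of <- setNames(sample_meta$tracer, sample_meta$sample)

  samples <- dplyr::bind_rows(sample_rows)
  samples <- tibble::tibble(sample = samples$sample,
                            condition = unname(cond_of[samples$sample]),
                            tracer = unname(trac_of[samples$sample]),
                            metabolite = samples$metabolite,
                            total_labelling = samples$total_labelling)

  totals <- grouped_mean_sem(samples$total_labelling,
                             list(condition = samples$condition,
                                  tracer = samples$tracer,
                                  metabolite = samples$metabolite))
  names(totals)[names(totals) == "mean"] <- "total_mean"
  names(totals)[names(totals) == "sem"] <- "total_sem"

  fr <- dplyr::bind_rows(frac_rows)
  fractions <- grouped_mean_sem(fr$fe,
                                list(condition = unname(cond_of[fr$sample]),
                                     tracer = unname(trac_of[fr$sample]),
                                     metabolite = fr$metabolite, k = fr$k))
  names(fractions)[names(fractions) == "mean"] <- "FE_mean"
  names(fractions)[names(fractions) == "sem"] <- "FE_sem"

  enrichment_table(totals, samples = samples, fractions = fractions)
}

# fast grouped mean / sem / n over a list of key vectors
grouped_mean_sem <- function(x, keys) {
  key <- do.call(paste, c(keys, sep = "\r"))
  first <- !duplicated(key)
  f <- factor(key, levels = key[first])
  n <- as.integer(tabulate(f))
  s1 <- rowsum(x, f, reorder = FALSE)[, 1L]
  s2 <- rowsum(x * x, f, reorder = FALSE)[, 1L]
  mu <- s1 / n
  varhat <- (s2 - n * mu^2) / pmax(n - 1L, 1L)
  sem <- ifelse(n > 1L, sqrt(pmax(varhat, 0) / n), NA_real_)
  out <- tibble::as_tibble(lapply(keys, function(kv) kv[first]))
  out$mean <- unname(mu)
  out$sem <- unname(sem)
  out$n <- n
  out
}

# long CSV layout of an enrichment table (per-isotopologue rows)
enrichment_csv <- function(enr) {
  if (!is.null(enr$fractions)) {
    enr$fractions |>
      dplyr::left_join(enr$totals[, c("condition", "tracer", "metabolite", "total_mean")],
                       by = c("condition", "tracer", "metabolite")) |>
      dplyr::rename(total_labelling = "total_mean") |>
      dplyr::arrange(.data$condition, .data$tracer, .data$metabolite, .data$k)
  } else {
    enr$totals |>
      dplyr::transmute(condition = .data$condition, tracer = .data$tracer,
                       metabolite = .data$metabolite, k = NA_integer_,
                       FE_mean = NA_real_, FE_sem = NA_real_,
                       total_labelling = .data$total_mean, n = .data$n) |>
      dplyr::arrange(.data$condition, .data$tracer, .data$metabolite)
  }
}

#' Normalize product labelling to its precursor's enrichment
#'
#' Divides a product metabolite's labelling by the fractional enrichment of
#' the cognate isotopologue of its precursor measured in the same condition
#' (e.g. UMP M+1 labelling over intracellular glutamine M+1 FE for the
#' amide-glutamine tracer), correcting for differences in intracellular
#' tracer accumulation. Ratios above 1 are possible and flagged with a
#' warning rather than clamped.
#'
#' @param product Product labelling (FE or total labelling, in 0..1).
#' @param precursor_fe Precursor fractional enrichment, must be positive.
#' @return `product / precursor_fe`.
#' @examples
#' normalize_to_precursor(0.12, 0.6)
#' @export
normalize_to_precursor <- function(product, precursor_fe) {
  if (any(precursor_fe <= 0)) {
    stop("precursor fractional enrichment must be positive", call. = FALSE)
  }
  ratio <- product / precursor_fe
  if (any(ratio > 1)) {
    warning("precursor-normalized labelling exceeds 1 for some entries")
  }
  ratio
}

#' Scale a set of values to its maximum
#'
#' Row-max normalization for cross-condition heat maps: every value is
#' divided by the maximum across conditions so the condition with maximal
#' labelling becomes exactly 1. Idempotent and order-preserving.
#'
#' @param values Non-negative numeric vector with at least one positive
#'   entry.
#' @return `values / max(values)`.
#' @examples
#' rowmax_normalize(c(0.2, 0.4))
#' @export
rowmax_normalize <- function(values) {
  if (length(values) == 0L || all(values == 0) || any(values < 0) || anyNA(values)) {
    stop("rowmax_normalize needs >= 1 positive value and no negatives", call. = FALSE)
  }
  values / max(values)
}

#' Area under a labelling time course
#'
#' Trapezoidal area under fractional enrichment sampled at ascending times,
#' in FE x hours. Used to compare labelling kinetics between conditions
#' (e.g. uridine-replete vs deprived) by testing AUC values.
#'
#' @param times Strictly increasing numeric vector of time points (hours).
#' @param values Fractional enrichment at each time.
#' @return Scalar area.
#' @examples
#' timecourse_auc(c(0, 6, 18), c(0, 0.2, 0.4))  # 4.2
#' @export
timecourse_auc <- function(times, values) {
  if (length(times) < 2L) stop("AUC needs at least 2 time points", call. = FALSE)
  if (length(times) != length(values)) stop("times and values differ in length", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  pracma::trapz(times, values)
}
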