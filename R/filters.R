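#' Filter cascade configuration
#'
#' Thresholds for the five-rule metabolite quality filter applied before
#' scoring and visualization. Thresholds that are percentages are stored in
#' percent. Boundary semantics follow the rule wording literally: labelling
#' strictly below `min_summed_labelling` removes, control labelling strictly
#' above `max_unlabelled_labelling` removes, summed labelling strictly above
#' `max_summed_labelling` removes; ties keep the metabolite.
#'
#' @param min_samples_quantified Minimum number of samples in which a
#'   metabolite must be quantified (intensity > 0); "more than one sample"
#'   gives the default 2.
#' @param pool_size_threshold Experiment-defined mean pool-size floor, in
#'   intensity units (presets used in practice: 2e6 for one experiment
#'   design, 1e5 for another).
#' @param min_summed_labelling Minimum summed total labelling across all
#'   tracer conditions, percent (default 1).
#' @param max_unlabelled_labelling Maximum apparent labelling tolerated in
#'   any tracer-free control sample, percent (default 3).
#' @param max_summed_labelling Maximum summed total labelling across all
#'   tracer conditions, percent (default 500).
#' @param summed_mode `"sum"` (default) to read "across all conditions" as
#'   the sum over (condition, tracer) pairs, `"max"` for the maximum.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_samples_quantified = 2,
                          pool_size_threshold = 1e5,
                          min_summed_labelling = 1,
                          max_unlabelled_labelling = 3,
                          max_summed_labelling = 500,
                          summed_mode = c("sum", "max")) {
  summed_mode <- match.arg(summed_mode)
  vals <- c(min_samples_quantified, pool_size_threshold, min_summed_labelling,
            max_unlabelled_labelling, max_summed_labelling)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("filter thresholds must be non-negative numbers", call. = FALSE)
  }
  if (min_summed_labelling >= max_summed_labelling) {
    stop("min_summed_labelling must be below max_summed_labelling", call. = FALSE)
  }
  structure(list(min_samples_quantified = min_samples_quantified,
                 pool_size_threshold = pool_size_threshold,
                 min_summed_labelling = min_summed_labelling,
                 max_unlabelled_labelling = max_unlabelled_labelling,
                 max_summed_labelling = max_summed_labelling,
                 summed_mode = summed_mode),
            class = "filter_config")
}

#' Apply the metabolite filter cascade
#'
#' Evaluates five independent removal rules per metabolite; reasons
#' accumulate, and the kept/removed sets partition the input metabolite
#' set exactly. Rules:
#' \describe{
#'   \item{LOW_QUANT}{quantified (pool > 0) in fewer than
#'     `min_samples_quantified` samples;}
#'   \item{LOW_POOL}{mean pool size over quantified samples below
#'     `pool_size_threshold`;}
#'   \item{LOW_LABEL}{summed total labelling across all tracer conditions
#'     strictly below `min_summed_labelling` percent;}
#'   \item{CONTROL_CONTAM}{apparent labelling strictly above
#'     `max_unlabelled_labelling` percent in any tracer-free control
#'     sample (skipped with a warning when no controls are present);}
#'   \item{OVER_LABEL}{summed total labelling strictly above
#'     `max_summed_labelling` percent.}
#' }
#' Summed labelling is computed from the replicate-mean enrichment table;
#' LOW_QUANT and CONTROL_CONTAM inspect per-sample data.
#'
#' @param enrichment An [enrichment_table()].
#' @param pools Pool-size tables from [pool_sizes()], or `NULL` to skip the
#'   two pool-based rules.
#' @param config A [filter_config()].
#' @return Object of class `filter_report`: list with `kept` and `removed`
#'   metabolite character vectors, `reasons` (named list) and `table`
#'   (per-metabolite tibble of the quantities each rule inspected).
#' @export
apply_filter_cascade <- function(enrichment, pools = NULL,
                                 config = filter_config()) {
  stopifnot(inherits(enrichment, "enrichment_table"))
  totals <- enrichment$totals
  mets <- sort(unique(c(totals$metabolite,
                        if (!is.null(pools)) pools$metabolites$metabolite)))

  # summed (or max) labelling across all tracer conditions, as a fraction
  # (compared against threshold/100 so boundary ties are exact)
  tr <- totals[!totals$is_control, ]
  agg <- tapply(tr$total_mean, tr$metabolite,
                if (config$summed_mode == "sum") sum else max)
  summed_frac <- setNames(rep(0, length(mets)), mets)
  summed_frac[names(agg)] <- unlist(agg)

  # control contamination fraction from per-sample control rows
  ctrl <- enrichment$samples[enrichment$samples$tracer == UNLABELLED, ]
  have_controls <- nrow(ctrl) > 0L
  max_ctrl <- setNames(rep(NA_real_, length(mets)), mets)
  if (have_controls) {
    mc <- tapply(ctrl$total_labelling, ctrl$metabolite, max)
    max_ctrl[names(mc)] <- unlist(mc)
  } else {
    warning("no tracer-free control samples: CONTROL_CONTAM rule skipped")
  }

  n_quant <- setNames(rep(NA_integer_, length(mets)), mets)
  mean_pool <- setNames(rep(NA_real_, length(mets)), mets)
  if (!is.null(pools)) {
    pm <- pools$metabolites
    n_quant[pm$metabolite] <- pm$n_quantified
    mean_pool[pm$metabolite] <- pm$mean_pool
  }

  reasons <- lapply(mets, function(m) {
    r <- character()
    if (!is.null(pools)) {
      if (!is.na(n_quant[[m]]) && n_quant[[m]] < config$min_samples_quantified) {
        r <- c(r, "LOW_QUANT")
      }
      if (!is.na(mean_pool[[m]]) && mean_pool[[m]] < config$pool_size_threshold) {
        r <- c(r, "LOW_POOL")
      }
    }
    if (summed_frac[[m]] < config$min_summed_labelling / 100) r <- c(r, "LOW_LABEL")
    if (have_controls && !is.na(max_ctrl[[m]]) &&
        max_ctrl[[m]] > config$max_unlabelled_labelling / 100) {
      r <- c(r, "CONTROL_CONTAM")
    }
    if (summed_frac[[m]] > config$max_summed_labelling / 100) r <- c(r, "OVER_LABEL")
    r
  })
  names(reasons) <- mets
  removed <- mets[lengths(reasons) > 0L]
  kept <- setdiff(mets, removed)

  tab <- tibble::tibble(
    metabolite = mets,
    status = ifelse(mets %in% removed, "removed", "kept"),
    reasons = vapply(reasons, paste, character(1L), collapse = ";"),
    n_quantified = unname(n_quant),
    mean_pool = unname(mean_pool),
    summed_labelling_pct = unname(summed_frac) * 100,
    max_control_pct = unname(max_ctrl) * 100)

  structure(list(kept = kept, removed = removed,
                 reasons = reasons[removed], table = tab),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d, removed %d metabolite(s)\n",
              length(x$kept), length(x$removed)))
  if (length(x$removed) > 0L) {
    counts <- table(unlist(x$reasons))
    cat("  reasons:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  }
  invisible(x)
}

filter_report_csv <- function(report) report$table
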