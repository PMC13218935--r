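#' Run the full nitrogen metabolism profiling pipeline
#'
#' End-to-end analysis of a validated peak table: pool sizes and
#' probabilistic quotient normalization factors, natural-abundance-corrected
#' enrichment table, metabolite filter cascade, differential labelling
#' score waterfall between the two conditions, and per-condition Sankey
#' flow sets. Pool-size filtering uses raw (pre-PQN) intensities; PQN
#' factors and the normalized pool matrix are returned for QC and
#' steady-state contrasts.
#'
#' @param records Peak records from [read_peak_table()] or
#'   [simulate_peak_table()].
#' @param catalog Metabolite catalog.
#' @param registry Tracer registry.
#' @param config Run configuration list ([read_run_config()]).
#' @return List with `enrichment`, `pools`, `pqn` (factors + normalized
#'   matrix, `NULL` when fewer than 2 samples), `filter_report`, `scores`
#'   (ranked waterfall tibble), `sankey` (named list per condition) and
#'   `seed`.
#' @export
run_profiling <- function(records, catalog = read_catalog(),
                          registry = read_tracer_registry(catalog = catalog),
                          config = read_run_config()) {
  pools <- pool_sizes(records)

  pqn <- NULL
  wide <- tidyr::pivot_wider(pools$samples[, c("sample", "metabolite", "pool")],
                             names_from = "metabolite", values_from = "pool")
  mat <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(mat) <- wide$sample
  if (nrow(mat) >= 2L) {
    pqn <- tryCatch(pqn_normalize(mat), error = function(e) {
      message("PQN skipped: ", conditionMessage(e))
      NULL
    })
  }

  enr <- build_enrichment_table(records, catalog, registry,
                                mode = config$correction_mode)

  fcfg <- filter_config(min_samples_quantified = config$min_samples_quantified,
                        pool_size_threshold = config$pool_size_threshold,
                        min_summed_labelling = config$min_summed_labelling,
                        max_unlabelled_labelling = config$max_unlabelled_labelling,
                        max_summed_labelling = config$max_summed_labelling,
                        summed_mode = config$summed_mode)
  report <- apply_filter_cascade(enr, pools, fcfg)

  conds <- sort(unique(records$condition))
  c1 <- config$condition1 %||% conds[1L]
  c2 <- config$condition2 %||% conds[2L]
  scores <- NULL
  if (length(conds) == 2L && length(report$kept) > 0L) {
    scores <- tryCatch(
      rank_waterfall(score_table(enr, c1, c2, kept = report$kept)),
      error = function(e) {
        message("scoring skipped: ", conditionMessage(e))
        NULL
      })
  }

  sankey <- lapply(setNames(conds, conds), function(cn) {
    flows_cat <- catalog
    flows_cat$representative <- flows_cat$representative &
      flows_cat$metabolite %in% report$kept
    has_rep <- tapply(flows_cat$representative, flows_cat$pathway, any)
    flows_cat <- flows_cat[flows_cat$pathway %in% names(has_rep)[has_rep], ]
    build_sankey_flows(enr, flows_cat, threshold = config$sankey_threshold,
                       condition = cn)
  })

  list(enrichment = enr, pools = pools, pqn = pqn, filter_report = report,
       scores = scores, sankey = sankey, seed = config$seed)
}

#' Waterfall plot of differential labelling scores
#'
#' Bar plot of ranked differential labelling scores (requires ggplot2).
#'
#' @param scores Ranked tibble from [rank_waterfall()].
#' @param top_n Optionally restrict to the `top_n` most extreme scores at
#'   each end.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(scores, top_n = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  if (!is.null(top_n)) {
    scores <- scores[scores$rank <= top_n | scores$rank > nrow(scores) - top_n, ]
  }
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$score > 0), show.legend = FALSE) +
    ggplot2::labs(x = "rank", y = "differential labelling score") +
    ggplot2::theme_minimal()
}
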