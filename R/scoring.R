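#' Differential labelling score
#'
#' Signed ranking statistic for a tracer-metabolite pair between two
#' conditions:
#' \deqn{|\ln(FE_1 / FE_2)| \times (FE_1 - FE_2)}
#' where the log arguments are clamped below at `eps` so that zero
#' enrichments remain scoreable (the difference term uses the unclamped
#' values). The score is antisymmetric in its arguments, zero exactly at
#' equality, and its sign agrees with the direction of the difference.
#'
#' @param fe1,fe2 Fractional enrichments (total labelling) in condition 1
#'   and condition 2, each in 0..1. Vectorized.
#' @param eps Lower clamp inside the logarithm (default 1e-6).
#' @return Signed numeric score(s).
#' @examples
#' differential_labelling_score(0.4, 0.1)  # |ln 4| * 0.3
#' @export
differential_labelling_score <- function(fe1, fe2, eps = 1e-6) {
  if (any(fe1 < 0 | fe1 > 1 | fe2 < 0 | fe2 > 1, na.rm = TRUE)) {
    stop("fractional enrichments must lie in [0, 1]", call. = FALSE)
  }
  abs(log(pmax(fe1, eps) / pmax(fe2, eps))) * (fe1 - fe2)
}

#' Score table of differential labelling between two conditions
#'
#' Computes one differential labelling score per (tracer, metabolite) pair
#' present in both conditions, using replicate-mean total labelling.
#' Tracer-free control rows are excluded. Pairs present in only one
#' condition are omitted with a message.
#'
#' @param enrichment An [enrichment_table()] containing exactly the two
#'   contrasted conditions (others raise an error).
#' @param condition1,condition2 Condition labels; the score is positive
#'   when labelling is higher in `condition1`.
#' @param kept Optional character vector of metabolites to restrict to
#'   (e.g. the `kept` set of a [apply_filter_cascade()] report).
#' @param eps Log clamp passed to [differential_labelling_score()].
#' @return Tibble: tracer, metabolite, fe1, fe2, score.
#' @export
score_table <- function(enrichment, condition1, condition2, kept = NULL,
                        eps = 1e-6) {
  stopifnot(inherits(enrichment, "enrichment_table"))
  totals <- enrichment$totals[!enrichment$totals$is_control, ]
  conds <- unique(totals$condition)
  if (!all(c(condition1, condition2) %in% conds)) {
    stop("both contrasted conditions must be present in the enrichment table",
         call. = FALSE)
  }
  if (length(conds) != 2L) {
    stop(sprintf("scoring requires exactly 2 conditions, found %d", length(conds)),
         call. = FALSE)
  }
  if (!is.null(kept)) totals <- totals[totals$metabolite %in% kept, ]
  t1 <- totals[totals$condition == condition1, c("tracer", "metabolite", "total_mean")]
  t2 <- totals[totals$condition == condition2, c("tracer", "metabolite", "total_mean")]
  merged <- dplyr::inner_join(t1, t2, by = c("tracer", "metabolite"),
                              suffix = c("1", "2"))
  n_only <- nrow(t1) + nrow(t2) - 2L * nrow(merged)
  if (n_only > 0L) {
    message(sprintf("score_table: omitted %d pair(s) present in only one condition",
                    n_only))
  }
  if (nrow(merged) == 0L) stop("no (tracer, metabolite) pair present in both conditions",
                               call. = FALSE)
  tibble::tibble(tracer = merged$tracer,
                 metabolite = merged$metabolite,
                 fe1 = merged$total_mean1,
                 fe2 = merged$total_mean2,
                 score = differential_labelling_score(merged$total_mean1,
                                                      merged$total_mean2, eps = eps))
}

#' Rank scores for a waterfall plot
#'
#' Orders score records by descending score and assigns ranks 1..N. Ties
#' are broken lexicographically by (tracer, metabolite) so reruns are
#' byte-identical.
#'
#' @param records Tibble from [score_table()].
#' @return The records ordered with a `rank` column added.
#' @export
rank_waterfall <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("rank_waterfall: no score records", call. = FALSE)
  }
  ord <- order(-records$score, records$tracer, records$metabolite)
  out <- records[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Build Sankey tracer-to-pathway flow sets
#'
#' Constructs the weighted edge set of a Sankey diagram for one condition:
#' one edge per (tracer, pathway-representative metabolite) with weight
#' equal to the tracer's total labelling of that metabolite. Metabolites
#' with total labelling strictly below the visualization threshold are
#' excluded (default 5 percent; ties are drawn). Tracer-free control rows
#' never contribute edges. Nodes are ordered by total outgoing (tracers) or
#' incoming (pathways) weight, descending, for stable rendering.
#'
#' @param enrichment An [enrichment_table()].
#' @param pathway_map Tibble mapping `metabolite` to `pathway` with a
#'   logical `representative` column (a catalog from [read_catalog()]
#'   works directly).
#' @param threshold Exclusion threshold in percent total labelling
#'   (default 5).
#' @param condition Condition label to build the flow set for.
#' @return Object of class `sankey_flows`: list with `edges` (tibble:
#'   condition, tracer, metabolite, pathway, weight), `tracers` and
#'   `pathways` (ordered node names).
#' @export
build_sankey_flows <- function(enrichment, pathway_map, threshold = 5,
                               condition) {
  stopifnot(inherits(enrichment, "enrichment_table"))
  if (!all(c("metabolite", "pathway") %in% names(pathway_map))) {
    stop("pathway_map needs metabolite and pathway columns", call. = FALSE)
  }
  if (!"representative" %in% names(pathway_map)) pathway_map$representative <- TRUE
  totals <- enrichment$totals
  totals <- totals[!totals$is_control & totals$condition == condition, ]
  reps <- pathway_map[pathway_map$representative, c("metabolite", "pathway")]
  orphan <- setdiff(unique(pathway_map$pathway), unique(reps$pathway))
  if (length(orphan) > 0L) {
    stop(sprintf("pathway class(es) without a representative: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  edges <- dplyr::inner_join(totals, reps, by = "metabolite")
  edges <- edges[!(edges$total_mean < threshold / 100), ]
  edges <- tibble::tibble(condition = edges$condition,
                          tracer = edges$tracer,
                          metabolite = edges$metabolite,
                          pathway = edges$pathway,
                          weight = edges$total_mean)
  edges <- edges[order(edges$tracer, edges$metabolite), ]
  out_w <- sort(tapply(edges$weight, edges$tracer, sum), decreasing = TRUE)
  in_w <- sort(tapply(edges$weight, edges$pathway, sum), decreasing = TRUE)
  structure(list(edges = edges,
                 tracers = names(out_w),
                 pathways = names(in_w),
                 condition = condition,
                 threshold = threshold),
            class = "sankey_flows")
}

#' @export
print.sankey_flows <- function(x, ...) {
  cat(sprintf("<sankey_flows> condition '%s': %d edge(s), %d tracer(s) -> %d pathway(s) (threshold %g%%)\n",
              x$condition, nrow(x$edges), length(x$tracers), length(x$pathways),
              x$threshold))
  invisible(x)
}

sankey_edges_csv <- function(flows) flows$edges

# nodes[]/links[] document consumable by standard Sankey renderers
sankey_json_document <- function(flows) {
  nodes <- c(flows$tracers, paste0("pathway:", flows$pathways))
  idx <- setNames(seq_along(nodes) - 1L, nodes)
  links <- lapply(seq_len(nrow(flows$edges)), function(i) {
    e <- flows$edges[i, ]
    list(source = unname(idx[[e$tracer]]),
         target = unname(idx[[paste0("pathway:", e$pathway)]]),
         metabolite = e$metabolite,
         value = e$weight)
  })
  list(condition = flows$condition,
       threshold_percent = flows$threshold,
       nodes = lapply(nodes, function(n) list(name = n)),
       links = links)
}
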