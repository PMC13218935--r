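# build a minimal enrichment table + pools for filter tests; `label` is the
# per-(condition,tracer) total labelling per metabolite (a named list of
# numeric vectors over tracer conditions), `control` the apparent labelling
# in the tracer-free control sample
make_filter_input <- function(label, control = NULL, pool = 1e7,
                              n_quantified = 4L) {
  mets <- names(label)
  totals <- dplyr::bind_rows(lapply(mets, function(m) {
    fe <- label[[m]]
    dplyr::bind_rows(
      tibble::tibble(condition = "A", tracer = paste0("tr", seq_along(fe)),
                     metabolite = m, total_mean = fe, n = 1L),
      tibble::tibble(condition = "A", tracer = UNLABELLED_ID, metabolite = m,
                     total_mean = if (is.null(control)) 0 else control[[m]],
                     n = 1L))
  }))
  enr <- enrichment_table(totals)
  pools <- list(metabolites = tibble::tibble(metabolite = mets,
                                             mean_pool = rep_len(pool, length(mets)),
                                             n_quantified = rep_len(n_quantified,
                                                                    length(mets))))
  list(enr = enr, pools = pools)
}
UNLABELLED_ID <- "unlabelled"

test_that("each filter rule fires on its canonical violation", {
  inp <- make_filter_input(
    label = list(clean = 0.40,          # kept: well-behaved
                 faint = 0.004,         # LOW_LABEL: summed 0.4% < 1%
                 contam = 0.40,         # CONTROL_CONTAM via control arg below
                 hot = c(rep(0.9, 6), 0.6)),  # OVER_LABEL: summed 600%
    control = list(clean = 0, faint = 0, contam = 0.04, hot = 0))
  inp$pools$metabolites$n_quantified[inp$pools$metabolites$metabolite == "clean"] <- 8L
  report <- apply_filter_cascade(inp$enr, inp$pools)
  expect_setequal(report$kept, "clean")
  expect_equal(report$reasons$faint, "LOW_LABEL")
  expect_equal(report$reasons$contam, "CONTROL_CONTAM")
  expect_equal(report$reasons$hot, "OVER_LABEL")

  # quantified in exactly one sample -> LOW_QUANT; low mean pool -> LOW_POOL
  inp2 <- make_filter_input(label = list(rare = 0.40, tiny = 0.40))
  inp2$pools$metabolites$n_quantified <- c(1L, 5L)
  inp2$pools$metabolites$mean_pool <- c(1e7, 5e4)
  report2 <- apply_filter_cascade(inp2$enr, inp2$pools)
  expect_equal(report2$reasons$rare, "LOW_QUANT")
  expect_equal(report2$reasons$tiny, "LOW_POOL")
})

test_that("reasons accumulate and kept/removed partition the input", {
  inp <- make_filter_input(label = list(bad = 0.004, ok = 0.3),
                           control = list(bad = 0.05, ok = 0))
  inp$pools$metabolites$mean_pool <- c(10, 1e7)
  report <- apply_filter_cascade(inp$enr, inp$pools)
  expect_setequal(report$reasons$bad, c("LOW_POOL", "LOW_LABEL", "CONTROL_CONTAM"))
  all_mets <- report$table$metabolite
  expect_setequal(c(report$kept, report$removed), all_mets)
  expect_length(intersect(report$kept, report$removed), 0)
})

test_that("raising the low-labelling threshold never rescues a metabolite", {
  set.seed(31)
  labels <- as.list(runif(20, 0, 0.05))
  names(labels) <- paste0("m", 1:20)
  inp <- make_filter_input(label = labels)
  removed_sets <- lapply(c(0.5, 1, 2, 4), function(thr) {
    apply_filter_cascade(inp$enr, inp$pools,
                         filter_config(min_summed_labelling = thr))$removed
  })
  for (i in seq_len(length(removed_sets) - 1L)) {
    expect_true(all(removed_sets[[i]] %in% removed_sets[[i + 1L]]))
  }
})

test_that("threshold boundaries are sharp with ties keeping the metabolite", {
  # 1% summed-labelling boundary: strictly below removes, exactly 1% keeps
  sweep <- seq(0.1, 2.0, by = 0.1)
  kept <- vapply(sweep, function(v) {
    inp <- make_filter_input(label = setNames(list(v / 100), "m"))
    "m" %in% apply_filter_cascade(inp$enr, inp$pools)$kept
  }, logical(1L))
  expect_equal(min(sweep[kept]), 1.0)

  # 3% control boundary: strictly above removes
  sweep5 <- seq(0.5, 6, by = 0.5)
  kept5 <- vapply(sweep5, function(v) {
    inp <- make_filter_input(label = list(m = 0.2),
                             control = setNames(list(v / 100), "m"))
    "m" %in% apply_filter_cascade(inp$enr, inp$pools)$kept
  }, logical(1L))
  expect_equal(max(sweep5[kept5]), 3.0)

  # 500% summed boundary: strictly above removes
  sweep6 <- seq(100, 700, by = 50)
  kept6 <- vapply(sweep6, function(v) {
    inp <- make_filter_input(label = setNames(list(rep(v / 1000, 10)), "m"))
    "m" %in% apply_filter_cascade(inp$enr, inp$pools)$kept
  }, logical(1L))
  expect_equal(max(sweep6[kept6]), 500)
})

test_that("missing control samples skip the contamination rule with a warning", {
  totals <- tibble::tibble(condition = "A", tracer = "tr1", metabolite = "m",
                           total_mean = 0.3, n = 1L)
  enr <- enrichment_table(totals)
  expect_warning(report <- apply_filter_cascade(enr, NULL), "control")
  expect_equal(report$kept, "m")
})

test_that("max mode reads the summed-labelling rule as a maximum", {
  inp <- make_filter_input(label = list(m = c(0.004, 0.02)))
  # sum = 2.4% keeps under sum mode; max = 2% also keeps; both modes agree here
  expect_true("m" %in% apply_filter_cascade(inp$enr, inp$pools)$kept)
  # but a metabolite at 0.6% + 0.6% differs: sum 1.2% keeps, max 0.6% removes
  inp2 <- make_filter_input(label = list(m = c(0.006, 0.006)))
  expect_true("m" %in% apply_filter_cascade(inp2$enr, inp2$pools)$kept)
  rep_max <- apply_filter_cascade(inp2$enr, inp2$pools,
                                  filter_config(summed_mode = "max"))
  expect_true("m" %in% rep_max$removed)
})
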