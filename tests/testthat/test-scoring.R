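test_that("differential labelling score evaluates the published formula", {
  expect_equal(differential_labelling_score(0.3, 0.3), 0)
  # independent arithmetic check of |ln(0.4/0.1)| * (0.4 - 0.1)
  expect_equal(differential_labelling_score(0.4, 0.1),
               abs(log(4)) * 0.3, tolerance = 1e-12)
  expect_equal(differential_labelling_score(0.4, 0.1), 0.4158883,
               tolerance = 1e-7)
  expect_equal(differential_labelling_score(0.1, 0.4), -0.4158883,
               tolerance = 1e-7)
  expect_error(differential_labelling_score(1.2, 0.1), "\\[0, 1\\]")
})

test_that("score algebra: antisymmetry, sign, and growth with the gap", {
  set.seed(41)
  a <- runif(200, 1e-6, 1)
  b <- runif(200, 1e-6, 1)
  s_ab <- differential_labelling_score(a, b)
  s_ba <- differential_labelling_score(b, a)
  expect_equal(s_ab, -s_ba, tolerance = 1e-12)
  expect_true(all(sign(s_ab) == sign(a - b)))
  # at fixed ratio, |score| grows with |a - b|
  ratio <- 3
  small <- differential_labelling_score(0.15, 0.15 / ratio)
  large <- differential_labelling_score(0.45, 0.45 / ratio)
  expect_gt(large, small)
  # zero enrichments remain scoreable through the epsilon clamp
  expect_true(is.finite(differential_labelling_score(0.2, 0)))
  expect_gt(differential_labelling_score(0.2, 0), 0)
})

test_that("score tables pair conditions and honour the kept set", {
  totals <- dplyr::bind_rows(
    tibble::tibble(condition = "A", tracer = c("leucine", "glutamine", "valine"),
                   metabolite = "glutamate", total_mean = c(0.4, 0.1, 0.2), n = 1L),
    tibble::tibble(condition = "B", tracer = c("leucine", "glutamine"),
                   metabolite = "glutamate", total_mean = c(0.1, 0.4), n = 1L))
  enr <- enrichment_table(totals)
  expect_message(st <- score_table(enr, "A", "B"), "omitted 1 pair")
  expect_equal(nrow(st), 2L)
  expect_equal(st$score[st$tracer == "leucine"], 0.4158883, tolerance = 1e-7)
  expect_equal(st$score[st$tracer == "glutamine"], -0.4158883, tolerance = 1e-7)
  expect_error(score_table(enr, "A", "C"), "must be present")

  # all pairs equal: all scores zero
  eq <- enrichment_table(dplyr::bind_rows(
    tibble::tibble(condition = "A", tracer = "t", metabolite = c("x", "y"),
                   total_mean = 0.3, n = 1L),
    tibble::tibble(condition = "B", tracer = "t", metabolite = c("x", "y"),
                   total_mean = 0.3, n = 1L)))
  expect_equal(score_table(eq, "A", "B")$score, c(0, 0))
})

test_that("waterfall ranking is descending with deterministic tie-breaks", {
  st <- tibble::tibble(tracer = c("b", "a", "c", "a"),
                       metabolite = c("m1", "m2", "m3", "m1"),
                       fe1 = 0, fe2 = 0,
                       score = c(0.2, -0.1, 0.5, 0.2))
  rk <- rank_waterfall(st)
  expect_equal(rk$score, c(0.5, 0.2, 0.2, -0.1))
  expect_equal(rk$rank, 1:4)
  # tie at 0.2 broken lexicographically: tracer "a" before "b"
  expect_equal(rk$tracer[2:3], c("a", "b"))
  expect_identical(rank_waterfall(st), rank_waterfall(st[sample(1:4), ]))
  expect_error(rank_waterfall(st[0, ]), "no score records")
})

test_that("sankey flows apply the visualization threshold to representatives", {
  pm <- tibble::tibble(metabolite = c("glutamate", "UMP"),
                       pathway = c("amino_acids", "pyrimidines"),
                       representative = TRUE)
  totals <- tibble::tibble(
    condition = "A",
    tracer = c("glutamine", "glutamine", "uridine"),
    metabolite = c("glutamate", "UMP", "UMP"),
    total_mean = c(0.06, 0.04, 0.30), n = 1L)
  fl <- build_sankey_flows(enrichment_table(totals), pm, threshold = 5,
                           condition = "A")
  expect_equal(nrow(fl$edges), 2L)  # the 4% edge is excluded
  expect_false(any(fl$edges$metabolite == "UMP" & fl$edges$tracer == "glutamine"))
  expect_equal(fl$edges$weight[fl$edges$tracer == "glutamine"], 0.06)
  # node ordering by flow weight, descending
  expect_equal(fl$tracers, c("uridine", "glutamine"))

  # JSON document indexes links into the node list
  doc <- azotrace:::sankey_json_document(fl)
  expect_length(doc$nodes, 4L)
  for (l in doc$links) {
    expect_gte(l$source, 0)
    expect_lt(l$target, length(doc$nodes))
  }

  empty <- enrichment_table(totals[0, ])
  fl0 <- build_sankey_flows(empty, pm, condition = "A")
  expect_equal(nrow(fl0$edges), 0L)

  bad_pm <- tibble::tibble(metabolite = "glutamate", pathway = "amino_acids",
                           representative = FALSE)
  expect_error(build_sankey_flows(enrichment_table(totals), bad_pm,
                                  condition = "A"),
               "without a representative")
})

test_that("non-representative metabolites never receive sankey edges", {
  pm <- tibble::tibble(metabolite = c("glutamate", "glutamine"),
                       pathway = "amino_acids",
                       representative = c(TRUE, FALSE))
  totals <- tibble::tibble(condition = "A", tracer = "leucine",
                           metabolite = c("glutamate", "glutamine"),
                           total_mean = c(0.3, 0.9), n = 1L)
  fl <- build_sankey_flows(enrichment_table(totals), pm, condition = "A")
  expect_equal(fl$edges$metabolite, "glutamate")
})
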