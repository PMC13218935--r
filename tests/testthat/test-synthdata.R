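test_that("default registry mirrors the 30-stock tracer library", {
  reg <- default_tracer_registry()
  expect_equal(nrow(reg), 30L)
  expect_equal(sum(reg$proteinogenic), 20L)
  expect_equal(reg$labelled_atoms[reg$tracer == "uridine"], 2L)
  expect_equal(reg$labelled_atoms[reg$tracer == "glutamine-amide"], 1L)
  expect_equal(reg$labelled_atoms[reg$tracer == "glutamine"], 2L)
})

test_that("default catalog is a valid nitrogenous metabolome", {
  catal <- default_catalog()
  expect_gte(nrow(catal), 100L)
  n_atoms <- vapply(catal$formula,
                    function(f) parse_formula(f)[["N"]], integer(1L))
  expect_true(all(n_atoms >= 1L))
  expect_true("UMP" %in% catal$metabolite)
  expect_equal(catal$formula[catal$metabolite == "UMP"], "C9H13N2O9P")
  reps <- tapply(catal$representative, catal$pathway, any)
  expect_true(all(reps))
  # the readouts highlighted in practice are flagged representatives
  expect_true(all(catal$representative[catal$metabolite %in%
                                         c("UMP", "UDP", "UTP", "glutamate",
                                           "glutathione")]))
})

test_that("planted flows define analytic ground-truth scores", {
  m <- base_model()
  m2 <- plant_differential_flow(m, "leucine", "glutamate", 0.4, 0.1)
  gt <- ground_truth_scores(m2)
  row <- gt[gt$tracer == "leucine" & gt$metabolite == "glutamate", ]
  expect_equal(row$score, 0.4158883, tolerance = 1e-7)
  m3 <- plant_differential_flow(m, "leucine", "glutamate", 0.2, 0.2)
  gt3 <- ground_truth_scores(m3)
  expect_equal(gt3$score[gt3$tracer == "leucine" & gt3$metabolite == "glutamate"], 0)
  expect_error(plant_differential_flow(m, "leucine", "unobtainium", 0.1, 0.2),
               "unknown metabolite")
  expect_error(plant_differential_flow(m, "15C-glc", "glutamate", 0.1, 0.2),
               "unknown tracer")
  # intact transfer cannot exceed the recipient's tracer atoms
  expect_error(plant_differential_flow(m, "hypoxanthine", "glutamate",
                                       0.1, 0.2, channel = "intact"),
               "exceeds")
})

test_that("peak-table simulation is a pure function of model and seed", {
  m <- base_model()
  t1 <- simulate_peak_table(m, seed = 77)
  t2 <- simulate_peak_table(m, seed = 77)
  expect_identical(t1, t2)
  t3 <- simulate_peak_table(m, seed = 78)
  expect_false(identical(t1$intensity, t3$intensity))
  # controls present per condition; replicate count honoured
  expect_true(all(c("A_unlabelled_r1", "B_unlabelled_r1") %in% t1$sample))
  t4 <- simulate_peak_table(m, n_replicates = 2)
  expect_equal(length(unique(t4$sample)), 2 * 31 * 2)
  expect_error(simulate_peak_table(m, n_replicates = 0), "positive integer")
})

test_that("planted transfer fractions are recovered end to end", {
  m <- ground_truth_model(noise_cv = 0.05, seed = 1)
  m <- plant_differential_flow(m, "glutamine-amide", "UMP", 0.30, 0.05)
  gt <- ground_truth_totals(m)
  errs <- c()
  planted_est <- c()
  for (s in 1:5) {
    pt <- simulate_peak_table(m, n_replicates = 3, seed = s)
    enr <- build_enrichment_table(pt, m$catalog, m$registry)
    est <- enr$totals[!enr$totals$is_control, ]
    merged <- dplyr::inner_join(
      est, gt, by = c("tracer", "metabolite", "condition"))
    expect_equal(nrow(merged), nrow(est))
    errs <- c(errs, abs(merged$total_mean - merged$fe_total))
    planted_est <- c(planted_est, merged$total_mean[
      merged$tracer == "glutamine-amide" & merged$metabolite == "UMP" &
        merged$condition == "A"])
  }
  # per-estimate noise at CV 5% / n = 3 has sd ~ 0.01 on the largest
  # fractions, so the error distribution is summarised rather than maxed
  expect_lt(median(errs), 0.005)
  expect_lt(sqrt(mean(errs^2)), 0.02)
  expect_lt(max(errs), 0.06)
  # the planted differential flow itself is recovered accurately on average
  expect_lt(abs(mean(planted_est) - 0.30), 0.02)
})

test_that("control samples never trip the contamination rule at low noise", {
  m <- base_model(noise_cv = 0.05, seed = 23)
  for (s in c(5, 6)) {
    pt <- simulate_peak_table(m, seed = s)
    res <- run_profiling(pt, m$catalog, m$registry)
    reasons <- unlist(res$filter_report$reasons)
    expect_false("CONTROL_CONTAM" %in% reasons)
  }
})

test_that("pixel-grid phantoms recover region enrichments", {
  m <- base_model(noise_cv = 0.05, seed = 2)
  h <- 20; w <- 30
  tumour <- matrix(FALSE, h, w); tumour[, 1:12] <- TRUE
  brain <- !tumour
  grid <- simulate_pixel_grid(m, "UMP", width = w, height = h,
                              regions = list(list(mask = tumour, fe = 0.30),
                                             list(mask = brain, fe = 0.05)),
                              shift = 1, seed = 13)
  out <- correct_pixel_grid(grid, correction_matrix("C9H13N2O9P"))
  fe1 <- out$images[, , 2]
  expect_lt(abs(mean(fe1[tumour]) - 0.30), 0.01)
  expect_lt(abs(mean(fe1[brain]) - 0.05), 0.01)

  # zero-enrichment phantom is clean after correction
  g0 <- simulate_pixel_grid(m, "UMP", width = 10, height = 10,
                            regions = list(list(mask = matrix(TRUE, 10, 10),
                                                fe = 0)), seed = 4)
  o0 <- correct_pixel_grid(g0, correction_matrix("C9H13N2O9P"))
  expect_lt(max(o0$total_labelling), 0.005)

  overlap <- list(list(mask = matrix(TRUE, 10, 10), fe = 0.1),
                  list(mask = matrix(TRUE, 10, 10), fe = 0.2))
  expect_error(simulate_pixel_grid(m, "UMP", 10, 10, overlap), "overlap")
})

test_that("time courses saturate and support AUC contrasts", {
  m <- base_model(noise_cv = 0)
  tc <- simulate_timecourse(m, times = c(0, 3, 6, 12, 18),
                            saturating_fe = 0.4, rate = 1e6)
  expect_equal(tc$fe[tc$time > 0], rep(0.4, 12), tolerance = 1e-9)
  tc0 <- simulate_timecourse(m, times = c(0, 6, 18), saturating_fe = 0,
                             rate = 0.2)
  mean_fe <- tapply(tc0$fe, tc0$time, mean)
  expect_equal(timecourse_auc(c(0, 6, 18), unname(mean_fe)), 0)
  expect_error(simulate_timecourse(m, times = 0, saturating_fe = 0.4,
                                   rate = 0.2), "ascending")
  expect_error(simulate_timecourse(m, times = c(0, 6), saturating_fe = 0.4,
                                   rate = -1), "non-negative")

  # replete vs deprived kinetics separate by AUC
  fast <- simulate_timecourse(m, times = c(0, 3, 6, 12, 18),
                              saturating_fe = 0.35, rate = 0.3)
  slow <- simulate_timecourse(m, times = c(0, 3, 6, 12, 18),
                              saturating_fe = 0.10, rate = 0.3)
  auc_of <- function(tc) {
    timecourse_auc(sort(unique(tc$time)), unname(tapply(tc$fe, tc$time, mean)))
  }
  expect_gt(auc_of(fast), auc_of(slow))
})
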