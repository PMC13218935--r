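# Independent oracles used across test files.

# Exhaustive per-atom enumeration of a molecule's isotopologue distribution.
# Every atom is enumerated over its isotope states with expand.grid; the
# probability mass is summed by total nominal shift. Labelled tracer atoms
# contribute a fixed shift of 1 each. Deliberately brute force and
# independent of the package's convolution code; only usable for small
# formulas.
enumerate_distribution <- function(formula, j, abundances, tracer = "N",
                                   resolved = TRUE, max_shift = NULL) {
  states <- list()
  for (el in names(formula)) {
    rows <- abundances[abundances$element == el, ]
    cnt <- formula[[el]]
    if (el == tracer) {
      # j labelled atoms (fixed shift 1), n - j unlabelled natural atoms
      if (j > 0) states <- c(states, rep(list(data.frame(shift = 1, p = 1)), j))
      cnt <- cnt - j
      if (cnt > 0) {
        states <- c(states, rep(list(data.frame(shift = rows$shift, p = rows$abundance)), cnt))
      }
    } else if (!resolved && cnt > 0) {
      states <- c(states, rep(list(data.frame(shift = rows$shift, p = rows$abundance)), cnt))
    }
  }
  n_tracer <- formula[[tracer]]
  if (is.null(max_shift)) max_shift <- n_tracer
  if (length(states) == 0L) {
    out <- numeric(max_shift + 1L)
    out[1L] <- 1
    return(out)
  }
  grids <- expand.grid(lapply(states, function(s) seq_len(nrow(s))))
  total_shift <- Reduce(`+`, lapply(seq_along(states),
                                    function(i) states[[i]]$shift[grids[[i]]]))
  prob <- Reduce(`*`, lapply(seq_along(states),
                             function(i) states[[i]]$p[grids[[i]]]))
  out <- numeric(max_shift + 1L)
  for (i in seq_along(total_shift)) {
    sh <- total_shift[i]
    if (sh <= max_shift) out[sh + 1L] <- out[sh + 1L] + prob[i]
  }
  out
}

# Dirichlet sampling via normalized gamma draws
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# A small ground-truth model reused by several tests (built once per run;
# tests that mutate it take copies via plant_differential_flow's value
# semantics).
base_model <- function(noise_cv = 0.05, seed = 11L, ...) {
  ground_truth_model(noise_cv = noise_cv, seed = seed, ...)
}

# tiny three-metabolite catalog/registry for focused IO tests
tiny_catalog <- function() {
  tibble::tibble(
    metabolite = c("glutamine", "glutamate", "UMP"),
    formula = c("C5H10N2O3", "C5H9NO4", "C9H13N2O9P"),
    pathway = c("amino_acids", "amino_acids", "pyrimidines"),
    representative = c(FALSE, TRUE, TRUE))
}

tiny_registry <- function() {
  tibble::tibble(tracer = c("glutamine", "glutamine-amide"),
                 nutrient = c("glutamine", "glutamine"),
                 labelled_atoms = c(2L, 1L),
                 element = "N", proteinogenic = c(TRUE, FALSE))
}
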