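#' Packaged default tracer registry and metabolite catalog
#'
#' The default registry emulates a 30-stock plasma-like-medium tracer
#' library: the 20 proteinogenic amino acids plus taurine, ornithine,
#' citrulline, hypoxanthine, uridine, nitrate, ammonium, urea, urate, and
#' an amide-position glutamine variant carrying a single labelled nitrogen.
#' The default catalog lists over 100 nitrogen-containing metabolites with
#' molecular formulas, pathway classes and pathway-representative flags.
#' Both are synthetic-but-realistic stand-ins for an experiment-specific
#' tracer/metabolite manifest and ship as editable CSVs under
#' `inst/extdata/`.
#'
#' @return A tibble (see [read_tracer_registry()] / [read_catalog()]).
#' @export
default_tracer_registry <- function() {
  read_tracer_registry()
}

#' @rdname default_tracer_registry
#' @export
default_catalog <- function() {
  read_catalog()
}

#' Ground-truth model for synthetic tracer experiments
#'
#' Defines the generative model behind [simulate_peak_table()]: a transfer
#' table of planted labelling fractions per (tracer, metabolite,
#' condition), per-metabolite pool-size means, and a multiplicative
#' lognormal noise model. Defaults emulate a two-condition profiling run of
#' the full tracer library: every tracer labels its own (cognate) nutrient
#' pool strongly, and a small diffuse background transfer places single
#' labelled nitrogens in every catalog metabolite, mimicking nitrogen
#' exchange through transamination networks. Condition-specific labelling
#' differences are added with [plant_differential_flow()].
#'
#' Transfers occur through two channels: `"intact"` places the tracer's
#' full labelled-atom count at M+m (moiety salvage), `"single"` places one
#' labelled nitrogen at M+1 (transamination-like transfer).
#'
#' @param registry Tracer registry (default packaged 30-stock library).
#' @param catalog Metabolite catalog (default packaged catalog).
#' @param conditions Two condition labels (default `c("A", "B")`).
#' @param cognate_fe Labelling fraction of each tracer's own nutrient pool
#'   through the intact channel (default 0.5).
#' @param background_fe Diffuse single-nitrogen transfer fraction from
#'   every tracer into every metabolite (default 0.02).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   intensity noise (default 0.10).
#' @param pool_meanlog,pool_sdlog Lognormal parameters of per-metabolite
#'   mean pool sizes (defaults `log(1e7)` and 0.5).
#' @param mode Correction-matrix mode used by the forward model.
#' @param seed Integer seed making pool sizes and all simulation
#'   reproducible.
#' @return Object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(registry = default_tracer_registry(),
                               catalog = default_catalog(),
                               conditions = c("A", "B"),
                               cognate_fe = 0.5,
                               background_fe = 0.02,
                               noise_cv = 0.10,
                               pool_meanlog = log(1e7),
                               pool_sdlog = 0.5,
                               mode = "resolved",
                               seed = 1L) {
  stopifnot(length(conditions) == 2L, cognate_fe >= 0, cognate_fe <= 1,
            background_fe >= 0, background_fe <= 1, noise_cv >= 0)
  n_atoms <- metabolite_atom_counts(catalog)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  pool_mean <- withr_seed(setNames(
    rlnorm(nrow(catalog), meanlog = pool_meanlog, sdlog = pool_sdlog),
    catalog$metabolite))

  bg <- expand.grid(tracer = registry$tracer, metabolite = catalog$metabolite,
                    condition = conditions, stringsAsFactors = FALSE)
  bg$fe <- background_fe
  bg$shift <- 1L
  cg <- expand.grid(tracer = registry$tracer, condition = conditions,
                    stringsAsFactors = FALSE)
  cg$metabolite <- registry$nutrient[match(cg$tracer, registry$tracer)]
  cg$shift <- pmin(registry$labelled_atoms[match(cg$tracer, registry$tracer)],
                   n_atoms[cg$metabolite])
  cg$fe <- cognate_fe
  flows <- dplyr::bind_rows(
    tibble::as_tibble(bg[bg$fe > 0, c("tracer", "metabolite", "condition", "shift", "fe")]),
    tibble::as_tibble(cg[cg$fe > 0, c("tracer", "metabolite", "condition", "shift", "fe")]))

  structure(list(registry = registry, catalog = catalog,
                 conditions = conditions, flows = flows,
                 n_atoms = n_atoms, pool_mean = pool_mean,
                 noise_cv = noise_cv, mode = mode, seed = as.integer(seed),
                 planted = tibble::tibble(tracer = character(),
                                          metabolite = character(),
                                          fe1 = double(), fe2 = double())),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf("<ground_truth_model> %d tracers x %d metabolites x 2 conditions; %d planted differential flow(s); noise CV %.2f; seed %d\n",
              nrow(x$registry), nrow(x$catalog), nrow(x$planted),
              x$noise_cv, x$seed))
  invisible(x)
}

#' Plant a condition-specific differential labelling flow
#'
#' Overrides the transfer fraction from `tracer` into `metabolite` with
#' `fe1` in the first condition and `fe2` in the second, through the chosen
#' channel. The planted pair is recorded so the ground-truth differential
#' labelling score is computable analytically ([ground_truth_scores()]).
#'
#' @param model A [ground_truth_model()].
#' @param tracer,metabolite Ids present in the model's registry/catalog.
#' @param fe1,fe2 Transfer fractions in 0..1 for the two conditions.
#' @param channel `"single"` (M+1, default) or `"intact"` (M+m).
#' @return The updated model.
#' @export
plant_differential_flow <- function(model, tracer, metabolite, fe1, fe2,
                                    channel = c("single", "intact")) {
  stopifnot(inherits(model, "ground_truth_model"))
  channel <- match.arg(channel)
  if (!tracer %in% model$registry$tracer) {
    stop(sprintf("unknown tracer '%s'", tracer), call. = FALSE)
  }
  if (!metabolite %in% model$catalog$metabolite) {
    stop(sprintf("unknown metabolite '%s'", metabolite), call. = FALSE)
  }
  if (any(c(fe1, fe2) < 0) || any(c(fe1, fe2) > 1)) {
    stop("planted fractions must lie in [0, 1]", call. = FALSE)
  }
  m <- model$registry$labelled_atoms[match(tracer, model$registry$tracer)]
  nN <- model$n_atoms[[metabolite]]
  shift <- if (channel == "single") 1L else as.integer(m)
  if (shift > nN) {
    stop(sprintf("intact transfer of %d atoms exceeds %s's %d tracer atoms",
                 shift, metabolite, nN), call. = FALSE)
  }
  fl <- model$flows
  drop <- fl$tracer == tracer & fl$metabolite == metabolite
  fl <- fl[!drop, ]
  add <- tibble::tibble(tracer = tracer, metabolite = metabolite,
                        condition = model$conditions,
                        shift = shift, fe = c(fe1, fe2))
  model$flows <- dplyr::bind_rows(fl, add)
  model$planted <- dplyr::bind_rows(
    model$planted[!(model$planted$tracer == tracer &
                      model$planted$metabolite == metabolite), ],
    tibble::tibble(tracer = tracer, metabolite = metabolite,
                   fe1 = fe1, fe2 = fe2))
  model
}

#' Ground-truth labelling totals and differential scores
#'
#' `ground_truth_totals()` returns the planted total labelling per
#' (tracer, metabolite, condition) — the sum over transfer channels.
#' `ground_truth_scores()` evaluates the differential labelling score
#' analytically on those totals for the planted pairs.
#'
#' @param model A [ground_truth_model()].
#' @return A tibble.
#' @export
ground_truth_totals <- function(model) {
  stopifnot(inherits(model, "ground_truth_model"))
  model$flows |>
    dplyr::group_by(.data$tracer, .data$metabolite, .data$condition) |>
    dplyr::summarise(fe_total = sum(.data$fe), .groups = "drop")
}

#' @rdname ground_truth_totals
#' @export
ground_truth_scores <- function(model) {
  gt <- ground_truth_totals(model)
  t1 <- gt[gt$condition == model$conditions[1L], ]
  t2 <- gt[gt$condition == model$conditions[2L], ]
  merged <- dplyr::inner_join(
    t1[, c("tracer", "metabolite", "fe_total")],
    t2[, c("tracer", "metabolite", "fe_total")],
    by = c("tracer", "metabolite"), suffix = c("1", "2"))
  tibble::tibble(tracer = merged$tracer, metabolite = merged$metabolite,
                 fe1 = merged$fe_total1, fe2 = merged$fe_total2,
                 score = differential_labelling_score(merged$fe_total1,
                                                      merged$fe_total2))
}

#' Simulate a long-format peak table from a ground-truth model
#'
#' For every (condition, tracer, replicate, metabolite) the planted
#' labelling fractions are assembled into a true enrichment vector,
#' forward-convolved with the metabolite's natural-abundance correction
#' matrix ([forward_convolve()] model), scaled by the metabolite's pool
#' size, and multiplied by lognormal noise. Tracer-free control samples
#' (tracer id `"unlabelled"`) are generated with zero transfer everywhere.
#' Identical `(model, seed)` give identical tables.
#'
#' @param model A [ground_truth_model()].
#' @param n_replicates Replicates per (condition, tracer); default 1,
#'   matching a profiling-scale design.
#' @param include_unlabelled_control Generate tracer-free control samples
#'   per condition (default TRUE).
#' @param seed Seed for the noise draws; defaults to the model seed.
#' @param noise_cv Override of the model's noise CV.
#' @return Tibble of peak records (see [read_peak_table()]).
#' @export
simulate_peak_table <- function(model, n_replicates = 1L,
                                include_unlabelled_control = TRUE,
                                seed = model$seed,
                                noise_cv = model$noise_cv) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (!is.numeric(n_replicates) || n_replicates < 1L ||
      n_replicates != round(n_replicates)) {
    stop("n_replicates must be a positive integer", call. = FALSE)
  }
  tracers <- model$registry$tracer
  if (include_unlabelled_control) tracers <- c(tracers, UNLABELLED)
  frame <- expand.grid(replicate = seq_len(n_replicates), tracer = tracers,
                       condition = model$conditions,
                       stringsAsFactors = FALSE)
  frame$sample <- sprintf("%s_%s_r%d", frame$condition, frame$tracer,
                          frame$replicate)
  nsamp <- nrow(frame)
  sdlog <- sqrt(log(1 + noise_cv^2))

  set.seed(seed)
  flows_by_met <- split(model$flows, model$flows$metabolite)
  out <- vector("list", nrow(model$catalog))
  for (mi in seq_len(nrow(model$catalog))) {
    met <- model$catalog$metabolite[mi]
    n <- model$n_atoms[[met]]
    FR <- matrix(0, nrow = n + 1L, ncol = nsamp)
    FR[1L, ] <- 1
    fl <- flows_by_met[[met]]
    if (!is.null(fl)) {
      for (fi in seq_len(nrow(fl))) {
        sel <- frame$tracer == fl$tracer[fi] & frame$condition == fl$condition[fi]
        if (!any(sel)) next
        s <- fl$shift[fi] + 1L
        FR[s, sel] <- FR[s, sel] + fl$fe[fi]
        FR[1L, sel] <- FR[1L, sel] - fl$fe[fi]
      }
    }
    if (any(FR[1L, ] < -1e-9)) {
      stop(sprintf("planted transfers into %s exceed total labelling 1", met),
           call. = FALSE)
    }
    FR[1L, ] <- pmax(FR[1L, ], 0)
    X <- if (n > 0L) {
      cached_correction_matrix(model$catalog$formula[mi], model$mode) %*% FR
    } else {
      FR
    }
    X <- X * model$pool_mean[[met]]
    if (noise_cv > 0) {
      X <- X * matrix(rlnorm(length(X), meanlog = -sdlog^2 / 2, sdlog = sdlog),
                      nrow = nrow(X))
    }
    out[[mi]] <- tibble::tibble(
      sample = rep(frame$sample, each = n + 1L),
      condition = rep(frame$condition, each = n + 1L),
      tracer = rep(frame$tracer, each = n + 1L),
      metabolite = met,
      k = rep(0:n, times = nsamp),
      intensity = as.vector(X))
  }
  dplyr::bind_rows(out)
}

#' Simulate a mass spectrometry imaging pixel grid
#'
#' Generates a per-pixel isotopologue grid for one metabolite with
#' region-specific planted fractional enrichments (e.g. tumour vs adjacent
#' brain), the forward natural-abundance model, and per-pixel lognormal
#' noise. Region masks must partition the grid.
#'
#' @param model A [ground_truth_model()] (supplies formulas and noise CV).
#' @param metabolite Catalog metabolite to image.
#' @param width,height Grid size in pixels.
#' @param regions List of regions, each `list(mask =, fe =)` with `mask` a
#'   `height x width` logical matrix and `fe` the planted enrichment at
#'   `shift`.
#' @param shift Mass shift carrying the planted label (default 1).
#' @param intensity Mean total intensity per pixel.
#' @param seed,noise_cv Noise controls; default to the model's.
#' @return A [pixel_grid()] with attribute `ground_truth` (the `height x
#'   width` matrix of planted enrichments).
#' @export
simulate_pixel_grid <- function(model, metabolite, width, height, regions,
                                shift = 1L, intensity = 1e4,
                                seed = model$seed, noise_cv = model$noise_cv) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (!metabolite %in% model$catalog$metabolite) {
    stop(sprintf("unknown metabolite '%s'", metabolite), call. = FALSE)
  }
  n <- model$n_atoms[[metabolite]]
  if (shift > n) stop("planted shift exceeds tracer-atom count", call. = FALSE)
  cover <- matrix(0L, nrow = height, ncol = width)
  for (r in regions) {
    if (!is.matrix(r$mask) || any(dim(r$mask) != c(height, width))) {
      stop("each region mask must be a height x width logical matrix", call. = FALSE)
    }
    cover <- cover + (r$mask * 1L)
  }
  if (any(cover > 1L)) stop("overlapping region masks", call. = FALSE)
  if (any(cover == 0L)) stop("region masks do not cover the grid", call. = FALSE)

  fe_truth <- matrix(0, nrow = height, ncol = width)
  for (r in regions) fe_truth[r$mask] <- r$fe
  # row-major pixel order: y rows, x columns
  fe_vec <- as.vector(t(fe_truth))
  npix <- width * height
  FR <- matrix(0, nrow = n + 1L, ncol = npix)
  FR[1L, ] <- 1 - fe_vec
  FR[shift + 1L, ] <- FR[shift + 1L, ] + fe_vec
  fml <- model$catalog$formula[match(metabolite, model$catalog$metabolite)]
  cmat <- cached_correction_matrix(fml, model$mode)
  X <- t(cmat %*% FR) * intensity
  set.seed(seed)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    X <- X * matrix(rlnorm(length(X), meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = nrow(X))
  }
  grid <- pixel_grid(X, width, height, metabolite)
  attr(grid, "ground_truth") <- fe_truth
  grid
}

#' Simulate a saturating labelling time course
#'
#' Fractional enrichment approaching saturation as
#' `FE(t) = saturating_fe * (1 - exp(-rate * t))`, with multiplicative
#' lognormal noise per observation. Supports AUC-based comparisons of
#' labelling kinetics ([timecourse_auc()]).
#'
#' @param model A [ground_truth_model()] (supplies noise CV).
#' @param times Ascending time points (hours); at least 2.
#' @param saturating_fe Plateau fractional enrichment in 0..1.
#' @param rate First-order labelling rate (per hour), non-negative.
#' @param n_replicates Replicates per time point (default 3).
#' @param seed Seed for the noise draws.
#' @return Tibble: time, replicate, fe.
#' @export
simulate_timecourse <- function(model, times, saturating_fe, rate,
                                n_replicates = 3L, seed = model$seed) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("times must be >= 2 ascending points", call. = FALSE)
  }
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  if (saturating_fe < 0 || saturating_fe > 1) {
    stop("saturating_fe must lie in [0, 1]", call. = FALSE)
  }
  mu <- saturating_fe * (1 - exp(-rate * times))
  set.seed(seed)
  sdlog <- sqrt(log(1 + model$noise_cv^2))
  out <- expand.grid(replicate = seq_len(n_replicates), time = times)
  out$fe <- rep(mu, each = n_replicates)
  if (model$noise_cv > 0) {
    out$fe <- out$fe * rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  tibble::as_tibble(out[, c("time", "replicate", "fe")])
}
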