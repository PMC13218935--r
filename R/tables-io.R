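#' Reserved tracer id for tracer-free control samples
#' @keywords internal
UNLABELLED <- "unlabelled"

read_delim_auto <- function(path, col_types = NULL) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    col_types = col_types, progress = FALSE)
}

#' Read a metabolite catalog
#'
#' The catalog lists every metabolite the pipeline may quantify, with its
#' molecular formula, pathway class and whether it is the pathway's
#' representative intermediate for Sankey visualization. Every formula must
#' parse and every pathway class must have at least one representative.
#'
#' @param path CSV/TSV with columns `metabolite`, `formula`, `pathway`,
#'   `representative`. Defaults to the packaged catalog of nitrogenous
#'   metabolites.
#' @return Tibble catalog; formulas are validated at read time.
#' @export
read_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metabolite_catalog.csv", package = "azotrace")
  }
  cat_tab <- read_delim_auto(path)
  required <- c("metabolite", "formula", "pathway", "representative")
  missing <- setdiff(required, names(cat_tab))
  if (length(missing) > 0L) {
    stop(sprintf("catalog is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(cat_tab$metabolite)) {
    dups <- unique(cat_tab$metabolite[duplicated(cat_tab$metabolite)])
    stop(sprintf("duplicate catalog metabolite(s): %s", paste(dups, collapse = ", ")),
         call. = FALSE)
  }
  cat_tab$representative <- as.logical(cat_tab$representative)
  for (i in seq_len(nrow(cat_tab))) {
    tryCatch(parse_formula(cat_tab$formula[i]),
             error = function(e) stop(sprintf("catalog row %d (%s): %s", i,
                                              cat_tab$metabolite[i], conditionMessage(e)),
                                      call. = FALSE))
  }
  reps <- tapply(cat_tab$representative, cat_tab$pathway, any)
  if (!all(reps)) {
    stop(sprintf("pathway class(es) without a representative: %s",
                 paste(names(reps)[!reps], collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(cat_tab)
}

#' Read a tracer registry
#'
#' One row per tracer medium stock: the traced nutrient, the number of
#' labelled tracer atoms per molecule (e.g. 1 for amide-position glutamine,
#' 2 for uniformly labelled uridine), the tracer element, and whether the
#' nutrient is a proteinogenic amino acid. Cross-checked against the
#' catalog: the nutrient must exist and the labelled-atom count may not
#' exceed the nutrient formula's tracer-element count.
#'
#' @param path CSV/TSV with columns `tracer`, `nutrient`, `labelled_atoms`,
#'   `element`, `proteinogenic`. Defaults to the packaged 30-stock registry.
#' @param catalog Catalog from [read_catalog()] used for cross-validation.
#' @return Tibble registry.
#' @export
read_tracer_registry <- function(path = NULL, catalog = read_catalog()) {
  if (is.null(path)) {
    path <- system.file("extdata", "tracer_registry.csv", package = "azotrace")
  }
  reg <- read_delim_auto(path)
  required <- c("tracer", "nutrient", "labelled_atoms", "element")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0L) {
    stop(sprintf("registry is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!"proteinogenic" %in% names(reg)) reg$proteinogenic <- FALSE
  reg$proteinogenic <- as.logical(reg$proteinogenic)
  if (UNLABELLED %in% reg$tracer) {
    stop(sprintf("'%s' is reserved for tracer-free controls", UNLABELLED), call. = FALSE)
  }
  if (anyDuplicated(reg$tracer)) {
    stop("duplicate tracer ids in registry", call. = FALSE)
  }
  for (i in seq_len(nrow(reg))) {
    row <- reg[i, ]
    idx <- match(row$nutrient, catalog$metabolite)
    if (is.na(idx)) {
      stop(sprintf("registry row %d: nutrient '%s' not in catalog", i, row$nutrient),
           call. = FALSE)
    }
    f <- parse_formula(catalog$formula[idx])
    n_el <- if (row$element %in% names(f)) f[[row$element]] else 0L
    if (row$labelled_atoms < 1L || row$labelled_atoms > n_el) {
      stop(sprintf(
        "registry row %d (%s): %d labelled %s atoms but nutrient formula %s has %d",
        i, row$tracer, row$labelled_atoms, row$element, catalog$formula[idx], n_el),
        call. = FALSE)
    }
  }
  tibble::as_tibble(reg)
}

#' Read a long-format peak table
#'
#' Reads validated peak records: one row per (sample, metabolite,
#' isotopologue index). The `tracer` column names the tracer medium stock
#' the sample was cultured in, or `"unlabelled"` for tracer-free controls.
#'
#' @param path CSV/TSV with columns `sample`, `condition`, `tracer`,
#'   `metabolite`, `k`, `intensity`.
#' @param catalog Catalog used to validate metabolite ids and isotopologue
#'   indices (`k` at most the tracer-element atom count).
#' @param registry Registry used to validate tracer ids.
#' @param tracer_element Element bounding `k` via the metabolite formula.
#' @return Tibble of peak records.
#' @export
read_peak_table <- function(path, catalog = read_catalog(),
                            registry = read_tracer_registry(catalog = catalog),
                            tracer_element = "N") {
  rec <- read_delim_auto(path)
  validate_peak_records(rec, catalog, registry, tracer_element)
}

#' Validate peak records against catalog and registry
#'
#' @param records Data frame of peak records (see [read_peak_table()]).
#' @inheritParams read_peak_table
#' @return The validated records as a tibble.
#' @export
validate_peak_records <- function(records, catalog, registry,
                                  tracer_element = "N") {
  required <- c("sample", "condition", "tracer", "metabolite", "k", "intensity")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop(sprintf("peak table is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  if (any(is.na(records$intensity)) || any(records$intensity < 0)) {
    bad <- which(is.na(records$intensity) | records$intensity < 0)
    stop(sprintf("negative or missing intensity at row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  key <- paste(records$sample, records$metabolite, records$k, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), c("sample", "metabolite", "k")][1L, ]
    stop(sprintf("duplicate (sample, metabolite, k) key: (%s, %s, %d)",
                 d$sample, d$metabolite, d$k), call. = FALSE)
  }
  unknown_met <- setdiff(unique(records$metabolite), catalog$metabolite)
  if (length(unknown_met) > 0L) {
    stop(sprintf("unknown metabolite id(s): %s", paste(unknown_met, collapse = ", ")),
         call. = FALSE)
  }
  unknown_tr <- setdiff(unique(records$tracer), c(registry$tracer, UNLABELLED))
  if (length(unknown_tr) > 0L) {
    stop(sprintf("unknown tracer id(s): %s", paste(unknown_tr, collapse = ", ")),
         call. = FALSE)
  }
  n_atoms <- metabolite_atom_counts(catalog, tracer_element)
  kmax <- n_atoms[records$metabolite]
  if (any(records$k < 0) || any(records$k > kmax)) {
    bad <- which(records$k < 0 | records$k > kmax)[1L]
    stop(sprintf("isotopologue index k = %d out of range 0..%d for %s",
                 records$k[bad], kmax[bad], records$metabolite[bad]), call. = FALSE)
  }
  records
}

# named vector: tracer-element atom count per catalog metabolite
metabolite_atom_counts <- function(catalog, tracer_element = "N") {
  vapply(seq_len(nrow(catalog)), function(i) {
    f <- parse_formula(catalog$formula[i])
    if (tracer_element %in% names(f)) f[[tracer_element]] else 0L
  }, integer(1L)) |> setNames(catalog$metabolite)
}

#' Read a run configuration file
#'
#' JSON or YAML (by extension). Recognised fields mirror the arguments of
#' [run_profiling()] and [filter_config()]; unspecified fields take package
#' defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file, or `NULL` for
#'   defaults.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    correction_mode = "resolved",
    min_samples_quantified = 2,
    pool_size_threshold = 1e5,
    min_summed_labelling = 1,
    max_unlabelled_labelling = 3,
    max_summed_labelling = 500,
    summed_mode = "sum",
    sankey_threshold = 5,
    condition1 = NULL,
    condition2 = NULL,
    seed = 1L,
    output_dir = "."
  )
  if (is.null(path)) return(defaults)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, cfg)
  num_fields <- c("pool_size_threshold", "min_summed_labelling",
                  "max_unlabelled_labelling", "max_summed_labelling",
                  "sankey_threshold", "min_samples_quantified")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("config field '%s' must be a non-negative number", f), call. = FALSE)
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write pipeline outputs to a directory
#'
#' Writes the deterministic file set produced by [run_profiling()]:
#' `enrichment_table.csv`, `filter_report.csv`, `score_table.csv`,
#' `sankey_edges.csv`, `sankey.json` and `run_log.txt`. Identical inputs
#' and seed yield byte-identical files.
#'
#' @param results List as returned by [run_profiling()] (fields may be
#'   `NULL`, in which case headers-only files are written).
#' @param directory Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(results, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop(sprintf("cannot create output directory '%s'", directory), call. = FALSE)
    }
  }
  paths <- c(enrichment = file.path(directory, "enrichment_table.csv"),
             filter = file.path(directory, "filter_report.csv"),
             scores = file.path(directory, "score_table.csv"),
             sankey_csv = file.path(directory, "sankey_edges.csv"),
             sankey_json = file.path(directory, "sankey.json"),
             log = file.path(directory, "run_log.txt"))

  enr_tab <- if (!is.null(results$enrichment)) {
    enrichment_csv(results$enrichment)
  } else {
    tibble::tibble(condition = character(), tracer = character(),
                   metabolite = character(), k = integer(),
                   FE_mean = double(), FE_sem = double(),
                   total_labelling = double(), n = integer())
  }
  readr::write_csv(enr_tab, paths[["enrichment"]])

  flt <- if (!is.null(results$filter_report)) {
    filter_report_csv(results$filter_report)
  } else {
    tibble::tibble(metabolite = character(), status = character(),
                   reasons = character(), n_quantified = integer(),
                   mean_pool = double(), summed_labelling_pct = double(),
                   max_control_pct = double())
  }
  readr::write_csv(flt, paths[["filter"]])

  sc <- results$scores %||% tibble::tibble(tracer = character(),
                                           metabolite = character(),
                                           fe1 = double(), fe2 = double(),
                                           score = double(), rank = integer())
  readr::write_csv(sc, paths[["scores"]])

  edges <- if (!is.null(results$sankey)) {
    dplyr::bind_rows(lapply(results$sankey, sankey_edges_csv))
  } else {
    tibble::tibble(condition = character(), tracer = character(),
                   metabolite = character(), pathway = character(),
                   weight = double())
  }
  readr::write_csv(edges, paths[["sankey_csv"]])

  sankey_doc <- if (!is.null(results$sankey)) {
    lapply(results$sankey, sankey_json_document)
  } else {
    list()
  }
  jsonlite::write_json(sankey_doc, paths[["sankey_json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  log_lines <- c(
    sprintf("INFO run seed=%s", results$seed %||% "NA"),
    sprintf("INFO enrichment rows=%d", nrow(enr_tab)),
    sprintf("INFO filter kept=%d removed=%d",
            sum(flt$status == "kept"), sum(flt$status == "removed")),
    sprintf("INFO scores n=%d", nrow(sc)),
    sprintf("INFO sankey edges=%d", nrow(edges)))
  writeLines(log_lines, paths[["log"]])
  invisible(paths)
}
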