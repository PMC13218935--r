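# package-level memoization of the packaged abundance table and of
# correction matrices built from it (keyed by formula string + mode);
# matrices from user-supplied abundance tables are never cached
.azocache <- new.env(parent = emptyenv())

default_abundances <- function() {
  if (is.null(.azocache$abund)) {
    .azocache$abund <- isotope_abundances()
  }
  .azocache$abund
}

cached_correction_matrix <- function(formula_string, mode = "resolved") {
  key <- paste(formula_string, mode, sep = "|")
  hit <- .azocache$cmats[[key]]
  if (!is.null(hit)) return(hit)
  cm <- correction_matrix(parse_formula(formula_string),
                          table = default_abundances(), mode = mode)
  if (is.null(.azocache$cmats)) .azocache$cmats <- list()
  .azocache$cmats[[key]] <- cm
  cm
}
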