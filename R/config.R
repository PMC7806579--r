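# Run configuration: one YAML file wiring the filter, annotation and io
# sections together for batch runs and the command-line tool.

#' Read a run configuration file
#'
#' YAML with up to four top-level sections: `filter`, `annotation`, `io`
#' and `seed`. Unknown keys anywhere are rejected with an error naming
#' them. The annotation section accepts `base_deltas`, `multimers`,
#' `max_depth`, `tolerance_mmu` and `polarity` (only `"positive"` sets are
#' shipped; requesting `"negative"` is an error).
#'
#' @param path Path to the YAML file. The packaged default lives at
#'   `system.file("extdata", "default_annotation.yaml", package = "adductgraph")`.
#' @return List with `config` (an [annotation_config()]), `io` (list with
#'   `graph_format`) and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("filter", "annotation", "io", "seed")
  check_keys(raw, known_top, "top level")
  fl <- raw$filter
  check_keys(fl, c("abs_intensity_min", "rel_intensity_min", "mz_range",
                   "isotope_ratio_range", "isotope_tolerance",
                   "monoisotopic_validation"), "filter section")
  filt <- do.call(filter_config, fl %||% list())
  an <- raw$annotation
  check_keys(an, c("base_deltas", "multimers", "max_depth", "max_losses",
                   "tolerance_mmu", "polarity"), "annotation section")
  an <- an %||% list()
  if (!is.null(an$polarity) && !identical(an$polarity, "positive"))
    stop("no negative-mode annotation set is shipped; the tool is currently focused on singly charged positive ions")
  tol <- if (is.null(an$tolerance_mmu)) 0.010 else an$tolerance_mmu / 1000
  cfg <- annotation_config(
    base_deltas = an$base_deltas %||% c("NH3_adduct", "Na_adduct", "K_adduct",
                                        "H2O_loss", "NH3_loss"),
    multimers = an$multimers %||% 1:3,
    max_depth = an$max_depth %||% 3L,
    max_losses = an$max_losses %||% 1L,
    tolerance = tol, filter = filt)
  io <- raw$io %||% list()
  check_keys(io, c("graph_format"), "io section")
  if (!is.null(io$graph_format))
    io$graph_format <- match.arg(io$graph_format, c("graphml", "dot"))
  list(config = cfg, io = io, seed = raw$seed %||% 1L)
}

check_keys <- function(x, known, where) {
  if (is.null(x)) return(invisible())
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop(sprintf("unknown key(s) in %s: %s (known: %s)", where,
                 paste(unknown, collapse = ", "), paste(known, collapse = ", ")))
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
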