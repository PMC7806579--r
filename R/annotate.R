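# Top-level annotation pipeline: filter -> graph -> clusters -> ranked
# [M+H]+ candidates with CGC/CIC/CCC indexes and diagnostics.

#' Annotation configuration
#'
#' Bundles the filter settings and the annotation set. The default set is
#' the tool's standard one: three adducts (ammonium, sodium, potassium),
#' two neutral losses (ammonia, water), dimers and trimers, combined to
#' depth 3, with an absolute tolerance of 10 mmu.
#'
#' @param base_deltas Base delta names, see [base_delta_names()].
#' @param multimers Multimer orders covered (default `1:3`).
#' @param max_depth Maximum number of combined base deltas (default 3).
#' @param max_losses Neutral-loss budget per combined species, see
#'   [expand_species_closure()] (default 1).
#' @param tolerance Absolute matching tolerance in Da (default 0.010).
#' @param filter A [filter_config()].
#' @return An `annotation_config` with the species closure precomputed.
#' @export
annotation_config <- function(base_deltas = c("NH3_adduct", "Na_adduct", "K_adduct",
                                              "H2O_loss", "NH3_loss"),
                              multimers = 1:3, max_depth = 3L, max_losses = 1L,
                              tolerance = 0.010, filter = filter_config()) {
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be a positive number of Da")
  closure <- expand_species_closure(base_deltas, max_depth, multimers, max_losses)
  structure(list(base_deltas = base_deltas, multimers = sort(unique(as.integer(multimers))),
                 max_depth = as.integer(max_depth), max_losses = as.integer(max_losses),
                 tolerance = tolerance, filter = filter, closure = closure),
            class = "annotation_config")
}

#' Annotate one spectrum
#'
#' Runs the full pipeline on a centroid spectrum: m/z and intensity
#' thresholds, deisotoping, annotation-graph construction over the species
#' closure, weak-component clustering, [M+H]+ candidate ranking by
#' explained TIC (connectivity tie-break), CGC/CIC/CCC indexes, and a
#' proton-bound heterodimer scan over the candidate list.
#'
#' @param s An `ms_spectrum` (positive polarity).
#' @param config An [annotation_config()].
#' @return A `spectrum_annotation` object; see [candidate_table()],
#'   [annotation_table()], and its `print()`, `summary()` and `plot()`
#'   methods.
#' @examples
#' ann <- annotate_spectrum(fixture_lc_mix())
#' ann
#' candidate_table(ann)
#' @export
annotate_spectrum <- function(s, config = annotation_config()) {
  stopifnot(inherits(s, "ms_spectrum"), inherits(config, "annotation_config"))
  if (!identical(attr(s, "polarity"), "positive"))
    stop("negative-mode annotation sets are not shipped; the tool is currently focused on singly charged positive ions")
  thresholded <- threshold_filter(s, config$filter)
  filtered <- deisotope(thresholded, config$filter)
  g <- build_graph(filtered, config$closure, config$tolerance)
  cl <- clusters(g)
  kept <- retained_peaks(filtered)

  # monoisotopic validation vetoes candidates that could be isotope peaks
  # (checked against the pre-deisotoping view)
  invalid <- integer(0)
  if (isTRUE(config$filter$monoisotopic_validation) && nrow(kept)) {
    ok <- vapply(kept$mz, function(m)
      validate_monoisotopic(thresholded, m, config$filter), logical(1))
    invalid <- which(!ok)
  }

  cand_rows <- list(); idx_rows <- list(); singleton_rows <- list()
  annotated_nodes <- integer(0)
  for (cc in cl) {
    idx <- cluster_indexes(cc, g, filtered)
    idx_rows[[length(idx_rows) + 1L]] <- data.frame(
      cluster_id = cc$cluster_id, cgc = idx$cgc, cic = idx$cic, ccc = idx$ccc)
    if (cc$is_singleton) {
      v <- cc$members
      singleton_rows[[length(singleton_rows) + 1L]] <- data.frame(
        cluster_id = cc$cluster_id, mz = g$nodes$mz[v],
        intensity = g$nodes$intensity[v],
        monoisotopic_ok = !(v %in% invalid))
      next
    }
    annotated_nodes <- c(annotated_nodes, cc$members)
    rk <- rank_candidates(g, cc, exclude = invalid)
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      cluster_id = cc$cluster_id, candidate_mz = rk$mz,
      explained_tic = rk$explained_tic, connectivity = rk$connectivity,
      cgc = idx$cgc, cic = idx$cic, ccc = idx$ccc,
      n_alternates = length(rk$alternates),
      alternate_mz = paste(sprintf("%.4f", g$nodes$mz[rk$alternates]),
                           collapse = ";"),
      stringsAsFactors = FALSE)
  }
  empty_cand <- data.frame(cluster_id = integer(0), candidate_mz = numeric(0),
                           explained_tic = numeric(0), connectivity = integer(0),
                           cgc = integer(0), cic = numeric(0), ccc = numeric(0),
                           n_alternates = integer(0), alternate_mz = character(0))
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else empty_cand
  singletons <- if (length(singleton_rows)) do.call(rbind, singleton_rows)
    else data.frame(cluster_id = integer(0), mz = numeric(0),
                    intensity = numeric(0), monoisotopic_ok = logical(0))
  indexes <- if (length(idx_rows)) do.call(rbind, idx_rows)
    else data.frame(cluster_id = integer(0), cgc = integer(0),
                    cic = numeric(0), ccc = numeric(0))
  hetero <- heterodimer_scan(filtered, candidates$candidate_mz,
                             tol = config$tolerance,
                             annotated_nodes = annotated_nodes, g = g)
  structure(list(spectrum = filtered, graph = g, clusters = cl,
                 candidates = candidates, singletons = singletons,
                 indexes = indexes, heterodimers = hetero, config = config),
            class = "spectrum_annotation")
}

#' Annotate a batch of spectra
#'
#' @param batch List of `ms_spectrum` objects (e.g. from [read_mgf()]).
#' @param config An [annotation_config()].
#' @return An `annotation_batch`: list of `spectrum_annotation` objects in
#'   input order.
#' @export
annotate_batch <- function(batch, config = annotation_config()) {
  if (inherits(batch, "ms_spectrum")) batch <- list(batch)
  if (!length(batch)) stop("empty spectrum batch")
  structure(lapply(batch, annotate_spectrum, config = config),
            class = "annotation_batch")
}

# member annotation string for report tables: minimal-|error| incoming edge
member_annotation <- function(g, v) {
  rows <- which(g$edges$child == v | (!g$edges$directed & g$edges$parent == v))
  if (!length(rows)) return("[M+H]+")
  r <- rows[which.min(abs(g$edges$mass_error[rows]))]
  sprintf("%s@%+.1fmmu", g$edges$label[r], g$edges$mass_error[r] * 1000)
}

#' Candidate and annotation output tables
#'
#' `candidate_table()` has one row per ranked [M+H]+ candidate (singletons
#' are reported separately by `singleton_table()`): spectrum title,
#' candidate m/z, explained TIC, connectivity, CGC, CIC, CCC and the
#' cluster members with their species labels and signed mass errors in
#' mmu. `annotation_table()` has one row per graph edge.
#'
#' @param x A `spectrum_annotation` or `annotation_batch`.
#' @return A data frame.
#' @export
candidate_table <- function(x) {
  if (inherits(x, "spectrum_annotation")) x <- list(x)
  rows <- lapply(x, function(a) {
    if (!nrow(a$candidates)) return(NULL)
    members <- vapply(seq_len(nrow(a$candidates)), function(i) {
      cc <- a$clusters[[a$candidates$cluster_id[i]]]
      paste(sprintf("%.4f(%s)", a$graph$nodes$mz[cc$members],
                    vapply(cc$members, function(v) member_annotation(a$graph, v), "")),
            collapse = ";")
    }, character(1))
    cbind(data.frame(title = spectrum_title(a$spectrum),
                     stringsAsFactors = FALSE),
          a$candidates, data.frame(members = members, stringsAsFactors = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(title = character(0), cluster_id = integer(0),
                      candidate_mz = numeric(0), explained_tic = numeric(0),
                      connectivity = integer(0), cgc = integer(0),
                      cic = numeric(0), ccc = numeric(0),
                      n_alternates = integer(0), alternate_mz = character(0),
                      members = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname candidate_table
#' @export
annotation_table <- function(x) {
  if (inherits(x, "spectrum_annotation")) x <- list(x)
  rows <- lapply(x, function(a) {
    e <- a$graph$edges
    if (!nrow(e)) return(NULL)
    data.frame(title = spectrum_title(a$spectrum),
               parent_mz = a$graph$nodes$mz[e$parent],
               child_mz = a$graph$nodes$mz[e$child],
               label = e$label,
               mass_error_mmu = e$mass_error * 1000,
               directed = e$directed,
               alt_labels = e$alt_labels,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(title = character(0), parent_mz = numeric(0),
                      child_mz = numeric(0), label = character(0),
                      mass_error_mmu = numeric(0), directed = logical(0),
                      alt_labels = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname candidate_table
#' @export
singleton_table <- function(x) {
  if (inherits(x, "spectrum_annotation")) x <- list(x)
  rows <- lapply(x, function(a) {
    if (!nrow(a$singletons)) return(NULL)
    cbind(data.frame(title = spectrum_title(a$spectrum), stringsAsFactors = FALSE),
          a$singletons)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(title = character(0), cluster_id = integer(0),
                      mz = numeric(0), intensity = numeric(0),
                      monoisotopic_ok = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.spectrum_annotation <- function(x, ...) {
  n_peaks <- nrow(x$spectrum)
  n_kept <- nrow(retained_peaks(x$spectrum))
  n_cl <- length(x$clusters)
  n_single <- sum(vapply(x$clusters, `[[`, logical(1), "is_singleton"))
  cat(sprintf("<annotation> '%s'\n", spectrum_title(x$spectrum)))
  cat(sprintf("  peaks: %d read, %d retained after filtering/deisotoping\n",
              n_peaks, n_kept))
  cat(sprintf("  clusters: %d (%d singletons); [M+H]+ putatives: %d -> %d\n",
              n_cl, n_single, n_kept, nrow(x$candidates) + n_single))
  if (nrow(x$candidates)) {
    cat("  ranked candidates:\n")
    for (i in seq_len(nrow(x$candidates)))
      cat(sprintf("    m/z %.4f  TICex %.4g  CGC %d  CIC %.0f%%  CCC %.0f%%\n",
                  x$candidates$candidate_mz[i], x$candidates$explained_tic[i],
                  x$candidates$cgc[i], x$candidates$cic[i], x$candidates$ccc[i]))
  }
  if (nrow(x$heterodimers))
    cat(sprintf("  putative heterodimers flagged: %d\n", nrow(x$heterodimers)))
  invisible(x)
}

#' @export
summary.spectrum_annotation <- function(object, ...) {
  candidate_table(object)
}

#' @export
print.annotation_batch <- function(x, ...) {
  cat(sprintf("<annotation batch> %d spectra, %d ranked candidates, %d singletons\n",
              length(x), nrow(candidate_table(x)), nrow(singleton_table(x))))
  invisible(x)
}

#' Plot an annotation graph
#'
#' Draws the cluster graph with node size scaled by log intensity and the
#' ranked [M+H]+ candidates highlighted.
#'
#' @param x A `spectrum_annotation`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.spectrum_annotation <- function(x, ...) {
  g <- x$graph
  ig <- g$igraph
  igraph::V(ig)$label <- sprintf("%.0f", g$nodes$mz)
  cand <- match(x$candidates$candidate_mz, g$nodes$mz)
  cols <- rep("grey80", nrow(g$nodes))
  cols[cand] <- "gold"
  igraph::plot.igraph(ig, vertex.color = cols,
                      vertex.size = 6 + 2 * log10(1 + g$nodes$intensity),
                      edge.arrow.size = 0.3, ...)
  invisible(x)
}
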