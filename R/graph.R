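# Weighted directed annotation graph over the retained peaks of one
# spectrum. Every peak is treated as a putative [M+H]+; edges point from
# that protonated frame to the peaks matching one of its closure species
# (adducts: protonated -> adducted; losses: precursor -> product; multimers:
# monomer -> multimer). A pure +/-NH3 step between two monomer peaks is
# directionally ambiguous (adduct or loss) and becomes a single
# bidirectional edge.

#' Match an observed mass difference against an annotation closure
#'
#' @param observed Observed signed mass difference in Da between two peaks
#'   of the same multimer frame.
#' @param closure Species list from [expand_species_closure()].
#' @param tol Absolute tolerance in Da (default 0.010 = 10 mmu).
#' @return Data frame of matches sorted by absolute mass error: `label`,
#'   `delta` (theoretical), `mass_error` (observed - theoretical, Da) and
#'   `directed` (`FALSE` for the +/-NH3 ambiguity, which reports both
#'   readings). Zero rows when nothing matches.
#' @examples
#' cl <- expand_species_closure()
#' match_delta(21.9822, cl) # [M+Na]+, error +0.0003
#' @export
match_delta <- function(observed, closure, tol = 0.010) {
  if (tol <= 0) stop("tolerance must be positive")
  mono <- Filter(function(s) s$multimer_n == 1L, closure)
  out <- list()
  for (s in mono) {
    if (all(s$deltas == 0L)) next  # identity [M+H]+
    d <- s$offset - .PROTON_MASS
    err <- observed - d
    if (abs(err) <= tol) {
      amb <- species_is_ambiguous(s)
      out[[length(out) + 1L]] <- data.frame(
        label = s$label, delta = d, mass_error = err,
        directed = !amb, stringsAsFactors = FALSE)
      if (amb) {
        # the complementary reading of the same shift, seen from the other peak
        other <- if (s$deltas[["NH3_adduct"]] == 1L)
          ion_species(1L, c(NH3_loss = 1L)) else ion_species(1L, c(NH3_adduct = 1L))
        out[[length(out) + 1L]] <- data.frame(
          label = other$label, delta = d, mass_error = err,
          directed = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(label = character(0), delta = numeric(0),
                      mass_error = numeric(0), directed = logical(0)))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res$label), , drop = FALSE]
  res[order(abs(res$mass_error)), , drop = FALSE]
}

#' Build the annotation graph of a filtered spectrum
#'
#' Every retained peak P is treated as a putative protonated molecule of
#' neutral mass `M = mz(P) - 1.007276`. Any other retained peak within
#' `tol` of `ion_mz(M, s)` for a closure species `s` receives a directed
#' edge P -> peak carrying the species label and the signed mass error
#' (observed - theoretical). When several species match one peak pair the
#' smallest-|error| relation labels the edge and the others are kept as
#' alternates. Pure +/-NH3 monomer relations are merged into one
#' bidirectional edge.
#'
#' @param s A filtered, deisotoped `ms_spectrum`.
#' @param closure Species list from [expand_species_closure()]; must cover
#'   the wanted multimer orders.
#' @param tol Absolute tolerance in Da (default 0.010).
#' @return An `annotation_graph`: list with `nodes` (data.frame `mz`,
#'   `intensity`), `edges` (data.frame `parent`, `child` as node indices,
#'   `label`, `mass_error`, `directed`, `alt_labels`), `tol`, `title` and
#'   the underlying `igraph` object (bidirectional edges stored as
#'   reciprocal arcs).
#' @export
build_graph <- function(s, closure, tol = 0.010) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (tol <= 0) stop("tolerance must be positive")
  kept <- retained_peaks(s)
  nodes <- data.frame(mz = kept$mz, intensity = kept$intensity)
  n <- nrow(nodes)
  edges <- data.frame(parent = integer(0), child = integer(0),
                      label = character(0), mass_error = numeric(0),
                      directed = logical(0), alt_labels = character(0),
                      stringsAsFactors = FALSE)
  if (n >= 2L) {
    mz <- nodes$mz
    sp_n <- vapply(closure, function(x) x$multimer_n, integer(1))
    sp_off <- vapply(closure, function(x) x$offset, numeric(1))
    sp_lab <- vapply(closure, function(x) x$label, character(1))
    sp_amb <- vapply(closure, species_is_ambiguous, logical(1))
    identity_sp <- sp_n == 1L &
      vapply(closure, function(x) all(x$deltas == 0L), logical(1))
    raw <- list()
    for (p in seq_len(n)) {
      M <- mz[p] - .PROTON_MASS
      if (M <= 0) next
      targets <- sp_n * M + sp_off
      lo <- findInterval(targets - tol, mz)
      hi <- findInterval(targets + tol, mz)
      hit <- which(hi > lo & !identity_sp)
      for (k in hit) {
        for (q in (lo[k] + 1L):hi[k]) {
          if (q == p) next
          raw[[length(raw) + 1L]] <- list(
            parent = p, child = q, label = sp_lab[k],
            mass_error = mz[q] - targets[k], directed = !sp_amb[k])
        }
      }
    }
    if (length(raw)) {
      raw_df <- data.frame(
        parent = vapply(raw, `[[`, integer(1), "parent"),
        child = vapply(raw, `[[`, integer(1), "child"),
        label = vapply(raw, `[[`, character(1), "label"),
        mass_error = vapply(raw, `[[`, numeric(1), "mass_error"),
        directed = vapply(raw, `[[`, logical(1), "directed"),
        stringsAsFactors = FALSE)
      edges <- collapse_edges(raw_df)
    }
  }
  ig <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (n) igraph::V(ig)$mz <- nodes$mz
  if (n) igraph::V(ig)$intensity <- nodes$intensity
  if (nrow(edges)) {
    arcs <- rbind(cbind(edges$parent, edges$child),
                  cbind(edges$child, edges$parent)[!edges$directed, , drop = FALSE])
    ig <- igraph::add_edges(ig, t(arcs))
  }
  structure(list(nodes = nodes, edges = edges, tol = tol,
                 title = attr(s, "title"), igraph = ig),
            class = "annotation_graph")
}

# one edge per ordered peak pair (min-|error| relation primary, rest as
# alternates), then merge reciprocal undirected pairs
collapse_edges <- function(raw) {
  key <- paste(raw$parent, raw$child)
  out <- lapply(split(seq_len(nrow(raw)), key), function(ii) {
    sub <- raw[ii[order(abs(raw$mass_error[ii]))], , drop = FALSE]
    best <- sub[1, , drop = FALSE]
    best$directed <- all(sub$directed)  # any ambiguous reading makes the pair ambiguous
    best$alt_labels <- paste(sub$label[-1], collapse = ";")
    best
  })
  edges <- do.call(rbind, out)
  rownames(edges) <- NULL
  # merge reciprocal undirected duplicates, keeping the lower-mz parent
  drop <- logical(nrow(edges))
  ekey <- paste(edges$parent, edges$child)
  for (i in seq_len(nrow(edges))) {
    if (drop[i] || edges$directed[i]) next
    j <- match(paste(edges$child[i], edges$parent[i]), ekey)
    if (!is.na(j) && !edges$directed[j] && !drop[j]) {
      keep <- if (edges$parent[i] < edges$parent[j]) i else j
      lose <- if (keep == i) j else i
      extra <- setdiff(c(edges$label[lose],
                         strsplit(edges$alt_labels[lose], ";")[[1]]),
                       c(edges$label[keep],
                         strsplit(edges$alt_labels[keep], ";")[[1]]))
      extra <- extra[nzchar(extra)]
      if (length(extra))
        edges$alt_labels[keep] <- paste(c(strsplit(edges$alt_labels[keep], ";")[[1]],
                                          extra), collapse = ";")
      drop[lose] <- TRUE
    }
  }
  edges <- edges[!drop, , drop = FALSE]
  edges[order(edges$parent, edges$child), , drop = FALSE]
}

#' @export
print.annotation_graph <- function(x, ...) {
  cat(sprintf("<annotation graph> '%s': %d peaks, %d edges (tolerance %.1f mmu)\n",
              x$title, nrow(x$nodes), nrow(x$edges), x$tol * 1000))
  invisible(x)
}

#' Export an annotation graph
#'
#' Writes the graph as GraphML or DOT with node attributes `mz` and
#' `intensity` and edge attributes `label`, `mass_error_mmu` and
#' `directed`.
#'
#' @param g An `annotation_graph`.
#' @param path Output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
write_annotation_graph <- function(g, path, format = c("graphml", "dot")) {
  stopifnot(inherits(g, "annotation_graph"))
  format <- match.arg(format)
  ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = TRUE)
  if (nrow(g$nodes)) {
    igraph::V(ig)$mz <- g$nodes$mz
    igraph::V(ig)$intensity <- g$nodes$intensity
    igraph::V(ig)$label <- sprintf("%.4f", g$nodes$mz)
  }
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, t(cbind(g$edges$parent, g$edges$child)))
    igraph::E(ig)$label <- g$edges$label
    igraph::E(ig)$mass_error_mmu <- round(g$edges$mass_error * 1000, 2)
    igraph::E(ig)$directed <- as.integer(g$edges$directed)  # DOT has no boolean
  }
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}
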