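# Cluster extraction, [M+H]+ candidate ranking and the CGC/CIC/CCC
# confidence indexes.
#
# Explained TIC of a peak is the summed intensity of every peak reachable
# from it along edge direction (bidirectional edges traversable both ways),
# itself included. Connectivity counts the peaks a candidate explains by a
# direct annotation (out-neighbors, excluding itself): for the three-ion
# example cluster {116 -> 154, 116 -> 231} the 116 peak has connectivity 2.
# Multi-hop reachability can tie two candidates exactly (a bidirectional
# pair shares its whole reachable set); direct connectivity is what breaks
# such ties.

#' Weakly connected clusters of an annotation graph
#'
#' @param g An `annotation_graph` from [build_graph()].
#' @return List of clusters, each a list with `cluster_id`, `members`
#'   (node indices, ascending m/z), `is_singleton`. Ids are assigned by
#'   ascending minimum member m/z, so repeated runs are identical.
#' @export
clusters <- function(g) {
  stopifnot(inherits(g, "annotation_graph"))
  n <- nrow(g$nodes)
  if (n == 0L) return(list())
  comp <- igraph::components(g$igraph, mode = "weak")
  groups <- split(seq_len(n), comp$membership)
  min_mz <- vapply(groups, function(ii) min(g$nodes$mz[ii]), numeric(1))
  groups <- groups[order(min_mz)]
  lapply(seq_along(groups), function(i) {
    ii <- sort(groups[[i]])
    list(cluster_id = i, members = ii, is_singleton = length(ii) == 1L)
  })
}

#' Explained TIC and connectivity of one peak
#'
#' @param g An `annotation_graph`.
#' @param node Node index (row of `g$nodes`).
#' @return List with `explained` (node indices reachable along edge
#'   direction, including the node), `explained_tic` (their intensity sum)
#'   and `connectivity` (number of directly annotated peaks, excluding the
#'   node itself).
#' @export
explain <- function(g, node) {
  stopifnot(inherits(g, "annotation_graph"))
  reach <- as.integer(igraph::subcomponent(g$igraph, node, mode = "out"))
  nb <- setdiff(unique(as.integer(igraph::neighbors(g$igraph, node, mode = "out"))),
                node)
  list(explained = sort(reach),
       explained_tic = sum(g$nodes$intensity[reach]),
       connectivity = length(nb))
}

#' Rank the [M+H]+ candidate of a cluster
#'
#' The candidate is the member with the largest explained TIC; ties are
#' broken by connectivity, then by lowest m/z, then by the smallest summed
#' |mass error| over outgoing edges. The m/z tie-break encodes a chemical
#' prior: when a +17.027 ambiguity leaves two frames explaining the same
#' peaks equally well, the lower-m/z frame reads the upper peak as an
#' ammonium adduct, which is far more common in positive ESI than the
#' competing in-source NH3-loss reading. Singleton clusters are not ranked
#' (they are reported separately as unexplained [M+H]+ putatives).
#'
#' @param g An `annotation_graph`.
#' @param cluster One cluster from [clusters()] (non-singleton).
#' @param exclude Node indices vetoed as candidates (e.g. by monoisotopic
#'   validation); they stay cluster members. Ignored if it would veto the
#'   whole cluster.
#' @return List with `candidate` (node index), `mz`, `explained_tic`,
#'   `connectivity`, `alternates` (node indices tied on explained TIC).
#' @export
rank_candidates <- function(g, cluster, exclude = integer(0)) {
  stopifnot(inherits(g, "annotation_graph"))
  if (cluster$is_singleton)
    stop("singleton clusters are not ranked; see the singleton report")
  mem <- cluster$members
  if (length(exclude) && !all(mem %in% exclude))
    mem <- setdiff(mem, exclude)
  ex <- lapply(mem, function(v) explain(g, v))
  tic <- vapply(ex, `[[`, numeric(1), "explained_tic")
  conn <- vapply(ex, `[[`, numeric(1), "connectivity")
  err_sum <- vapply(mem, function(v) {
    rows <- g$edges$parent == v | (!g$edges$directed & g$edges$child == v)
    sum(abs(g$edges$mass_error[rows]))
  }, numeric(1))
  ord <- order(-tic, -conn, g$nodes$mz[mem], err_sum)
  best <- ord[1]
  ties <- which(abs(tic - tic[best]) < 1e-9)
  list(candidate = mem[best], mz = g$nodes$mz[mem[best]],
       explained_tic = tic[best], connectivity = as.integer(conn[best]),
       alternates = mem[setdiff(ties, best)])
}

#' CGC, CIC and CCC indexes of a cluster
#'
#' CGC is the number of ions in the cluster; CIC and CCC are the
#' percentages of the filtered spectrum's total ion current and retained
#' peak count contained in the cluster. Over all clusters of a spectrum
#' (singletons included) CIC and CCC each sum to 100.
#'
#' @param cluster One cluster from [clusters()].
#' @param g The `annotation_graph` the cluster came from.
#' @param s The filtered, deisotoped `ms_spectrum` the graph was built on.
#' @return List with `cgc` (integer), `cic` and `ccc` (percent).
#' @export
cluster_indexes <- function(cluster, g, s) {
  stopifnot(inherits(g, "annotation_graph"), inherits(s, "ms_spectrum"))
  tic <- spectrum_tic(s)
  if (tic <= 0) stop("cluster indexes are undefined for a zero-TIC spectrum")
  kept <- nrow(retained_peaks(s))
  mem <- cluster$members
  list(cgc = length(mem),
       cic = 100 * sum(g$nodes$intensity[mem]) / tic,
       ccc = 100 * length(mem) / kept)
}

#' Scan for putative proton-bound heterodimers
#'
#' For every pair of [M+H]+ candidates (A, B) the proton-bound heterodimer
#' is expected at `MA + MB + 1.007276 = mz(A) + mz(B) - 1.007276`. Retained
#' peaks within `tol` of such a value are flagged. This is a diagnostic:
#' flagged peaks are never merged into clusters, and a peak may be flagged
#' even though the graph already annotated it (the typical signature is a
#' forced assignment with a large mass error).
#'
#' @param s Filtered `ms_spectrum`.
#' @param candidate_mz Numeric vector of candidate [M+H]+ m/z values.
#' @param tol Tolerance in Da (default 0.010).
#' @param annotated_nodes Optional integer vector of node indices that sit
#'   in non-singleton clusters, used to fill the `annotated` column.
#' @param g Optional `annotation_graph` (to map peaks to nodes for
#'   `annotated`).
#' @return Data frame: `mz` (flagged peak), `candidate_a`, `candidate_b`,
#'   `expected_mz`, `mass_error`, `annotated`.
#' @export
heterodimer_scan <- function(s, candidate_mz, tol = 0.010,
                             annotated_nodes = integer(0), g = NULL) {
  stopifnot(inherits(s, "ms_spectrum"))
  kept <- retained_peaks(s)
  out <- list()
  cand <- sort(unique(candidate_mz))
  if (length(cand) >= 2L) {
    pairs <- utils::combn(cand, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      expected <- a + b - .PROTON_MASS
      hits <- which(abs(kept$mz - expected) <= tol)
      for (h in hits) {
        annotated <- if (!is.null(g) && length(annotated_nodes))
          h %in% annotated_nodes else NA
        out[[length(out) + 1L]] <- data.frame(
          mz = kept$mz[h], candidate_a = a, candidate_b = b,
          expected_mz = expected, mass_error = kept$mz[h] - expected,
          annotated = annotated, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(mz = numeric(0), candidate_a = numeric(0),
                      candidate_b = numeric(0), expected_mz = numeric(0),
                      mass_error = numeric(0), annotated = logical(0)))
  res <- do.call(rbind, out)
  res[order(res$mz), , drop = FALSE]
}
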