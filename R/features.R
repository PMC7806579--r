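# Conversion of chromatographic feature tables (peak-picker exports) into
# pseudo-spectrum batches: one spectrum per feature group.

#' Convert a feature table to pseudo-spectra
#'
#' Each distinct `group_id` becomes one pseudo-spectrum titled
#' `"pseudo-spectrum <group_id>"`, with the group's features as peaks and
#' the intensity-weighted mean retention time.
#'
#' @param rows Data frame with columns `mz` (Da), `rt` (minutes),
#'   `intensity` (cps) and `group_id`. CAMERA-style column names (`into`,
#'   `pcgroup`) are accepted as aliases.
#' @return List of [new_spectrum()] objects, ordered by first appearance of
#'   the group id.
#' @examples
#' rows <- data.frame(mz = c(116.07, 138.05, 200.1), rt = c(1.3, 1.31, 5.0),
#'                    intensity = c(1e5, 2e4, 5e3), group_id = c(1, 1, 2))
#' features_to_mgf(rows)
#' @export
features_to_mgf <- function(rows) {
  if (is.null(rows) || !is.data.frame(rows) || nrow(rows) == 0L)
    stop("feature table is empty")
  aliases <- c(into = "intensity", maxo = "intensity", pcgroup = "group_id",
               psg = "group_id")
  for (a in names(aliases))
    if (a %in% names(rows) && !(aliases[[a]] %in% names(rows)))
      names(rows)[names(rows) == a] <- aliases[[a]]
  need <- c("mz", "rt", "intensity", "group_id")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols))
    stop(sprintf("feature table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (any(!nzchar(as.character(rows$group_id))) || anyNA(rows$group_id))
    stop("group_id must be non-empty for every row")
  if (any(rows$mz <= 0)) stop("feature m/z values must be positive")
  ids <- unique(as.character(rows$group_id))
  lapply(ids, function(id) {
    g <- rows[as.character(rows$group_id) == id, , drop = FALSE]
    rt <- sum(g$rt * g$intensity) / sum(g$intensity)
    new_spectrum(g$mz, g$intensity,
                 title = sprintf("pseudo-spectrum %s", id),
                 retention_time = rt)
  })
}

#' Read a feature table CSV
#'
#' Headered CSV with columns `mz`, `rt`, `intensity` (or `into`) and
#' `group_id` (or `pcgroup`).
#'
#' @param path CSV path.
#' @return Data frame suitable for [features_to_mgf()].
#' @export
read_feature_table <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(rows) == 0L) stop(sprintf("feature table '%s' is empty", path))
  rows
}
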