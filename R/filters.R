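# Pre-annotation spectrum cleanup. Peaks are flagged, never deleted, so
# reports can show what each rule removed. Pipeline order is fixed:
# m/z window -> intensity thresholds -> deisotoping.

#' Filter configuration
#'
#' Defaults are the tool's standard settings: absolute intensity threshold
#' 500 cps, 1% relative intensity, a 1-100% isotope ratio window for the
#' z = 1 deisotoper, and monoisotopic validation enabled.
#'
#' @param abs_intensity_min Absolute intensity threshold in cps (default 500).
#' @param rel_intensity_min Relative threshold, percent of the base peak of
#'   the post-m/z-filter spectrum (default 1).
#' @param mz_range Optional `c(low, high)` window in Da.
#' @param isotope_ratio_range Percent interval for the intensity of an
#'   isotope peak relative to its envelope's monoisotopic peak
#'   (default `c(1, 100)`).
#' @param isotope_tolerance m/z tolerance in Da for the 1.003355 spacing
#'   (default 0.010, the annotation tolerance).
#' @param monoisotopic_validation Veto candidates that could themselves be
#'   isotopes (default `TRUE`).
#' @return A `filter_config` list.
#' @export
filter_config <- function(abs_intensity_min = 500, rel_intensity_min = 1,
                          mz_range = NULL, isotope_ratio_range = c(1, 100),
                          isotope_tolerance = 0.010,
                          monoisotopic_validation = TRUE) {
  if (rel_intensity_min < 0 || rel_intensity_min > 100)
    stop("rel_intensity_min must be in [0, 100]")
  if (length(isotope_ratio_range) != 2L || diff(isotope_ratio_range) <= 0)
    stop("isotope_ratio_range must be an increasing [low, high] percent interval")
  if (!is.null(mz_range)) {
    if (length(mz_range) != 2L || mz_range[1] >= mz_range[2])
      stop("mz_range must be c(low, high) with low < high")
  }
  if (isotope_tolerance <= 0) stop("isotope_tolerance must be positive")
  structure(list(abs_intensity_min = abs_intensity_min,
                 rel_intensity_min = rel_intensity_min,
                 mz_range = mz_range,
                 isotope_ratio_range = isotope_ratio_range,
                 isotope_tolerance = isotope_tolerance,
                 monoisotopic_validation = monoisotopic_validation),
            class = "filter_config")
}

#' Apply m/z and intensity thresholds
#'
#' Retains peaks inside `mz_range` whose intensity is at least
#' `abs_intensity_min` cps and at least `rel_intensity_min` percent of the
#' base peak (the base peak is taken after the m/z window). Removed peaks
#' are flagged `below_threshold`, not deleted. Idempotent.
#'
#' @param s An `ms_spectrum`.
#' @param cfg A [filter_config()].
#' @return The spectrum with `below_threshold` flags set.
#' @export
threshold_filter <- function(s, cfg = filter_config()) {
  stopifnot(inherits(s, "ms_spectrum"), inherits(cfg, "filter_config"))
  if (nrow(s) == 0L) return(s)
  flag <- s$below_threshold  # never un-flag: idempotence over repeated calls
  in_window <- rep(TRUE, nrow(s))
  if (!is.null(cfg$mz_range))
    in_window <- s$mz >= cfg$mz_range[1] & s$mz <= cfg$mz_range[2]
  flag <- flag | !in_window
  base <- max(c(0, s$intensity[in_window & !s$isotope_removed]))
  flag <- flag | s$intensity < cfg$abs_intensity_min
  flag <- flag | s$intensity < cfg$rel_intensity_min / 100 * base
  s$below_threshold <- flag
  if (all(flag | s$isotope_removed))
    warning(sprintf("spectrum '%s' is empty after threshold filtering",
                    attr(s, "title")))
  s
}

#' Deisotope a centroid spectrum (z = 1)
#'
#' Walks the retained peaks in ascending m/z. For each peak starting an
#' envelope, contiguous peaks at +k * 1.003355 Da (within
#' `isotope_tolerance`) whose intensity relative to the envelope's
#' monoisotopic peak lies inside `isotope_ratio_range` are flagged
#' `isotope_removed`. A peak claimed as an isotope cannot start a new
#' envelope; the lightest member of each envelope is always retained.
#' Multiply charged envelopes are not considered.
#'
#' @inheritParams threshold_filter
#' @return The spectrum with `isotope_removed` flags set.
#' @export
deisotope <- function(s, cfg = filter_config()) {
  stopifnot(inherits(s, "ms_spectrum"), inherits(cfg, "filter_config"))
  idx <- which(!s$below_threshold & !s$isotope_removed)
  if (length(idx) < 2L) return(s)
  mz <- s$mz[idx]; int <- s$intensity[idx]
  claimed <- logical(length(idx))
  for (i in seq_along(idx)) {
    if (claimed[i]) next
    k <- 1L
    repeat {
      target <- mz[i] + k * .C13_SPACING
      j <- which(!claimed & abs(mz - target) <= cfg$isotope_tolerance)
      if (length(j) == 0L) break
      j <- j[which.min(abs(mz[j] - target))]
      ratio <- 100 * int[j] / int[i]
      if (ratio < cfg$isotope_ratio_range[1] || ratio > cfg$isotope_ratio_range[2])
        break
      claimed[j] <- TRUE
      k <- k + 1L
    }
  }
  s$isotope_removed[idx[claimed]] <- TRUE
  s
}

#' Monoisotopic validation of a candidate peak
#'
#' A peak is a plausible monoisotopic (and hence [M+H]+ candidate) only if
#' no retained peak one 13C spacing below it could be its isotope parent,
#' i.e. there is no peak at `mz - 1.003355` (within tolerance) for which
#' the candidate's relative intensity falls inside `isotope_ratio_range`.
#'
#' @param s The spectrum (pre-deisotoping view: all non-threshold-flagged
#'   peaks are considered as possible parents).
#' @param mz m/z of the peak to validate.
#' @param cfg A [filter_config()].
#' @return `TRUE` if the peak passes (cannot be an isotope), else `FALSE`.
#' @export
validate_monoisotopic <- function(s, mz, cfg = filter_config()) {
  stopifnot(inherits(s, "ms_spectrum"))
  i <- which(abs(s$mz - mz) <= cfg$isotope_tolerance & !s$below_threshold)
  if (length(i) == 0L) stop(sprintf("no retained peak at m/z %.4f", mz))
  i <- i[which.min(abs(s$mz[i] - mz))]
  parents <- which(!s$below_threshold &
                     abs(s$mz - (s$mz[i] - .C13_SPACING)) <= cfg$isotope_tolerance)
  if (length(parents) == 0L) return(TRUE)
  ratios <- 100 * s$intensity[i] / s$intensity[parents]
  !any(ratios >= cfg$isotope_ratio_range[1] & ratios <= cfg$isotope_ratio_range[2])
}

#' Run the full filter pipeline
#'
#' Fixed order: m/z window and intensity thresholds, then deisotoping.
#'
#' @inheritParams threshold_filter
#' @return The filtered, deisotoped spectrum (flags set).
#' @export
filter_spectrum <- function(s, cfg = filter_config()) {
  deisotope(threshold_filter(s, cfg), cfg)
}
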