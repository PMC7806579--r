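# Centroid spectrum container. Peaks live in a data.frame with provenance
# flags so filtered peaks can be reported rather than silently dropped;
# retained = !below_threshold & !isotope_removed.

#' Construct a centroid spectrum
#'
#' @param mz Numeric vector of m/z values (Da, positive).
#' @param intensity Numeric vector of intensities (counts per second,
#'   non-negative), same length as `mz`.
#' @param title Free-text spectrum title.
#' @param retention_time Retention time in minutes, or `NA`.
#' @param polarity `"positive"` or `"negative"`.
#' @param merge_tol Duplicate m/z values closer than this (Da) are merged on
#'   construction by summing intensities (centroid exports occasionally
#'   repeat values). Default `1e-4`.
#' @return An `ms_spectrum`: data.frame with columns `mz`, `intensity`,
#'   `below_threshold`, `isotope_removed`, sorted by ascending m/z, plus
#'   `title`, `retention_time` and `polarity` attributes. `spectrum_tic()`
#'   gives the summed intensity of retained peaks.
#' @examples
#' s <- new_spectrum(c(116.0706, 154.0265), c(1e5, 2e4), title = "proline")
#' spectrum_tic(s)
#' @export
new_spectrum <- function(mz, intensity, title = "", retention_time = NA_real_,
                         polarity = "positive", merge_tol = 1e-4) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(mz <= 0)) stop("all m/z values must be positive")
    if (any(!is.finite(intensity)) || any(intensity < 0)) stop("intensities must be non-negative")
  }
  polarity <- match.arg(polarity, c("positive", "negative"))
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (length(mz) > 1L) {
    grp <- cumsum(c(TRUE, diff(mz) > merge_tol))
    if (max(grp) < length(mz)) {
      intensity <- as.numeric(tapply(intensity, grp, sum))
      mz <- as.numeric(tapply(mz, grp, function(x) x[1]))
    }
  }
  df <- data.frame(mz = mz, intensity = intensity,
                   below_threshold = logical(length(mz)),
                   isotope_removed = logical(length(mz)))
  structure(df, class = c("ms_spectrum", "data.frame"),
            title = title, retention_time = retention_time, polarity = polarity)
}

#' Retained peaks of a spectrum
#'
#' @param s An `ms_spectrum`.
#' @return Data frame of peaks not flagged by the intensity/m/z filters or
#'   the deisotoper.
#' @export
retained_peaks <- function(s) {
  stopifnot(inherits(s, "ms_spectrum"))
  s[!s$below_threshold & !s$isotope_removed, , drop = FALSE]
}

#' @rdname retained_peaks
#' @return `spectrum_tic()`: total ion current (sum of retained intensities).
#' @export
spectrum_tic <- function(s) sum(retained_peaks(s)$intensity)

#' @export
print.ms_spectrum <- function(x, ...) {
  kept <- retained_peaks(x)
  cat(sprintf("<spectrum> '%s'  %d peaks (%d retained), TIC %.4g",
              attr(x, "title"), nrow(x), nrow(kept), spectrum_tic(x)))
  rt <- attr(x, "retention_time")
  if (!is.na(rt)) cat(sprintf(", RT %.2f min", rt))
  cat("\n")
  invisible(x)
}

spectrum_title <- function(s) attr(s, "title")

# rebuild a spectrum keeping attributes but replacing the peak table
set_peaks <- function(s, df) {
  structure(df, class = c("ms_spectrum", "data.frame"),
            title = attr(s, "title"), retention_time = attr(s, "retention_time"),
            polarity = attr(s, "polarity"))
}
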