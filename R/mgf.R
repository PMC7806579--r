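# Mascot generic format (mgf) reading and writing for MS1 centroid batches.
# The dialect is deliberately tolerant: PEPMASS/CHARGE and other KEY=VALUE
# headers are accepted (MS1 exports usually carry none), peak lines are
# whitespace-separated "mz intensity" pairs, and polarity defaults to
# positive unless a CHARGE line says otherwise.

#' Read an mgf file into a batch of spectra
#'
#' @param path Path to an mgf file, or a character vector of lines via
#'   `text =`.
#' @param text Optional character vector of mgf lines (used instead of
#'   `path`).
#' @return A list of [new_spectrum()] objects, one per
#'   `BEGIN IONS`/`END IONS` block, in file order. `TITLE` and
#'   `RTINSECONDS` (converted to minutes) are parsed when present.
#' @examples
#' lines <- c("BEGIN IONS", "TITLE=demo", "100.05 1200", "END IONS")
#' read_mgf(text = lines)
#' @export
read_mgf <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("either path or text must be given")
    text <- readLines(path, warn = FALSE)
  }
  batch <- list()
  in_block <- FALSE
  mz <- NULL; int <- NULL; title <- ""; rt <- NA_real_; pol <- "positive"
  begin_line <- 0L
  for (i in seq_along(text)) {
    line <- trimws(text[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block)
        stop(sprintf("mgf format error: BEGIN IONS inside block at line %d", i))
      in_block <- TRUE; begin_line <- i
      mz <- numeric(0); int <- numeric(0)
      title <- ""; rt <- NA_real_; pol <- "positive"
    } else if (line == "END IONS") {
      if (!in_block)
        stop(sprintf("mgf format error: END IONS without BEGIN IONS at line %d", i))
      in_block <- FALSE
      batch[[length(batch) + 1L]] <-
        new_spectrum(mz, int, title = title, retention_time = rt, polarity = pol)
    } else if (in_block && grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "TITLE") title <- val
      else if (key == "RTINSECONDS") rt <- suppressWarnings(as.numeric(val)) / 60
      else if (key == "CHARGE" && grepl("-", val, fixed = TRUE)) pol <- "negative"
      # PEPMASS and any other headers are ignored
    } else if (in_block) {
      fields <- strsplit(line, "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields[1:2]))
      if (length(fields) < 2L || anyNA(vals))
        stop(sprintf("mgf format error: non-numeric peak line at line %d: '%s'", i, line))
      mz <- c(mz, vals[1]); int <- c(int, vals[2])
    } else {
      stop(sprintf("mgf format error: content outside BEGIN/END IONS at line %d", i))
    }
  }
  if (in_block)
    stop(sprintf("mgf format error: missing END IONS for block starting at line %d", begin_line))
  batch
}

#' Write a batch of spectra as mgf
#'
#' All peaks are written, including ones flagged by filters (mgf carries no
#' flag column); round-tripping a freshly read batch reproduces peaks to
#' 1e-4 m/z and 1e-2 intensity.
#'
#' @param batch A list of `ms_spectrum` objects (a single spectrum is
#'   accepted).
#' @param path Output path; omit to get the lines invisibly.
#' @return Character vector of mgf lines, invisibly when written to `path`.
#' @export
write_mgf <- function(batch, path = NULL) {
  if (inherits(batch, "ms_spectrum")) batch <- list(batch)
  lines <- character(0)
  for (s in batch) {
    stopifnot(inherits(s, "ms_spectrum"))
    if (nrow(s) == 0L)
      warning(sprintf("writing empty spectrum '%s'", attr(s, "title")))
    hdr <- c("BEGIN IONS",
             if (nzchar(attr(s, "title"))) sprintf("TITLE=%s", attr(s, "title")),
             if (!is.na(attr(s, "retention_time")))
               sprintf("RTINSECONDS=%.3f", attr(s, "retention_time") * 60),
             if (identical(attr(s, "polarity"), "negative")) "CHARGE=1-")
    peaks <- sprintf("%.4f %.2f", s$mz, s$intensity)
    lines <- c(lines, hdr, peaks, "END IONS", "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
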