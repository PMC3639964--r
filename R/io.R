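## Readers and writers for capture-history files (CSV and MARK-style .inp),
## fit and GOF reports, and JSON run manifests. Occasions are 1-based in all
## user-facing files.

#' Write capture histories as CSV
#'
#' Header row `id,occ1..occK`, 0/1 cells. With `sidecar = TRUE` a second
#' file `<path basename>_truth.csv` records the generating per-individual
#' detection probabilities (and group labels) of simulated data.
#'
#' @param ch a [capture_history()].
#' @param path output file.
#' @param sidecar also write the simulated-truth sidecar (ignored when the
#'   object carries no `true_p`)?
#' @return `path`, invisibly.
#' @export
write_capture_csv <- function(ch, path, sidecar = FALSE) {
  stopifnot(inherits(ch, "capture_history"))
  df <- data.frame(id = seq_len(ch$n), ch$y)
  names(df) <- c("id", paste0("occ", seq_len(ch$K)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar && !is.null(ch$true_p)) {
    tp <- data.frame(id = seq_len(ch$n), true_p = ch$true_p,
                     true_group = if (is.null(ch$true_group)) NA_integer_
                                  else ch$true_group)
    utils::write.csv(tp, sub("(\\.csv)?$", "_truth.csv", path, perl = TRUE),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read capture histories from CSV
#'
#' Expects the dialect of [write_capture_csv()]: an `id` column followed by
#' one 0/1 column per occasion.
#'
#' @param path input file.
#' @return a [capture_history()].
#' @export
read_capture_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  occ <- grep("^occ", names(df))
  if (!length(occ)) stop("no occasion columns (occ1..occK) found in ", path)
  y <- as.matrix(df[occ])
  if (anyNA(y) || !all(y %in% 0:1))
    stop("non-binary detection values in ", path)
  capture_history(y)
}

#' Write capture histories as a MARK-style .inp file
#'
#' One line per history: K digits, whitespace, a frequency, and a
#' terminating semicolon (e.g. `10110 3;`). By default one line per
#' individual (frequency 1) in row order, so a write/read round-trip
#' reproduces the matrix bit-identically; with `aggregate = TRUE` identical
#' histories are collapsed into one line with their count.
#'
#' @param ch a [capture_history()].
#' @param path output file.
#' @param aggregate collapse duplicate histories?
#' @return `path`, invisibly.
#' @export
write_inp <- function(ch, path, aggregate = FALSE) {
  stopifnot(inherits(ch, "capture_history"))
  strings <- apply(ch$y, 1, paste, collapse = "")
  if (aggregate) {
    tab <- table(strings)
    writeLines(sprintf("%s %d;", names(tab), as.integer(tab)), path)
  } else {
    writeLines(sprintf("%s 1;", strings), path)
  }
  invisible(path)
}

#' Read a MARK-style .inp capture-history file
#'
#' Dialect: each non-comment line is a digit string (one 0/1 digit per
#' occasion), whitespace, a positive integer frequency, and a terminating
#' semicolon; the frequency expands to that many identical rows. Comment
#' lines starting with `/*` are ignored. Malformed lines are reported with
#' their line numbers.
#'
#' @param path input file.
#' @return a [capture_history()].
#' @export
read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(/\\*|$)", lines))
  if (!length(keep)) stop("no capture histories found in ", path)
  pat <- "^\\s*([01]+)\\s+(\\d+)\\s*;\\s*$"
  bad <- keep[!grepl(pat, lines[keep])]
  if (length(bad))
    stop("malformed .inp line(s) ", paste(bad, collapse = ", "), " in ",
         path, " (expected e.g. \"10110 1;\")")
  hist <- sub(pat, "\\1", lines[keep])
  freq <- as.integer(sub(pat, "\\2", lines[keep]))
  if (length(unique(nchar(hist))) != 1)
    stop("ragged histories in ", path, ": occasion counts differ")
  if (any(freq < 1)) stop("frequencies must be positive in ", path)
  rows <- rep(seq_along(hist), freq)
  y <- do.call(rbind, lapply(strsplit(hist, "")[rows], as.integer))
  capture_history(y)
}

#' Read capture histories in either supported format
#'
#' @param path input file.
#' @param format `"auto"` (by file extension), `"csv"`, or `"inp"`.
#' @return a [capture_history()].
#' @export
read_capture_histories <- function(path, format = c("auto", "csv", "inp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.inp$", path, ignore.case = TRUE)) "inp" else "csv"
  switch(format, csv = read_capture_csv(path), inp = read_inp(path))
}

#' Write a fit summary as flat CSV
#'
#' Columns: parameter, mean, sd, q2.5, q50, q97.5, rhat.
#'
#' @param fit a `cjs_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  utils::write.csv(summary(fit), path, row.names = FALSE)
  invisible(path)
}

#' Write a GOF report as flat CSV
#' @param report a `gof_report` from [overall_gof()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gof_csv <- function(report, path) {
  stopifnot(inherits(report, "gof_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce an artifact: the seed, the full
#' configuration, package version and timestamp.
#'
#' @param path output file.
#' @param seed the seed used.
#' @param config list of configuration values (stored verbatim).
#' @param extra optional named list of further fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config = list(), extra = list()) {
  manifest <- c(list(
    package = "hetcjs",
    version = as.character(utils::packageVersion("hetcjs")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
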