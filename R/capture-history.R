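#' Capture-history objects
#'
#' A `capture_history` holds an individuals-by-occasions binary detection
#' matrix together with each individual's first-capture occasion, and
#' (for simulated data) the generating per-individual detection probabilities,
#' group labels and, optionally, the latent alive/dead states.
#'
#' Invariants enforced on construction: every entry is exactly 0 or 1, every
#' individual is detected at its first-capture occasion, and no detections
#' occur before first capture.
#'
#' @param detections binary matrix, individuals in rows, occasions in columns.
#' @param first_capture optional integer vector of first-capture occasions;
#'   computed from `detections` when `NULL`, validated against it otherwise.
#' @param true_p optional numeric vector of generating per-individual
#'   detection probabilities (simulated data only).
#' @param true_group optional group labels (two-group scenario).
#' @param alive optional binary matrix of latent alive states (debug mode).
#' @param scenario optional scenario label carried through from the simulator.
#'
#' @return An object of class `capture_history`: a list with elements `y`
#'   (the detection matrix), `first`, `n`, `K`, and any of the optional
#'   fields supplied.
#' @export
capture_history <- function(detections, first_capture = NULL, true_p = NULL,
                            true_group = NULL, alive = NULL, scenario = NULL) {
  y <- as.matrix(detections)
  dimnames(y) <- NULL
  storage.mode(y) <- "integer"
  if (anyNA(y) || !all(y == 0L | y == 1L))
    stop("detections must contain only 0/1 values")
  n <- nrow(y); K <- ncol(y)
  if (K < 2) stop("need at least 2 occasions")
  if (n > 0L && any(rowSums(y) == 0L))
    stop("every individual must be detected at least once")
  f <- if (n > 0L) max.col(y == 1L, ties.method = "first") else integer(0)
  if (!is.null(first_capture)) {
    if (!identical(as.integer(first_capture), as.integer(f)))
      stop("first_capture inconsistent with the detection matrix")
  }
  if (!is.null(true_p)) {
    if (length(true_p) != n) stop("true_p must have one entry per individual")
    if (any(true_p <= 0 | true_p > 1)) stop("true_p must lie in (0,1]")
  }
  structure(list(y = y, first = as.integer(f), n = n, K = K,
                 true_p = true_p, true_group = true_group,
                 alive = alive, scenario = scenario),
            class = "capture_history")
}

#' @export
print.capture_history <- function(x, ...) {
  cat(sprintf("Capture histories: %d individuals x %d occasions\n", x$n, x$K))
  if (!is.null(x$scenario)) cat("  scenario:", x$scenario, "\n")
  if (x$n > 0) {
    cat(sprintf("  detections: %d (%.1f%% of cells); cohort sizes: %s\n",
                sum(x$y), 100 * mean(x$y),
                paste(tabulate(x$first, x$K), collapse = " ")))
  }
  invisible(x)
}

#' @export
as.matrix.capture_history <- function(x, ...) x$y

#' Number of individuals first marked at the final occasion
#'
#' These individuals carry no recapture information and contribute a constant
#' to CJS likelihoods (which condition on first capture); they are retained
#' for fidelity to the release schedule.
#'
#' @param ch a [capture_history()].
#' @return integer count.
#' @export
n_terminal_releases <- function(ch) sum(ch$first == ch$K)
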