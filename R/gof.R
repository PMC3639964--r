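## Goodness-of-fit suite for the CJS model, in the RELEASE / U-CARE
## tradition: per-occasion 2x2 contingency tables for transience (TEST3.SR),
## timing of next reencounter among newly vs previously marked (TEST3.SM),
## immediate trap-dependence (TEST2.CT), and timing structure among animals
## skipping an occasion (TEST2.CL); component chi-squares are summed into an
## overall statistic whose ratio to its df is the overdispersion factor
## c-hat.
##
## Pooling rule: tables whose four expected counts are all >= 2 contribute
## one df each; the remaining tables of a component are summed into a single
## pooled table which contributes one df iff its margins are positive and
## its expected counts reach the same threshold. Directional z statistics
## use all tables with nonzero hypergeometric variance (no pooling) and are
## the sum of per-table standardized deviations over sqrt(#tables).

#' Build the m-array of a capture-history dataset
#'
#' The standard sufficient reduction of CJS data: for each release occasion
#' `t` (1..K-1), the number of animals released (newly marked or just
#' recaptured — every detection is a release for the next interval), the
#' counts of first recaptures at each later occasion `j`, and the number
#' never recaptured after `t`.
#'
#' @param ch a [capture_history()].
#' @return Object of class `marray`: list with `releases` (length K-1), `m`
#'   (matrix, rows = release occasions 1..K-1, columns = recapture occasions
#'   2..K), and `never_recaptured` (length K-1).
#' @export
build_marray <- function(ch) {
  stopifnot(inherits(ch, "capture_history"))
  K <- ch$K
  m <- matrix(0L, K - 1L, K - 1L,
              dimnames = list(released = seq_len(K - 1L),
                              recaptured = 2:K))
  releases <- integer(K - 1L)
  never <- integer(K - 1L)
  y <- ch$y
  for (t in seq_len(K - 1L)) {
    rel <- which(y[, t] == 1L)
    releases[t] <- length(rel)
    if (!length(rel)) next
    later <- y[rel, (t + 1L):K, drop = FALSE]
    nxt <- apply(later, 1L, function(r) {
      w <- which(r == 1L)
      if (length(w)) w[1] + t else NA_integer_
    })
    never[t] <- sum(is.na(nxt))
    tab <- table(factor(nxt[!is.na(nxt)], levels = 2:K))
    m[t, ] <- m[t, ] + as.integer(tab)
  }
  structure(list(releases = releases, m = m, never_recaptured = never),
            class = "marray")
}

#' @export
print.marray <- function(x, ...) {
  cat("CJS m-array (rows: release occasion; columns: first recapture)\n")
  out <- cbind(R = x$releases, x$m, never = x$never_recaptured)
  print(out)
  invisible(x)
}

# Pearson chi-square of a 2 x C contingency table (all-zero columns
# removed by the caller). For 2x2 tables a hypergeometric-standardized
# deviation of cell [1,1] is also returned: variance
# R1*R2*C1*C2 / (N^2 (N-1)).
.table_stats <- function(tab) {
  N <- sum(tab)
  r <- rowSums(tab); cs <- colSums(tab)
  if (N == 0 || any(r == 0) || any(cs == 0) || ncol(tab) < 2)
    return(list(informative = FALSE, chi2 = 0, df = 0L, z = NA_real_,
                min_expected = 0, tab = tab))
  E <- outer(r, cs) / N
  chi2 <- sum((tab - E)^2 / E)
  z <- NA_real_
  if (all(dim(tab) == 2)) {
    v <- prod(r) * prod(cs) / (N^2 * (N - 1))
    if (v > 0) z <- (tab[1, 1] - E[1, 1]) / sqrt(v)
  }
  list(informative = TRUE, chi2 = chi2,
       df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
       z = z, min_expected = min(E), tab = tab)
}

# Column pooling for timing tables: drop all-zero columns, then merge the
# rightmost column into its neighbour (longer reencounter gaps are the
# sparse ones) until every expected count reaches the threshold or only
# two columns remain.
.pool_columns <- function(tab, min_expected) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  while (ncol(tab) > 2) {
    N <- sum(tab)
    if (N > 0 && all(rowSums(tab) > 0)) {
      E <- outer(rowSums(tab), colSums(tab)) / N
      if (min(E) >= min_expected) break
    }
    C <- ncol(tab)
    tab[, C - 1L] <- tab[, C - 1L] + tab[, C]
    tab <- tab[, -C, drop = FALSE]
  }
  tab
}

# Collapse a timing table to 2x2 (first column vs the rest) so that sparse
# leftovers can be accumulated across occasions.
.collapse_2x2 <- function(tab) {
  if (ncol(tab) < 2) return(NULL)
  cbind(tab[, 1], rowSums(tab[, -1, drop = FALSE]))
}

# Combine a component's per-occasion tables (2x2 or 2xC timing tables)
# into (chi2, df, p) with pooling, and a directional z (sign_flip = TRUE
# flips so that the component's "positive" direction matches its
# convention). Tables that stay sparse after column pooling are collapsed
# to 2x2 and accumulated into one pooled table.
.combine_tables <- function(tables, min_expected = 2, sign_flip = FALSE) {
  if (!length(tables))
    return(list(chi2 = 0, df = 0L, p = NA_real_, z = NA_real_,
                p_z = NA_real_, degenerate = TRUE, pooled_used = FALSE,
                n_tables = 0L, tables = tables))
  pooled_tabs <- lapply(tables, .pool_columns, min_expected = min_expected)
  stats_list <- lapply(pooled_tabs, .table_stats)
  use <- vapply(stats_list, function(s)
    s$informative && s$min_expected >= min_expected, logical(1))
  chi2 <- sum(vapply(stats_list[use], `[[`, numeric(1), "chi2"))
  df <- sum(vapply(stats_list[use], `[[`, integer(1), "df"))
  pooled_used <- FALSE
  if (any(!use)) {
    leftovers <- Filter(Negate(is.null),
                        lapply(pooled_tabs[!use], .collapse_2x2))
    if (length(leftovers)) {
      ps <- .table_stats(Reduce(`+`, leftovers))
      if (ps$informative && ps$min_expected >= min_expected) {
        chi2 <- chi2 + ps$chi2
        df <- df + ps$df
        pooled_used <- TRUE
      }
    }
  }
  # directional statistic: per-table standardized deviations of the 2x2
  # collapse, aggregated over informative occasions
  zs <- vapply(tables, function(tab) {
    t2 <- .collapse_2x2(.pool_columns(tab, min_expected))
    if (is.null(t2)) return(NA_real_)
    .table_stats(t2)$z
  }, numeric(1))
  zs <- zs[is.finite(zs)]
  z <- if (length(zs)) sum(zs) / sqrt(length(zs)) else NA_real_
  if (sign_flip) z <- -z
  list(chi2 = chi2, df = as.integer(df),
       p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
           else NA_real_,
       z = z,
       p_z = if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else NA_real_,
       degenerate = df == 0L, pooled_used = pooled_used,
       n_tables = length(tables), tables = tables)
}

.component_result <- function(component, res) {
  structure(c(list(component = component), res), class = "gof_component")
}

#' @export
print.gof_component <- function(x, ...) {
  cat(sprintf("%s: chi2 = %.3f, df = %d, p = %s", x$component, x$chi2, x$df,
              if (is.na(x$p)) "NA (degenerate)" else format(x$p, digits = 3)))
  if (!is.null(x$z) && is.finite(x$z))
    cat(sprintf("; directional z = %.3f (p = %.3g)", x$z, x$p_z))
  cat("\n")
  invisible(x)
}

#' TEST3.SR: transience
#'
#' Per intermediate occasion `t`, a 2x2 table of newly marked (first capture
#' at `t`) versus previously marked animals captured at `t`, against whether
#' they are ever reseen after `t`. The directional z is positive when newly
#' marked animals are reseen less than expected (transience).
#'
#' @param ch a [capture_history()].
#' @param min_expected pooling threshold on expected cell counts.
#' @return `gof_component` with `chi2`, `df`, `p`, directional `z`, `p_z`.
#' @export
test3_sr <- function(ch, min_expected = 2) {
  stopifnot(inherits(ch, "capture_history"))
  if (ch$K < 3) stop("TEST3.SR requires at least 3 occasions")
  y <- ch$y; K <- ch$K
  tables <- lapply(2:(K - 1L), function(t) {
    at_t <- y[, t] == 1L
    new <- at_t & ch$first == t
    old <- at_t & ch$first < t
    reseen <- rowSums(y[, (t + 1L):K, drop = FALSE]) > 0
    rbind(new = c(reseen = sum(new & reseen), not = sum(new & !reseen)),
          old = c(reseen = sum(old & reseen), not = sum(old & !reseen)))
  })
  # cell [1,1] is "new & reseen"; transience = new reseen *less* -> flip
  .component_result("TEST3.SR",
                    .combine_tables(tables, min_expected, sign_flip = TRUE))
}

#' TEST3.SM: timing of next reencounter, newly vs previously marked
#'
#' Among animals captured at `t` that are reseen again, compares newly vs
#' previously marked animals on the occasion of their next reencounter
#' (a `2 x (K - t)` timing table per occasion; sparse tail columns are
#' pooled).
#'
#' @inheritParams test3_sr
#' @return `gof_component` (no directional statistic).
#' @export
test3_sm <- function(ch, min_expected = 2) {
  stopifnot(inherits(ch, "capture_history"))
  if (ch$K < 3) stop("TEST3.SM requires at least 3 occasions")
  y <- ch$y; K <- ch$K
  tables <- lapply(2:(K - 1L), function(t) {
    later <- y[, (t + 1L):K, drop = FALSE]
    keep <- y[, t] == 1L & rowSums(later) > 0
    nxt <- max.col(later == 1L, ties.method = "first")   # 1 .. K - t
    rbind(new = tabulate(nxt[keep & ch$first == t], K - t),
          old = tabulate(nxt[keep & ch$first < t], K - t))
  })
  res <- .combine_tables(tables, min_expected)
  res$z <- NA_real_; res$p_z <- NA_real_
  .component_result("TEST3.SM", res)
}

#' TEST2.CT: immediate trap-dependence
#'
#' Per occasion `t`, among animals marked at or before `t` and known alive
#' at `t + 1` (seen at or after `t + 1`), a 2x2 table of captured at `t`
#' versus not, against captured at `t + 1` versus not. The directional z is
#' positive when capture at `t` predicts capture at `t + 1`
#' (trap-happiness); negative z indicates trap-shyness.
#'
#' @inheritParams test3_sr
#' @return `gof_component` with directional `z`.
#' @export
test2_ct <- function(ch, min_expected = 2) {
  stopifnot(inherits(ch, "capture_history"))
  if (ch$K < 3) stop("TEST2.CT requires at least 3 occasions")
  y <- ch$y; K <- ch$K
  tables <- lapply(2:(K - 1L), function(t) {
    marked <- ch$first <= t
    alive_after <- rowSums(y[, (t + 1L):K, drop = FALSE]) > 0
    keep <- marked & alive_after
    ct <- y[, t] == 1L
    ct1 <- y[, t + 1L] == 1L
    rbind(caught_t = c(caught_t1 = sum(keep & ct & ct1),
                       not = sum(keep & ct & !ct1)),
          missed_t = c(caught_t1 = sum(keep & !ct & ct1),
                       not = sum(keep & !ct & !ct1)))
  })
  .component_result("TEST2.CT", .combine_tables(tables, min_expected))
}

#' TEST2.CL: timing structure among animals skipping an occasion
#'
#' Among animals marked at or before `t`, not seen at `t + 1`, and seen at
#' or after `t + 2`, compares animals captured at `t` versus not on the
#' occasion of their next encounter (a `2 x (K - t - 1)` timing table per
#' occasion; sparse tail columns are pooled). Needs at least 4 occasions to
#' be informative; with exactly 3 a degenerate df-0 result is returned,
#' flagged.
#'
#' @inheritParams test3_sr
#' @return `gof_component` (no directional statistic).
#' @export
test2_cl <- function(ch, min_expected = 2) {
  stopifnot(inherits(ch, "capture_history"))
  if (ch$K < 3) stop("TEST2.CL requires at least 3 occasions")
  y <- ch$y; K <- ch$K
  ts <- if (K >= 4) 2:(K - 2L) else integer(0)
  tables <- lapply(ts, function(t) {
    later <- y[, (t + 2L):K, drop = FALSE]
    keep <- ch$first <= t & y[, t + 1L] == 0L & rowSums(later) > 0
    nxt <- max.col(later == 1L, ties.method = "first")   # 1 .. K - t - 1
    ct <- y[, t] == 1L
    rbind(caught_t = tabulate(nxt[keep & ct], K - t - 1L),
          missed_t = tabulate(nxt[keep & !ct], K - t - 1L))
  })
  res <- .combine_tables(tables, min_expected)
  res$z <- NA_real_; res$p_z <- NA_real_
  .component_result("TEST2.CL", res)
}

#' Overall CJS goodness-of-fit test and overdispersion factor
#'
#' Sums the four component tests (TEST3.SR + TEST3.SM + TEST2.CT + TEST2.CL)
#' into an overall chi-square and computes the overdispersion factor
#' `c_hat = chi2 / df` (NA, flagged, when the total df is 0). TEST2.CL
#' contributes df 0 when the study has fewer than 4 occasions.
#'
#' @inheritParams test3_sr
#' @return Object of class `gof_report`: component results, `chi2`, `df`,
#'   `p`, `c_hat`, directional test results, and the m-array.
#' @export
overall_gof <- function(ch, min_expected = 2) {
  stopifnot(inherits(ch, "capture_history"))
  comps <- list(test3_sr(ch, min_expected), test3_sm(ch, min_expected),
                test2_ct(ch, min_expected), test2_cl(ch, min_expected))
  names(comps) <- vapply(comps, `[[`, character(1), "component")
  chi2 <- sum(vapply(comps, `[[`, numeric(1), "chi2"))
  df <- sum(vapply(comps, `[[`, numeric(1), "df"))
  structure(list(
    components = comps,
    chi2 = chi2, df = df,
    p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
    c_hat = if (df > 0) chi2 / df else NA_real_,
    degenerate = df == 0L,
    transience = comps$TEST3.SR[c("z", "p_z")],
    trap_dependence = comps$TEST2.CT[c("z", "p_z")],
    marray = build_marray(ch)), class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat("CJS goodness-of-fit (TEST3.SR + TEST3.SM + TEST2.CT + TEST2.CL)\n")
  for (comp in x$components) print(comp)
  cat(sprintf("Overall: chi2 = %.3f, df = %d, p = %s; c-hat = %s\n",
              x$chi2, x$df,
              if (is.na(x$p)) "NA" else format(x$p, digits = 3),
              if (is.na(x$c_hat)) "NA (df = 0)"
              else format(x$c_hat, digits = 4)))
  invisible(x)
}

#' @export
as.data.frame.gof_report <- function(x, ...) {
  rows <- lapply(x$components, function(cmp)
    data.frame(component = cmp$component, chi2 = cmp$chi2, df = cmp$df,
               p = cmp$p, z = cmp$z, p_z = cmp$p_z))
  out <- do.call(rbind, c(rows, list(
    data.frame(component = "overall", chi2 = x$chi2, df = x$df, p = x$p,
               z = NA_real_, p_z = NA_real_))))
  rownames(out) <- NULL
  out
}
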