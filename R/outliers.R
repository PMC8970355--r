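# Genome-wide balancing-selection outlier scan: per-statistic extreme-tail
# flags combined into candidate calls.

default_directions <- function() {
  c(pi_over_dxy = "high", tajima_D = "high", dS = "high",
    partial_hka = "high", fst = "low")
}

# nearest-rank tail threshold: the k = ceiling(q*m) most extreme values are
# beyond it; ties AT the threshold are not flagged (strictly-beyond rule)
tail_flags <- function(x, q, direction) {
  flags <- rep(FALSE, length(x))
  ok <- !is.na(x)
  m <- sum(ok)
  if (m == 0L) return(flags)
  k <- ceiling(q * m)
  sorted <- sort(x[ok])
  if (direction == "high") {
    thr <- if (m - k >= 1L) sorted[m - k] else -Inf
    flags[ok] <- x[ok] > thr
  } else {
    thr <- if (k + 1L <= m) sorted[k + 1L] else Inf
    flags[ok] <- x[ok] < thr
  }
  flags
}

#' Genome-wide outlier scan over per-gene statistics
#'
#' For each statistic column the empirical extreme tail is flagged: the
#' `ceiling(q * m)` most extreme non-missing values among `m` genes
#' (upper tail for "high" statistics, lower tail for Fst), by the
#' nearest-rank rule with ties at the threshold not flagged. Per-species
#' columns of one statistic family (e.g. `pi_over_dxy_A` /
#' `pi_over_dxy_B`) are each flagged on their own tail; `n_flags` counts
#' flagged columns. A gene is a candidate when `n_flags >= min_flags`.
#'
#' @param stats_table data.frame with a `gene_id` column and statistic
#'   columns; recognised families are `pi_over_dxy_*` (high), `tajima_*`
#'   (high), `ds_within` (high), `partial_hka*` (high), `fst` (low).
#' @param directions Named character vector family -> `"high"`/`"low"`;
#'   defaults to the five families above. `dN` is reported upstream but is
#'   not a default flag family.
#' @param q Tail mass per statistic (default 0.01).
#' @param min_flags Families required to call a candidate (default 2).
#' @return data.frame of class `outlier_report`: the input statistic
#'   columns plus per-family `flag_*` logicals, `n_flags` and `candidate`.
#' @export
outlier_scan <- function(stats_table, directions = default_directions(),
                         q = 0.01, min_flags = 2L) {
  if (nrow(stats_table) < 10L) stop("outlier scan needs >= 10 genes")
  if (q <= 0 || q >= 0.5 + 1e-12) stop("q must be in (0, 0.5]")
  fam_cols <- list(
    pi_over_dxy = grep("^pi_over_dxy", names(stats_table), value = TRUE),
    tajima_D = grep("^tajima", names(stats_table), value = TRUE),
    dS = intersect(c("ds_within_A", "ds_within_B"), names(stats_table)),
    partial_hka = grep("^partial_hka", names(stats_table), value = TRUE),
    fst = intersect("fst", names(stats_table)))
  out <- stats_table
  n_flags <- rep(0L, nrow(stats_table))
  for (fam in names(directions)) {
    cols <- fam_cols[[fam]]
    if (is.null(cols) || !length(cols)) next
    for (col in cols) {
      x <- stats_table[[col]]
      if (all(is.na(x))) {
        warning("statistic column '", col, "' is all-missing: skipped")
        next
      }
      fl <- tail_flags(x, q, directions[[fam]])
      out[[paste0("flag_", col)]] <- fl
      n_flags <- n_flags + as.integer(fl)
    }
  }
  out$n_flags <- n_flags
  out$candidate <- n_flags >= min_flags
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<outlier_report> %d genes, %d candidate(s)\n",
              nrow(df), sum(df$candidate %||% FALSE)))
  cand <- df[isTRUE(df$candidate) | df$candidate %in% TRUE,
             intersect(c("gene_id", "category", "n_flags"), names(df)),
             drop = FALSE]
  if (nrow(cand)) print(cand, row.names = FALSE)
  invisible(x)
}

#' @export
`[.outlier_report` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}
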