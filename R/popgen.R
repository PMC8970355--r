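# Per-gene population-genetic statistics: segregating sites, nucleotide
# diversity, dxy, Hudson's Fst, Tajima's D, and the per-gene summary table.
#
# Missing-data policy: S (a column property) uses complete deletion --
# columns containing any gap or ambiguity in any selected strain are
# dropped, and the mean pairwise difference feeding Tajima's D is computed
# on the same column set. pi and dxy (pair properties) use pairwise
# deletion.

complete_cols <- function(m, alphabet) {
  miss <- missing_chars(alphabet)
  which(colSums(matrix(m %in% miss, nrow = nrow(m))) == 0L)
}

#' Number of segregating sites
#'
#' Counts alignment columns with at least two distinct residues among the
#' selected strains, after complete deletion of columns containing any
#' gap/ambiguity character.
#'
#' @param aln A [species_alignment()].
#' @param strains Strain ids to use (default: all).
#' @return Integer count.
#' @export
segregating_sites <- function(aln, strains = NULL) {
  m <- aln_matrix(aln, strains)
  if (nrow(m) < 2L) stop("segregating_sites needs >= 2 strains")
  keep <- complete_cols(m, aln$alphabet)
  if (!length(keep)) return(0L)
  m <- m[, keep, drop = FALSE]
  sum(apply(m, 2L, function(col) length(unique(col))) >= 2L)
}

# S, mean pairwise difference count and n on the complete-deletion columns
tajima_inputs <- function(aln, strains = NULL) {
  m <- aln_matrix(aln, strains)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 strains")
  keep <- complete_cols(m, aln$alphabet)
  m <- m[, keep, drop = FALSE]
  S <- if (ncol(m)) sum(apply(m, 2L, function(col) length(unique(col))) >= 2L) else 0L
  diffs <- 0
  npair <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    diffs <- diffs + sum(m[i, ] != m[j, ])
    npair <- npair + 1L
  }
  list(S = S, khat = diffs / npair, n = n, L = ncol(m))
}

#' Nucleotide diversity per site (pi)
#'
#' Mean over all strain pairs of per-site differences, with pairwise
#' deletion of columns missing in either member of a pair. Pairs with zero
#' comparable sites are excluded with a warning; if every pair is excluded
#' the result is `NA`.
#'
#' @inheritParams segregating_sites
#' @return Per-site diversity (numeric), or `NA` if undefined.
#' @export
nucleotide_diversity <- function(aln, strains = NULL) {
  m <- aln_matrix(aln, strains)
  if (nrow(m) < 2L) stop("nucleotide_diversity needs >= 2 strains")
  miss <- missing_chars(aln$alphabet)
  vals <- c()
  dropped <- 0L
  n <- nrow(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !(m[i, ] %in% miss) & !(m[j, ] %in% miss)
    if (!any(ok)) { dropped <- dropped + 1L; next }
    vals <- c(vals, sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
  if (dropped > 0L)
    warning(dropped, " pair(s) with zero comparable sites excluded")
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Absolute divergence per site (dxy)
#'
#' Mean over all cross-group strain pairs of per-site differences, with
#' pairwise deletion.
#'
#' @param aln A [species_alignment()].
#' @param strains_A,strains_B Strain ids of the two groups (non-empty,
#'   disjoint).
#' @return Per-site divergence, or `NA` if no pair is comparable.
#' @export
dxy <- function(aln, strains_A, strains_B) {
  if (!length(strains_A) || !length(strains_B))
    stop("dxy needs a non-empty strain set on both sides")
  mA <- aln_matrix(aln, strains_A)
  mB <- aln_matrix(aln, strains_B)
  miss <- missing_chars(aln$alphabet)
  vals <- c()
  dropped <- 0L
  for (i in seq_len(nrow(mA))) for (j in seq_len(nrow(mB))) {
    ok <- !(mA[i, ] %in% miss) & !(mB[j, ] %in% miss)
    if (!any(ok)) { dropped <- dropped + 1L; next }
    vals <- c(vals, sum(mA[i, ok] != mB[j, ok]) / sum(ok))
  }
  if (dropped > 0L)
    warning(dropped, " cross pair(s) with zero comparable sites excluded")
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Hudson's Fst from pi and dxy
#'
#' `Fst = 1 - ((pi_A + pi_B) / 2) / dxy`. Undefined (`NA`) when `dxy` is
#' zero; negative values are reported as computed, not clamped.
#'
#' @param pi_A,pi_B Within-species per-site diversities (>= 0).
#' @param dxy Between-species per-site divergence (>= 0).
#' @return Fst (numeric <= 1), or `NA`.
#' @export
hudson_fst <- function(pi_A, pi_B, dxy) {
  if (any(c(pi_A, pi_B, dxy) < 0, na.rm = TRUE))
    stop("pi and dxy must be non-negative")
  if (is.na(dxy) || is.na(pi_A) || is.na(pi_B)) return(NA_real_)
  if (dxy == 0) return(NA_real_)
  1 - ((pi_A + pi_B) / 2) / dxy
}

#' Tajima's D constants for sample size n
#'
#' The a1, a2, b1, b2, c1, c2, e1, e2 coefficients of Tajima's (1989)
#' variance formula.
#'
#' @param n Sample size (>= 2).
#' @return Named list of constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2L) stop("Tajima constants require n >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from summary quantities
#'
#' `D = (khat - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with `khat` the mean
#' pairwise difference count (not per site) on the same complete-deletion
#' column set that produced `S`. Returns `NA` when `S = 0` (the statistic
#' is undefined).
#'
#' @param S Number of segregating sites (>= 0).
#' @param khat Mean pairwise difference count.
#' @param n Sample size; `n < 4` is accepted with a warning (the variance
#'   terms are unstable).
#' @return Tajima's D, or `NA`.
#' @export
tajimas_d <- function(S, khat, n) {
  if (S < 0) stop("S must be >= 0")
  if (n < 2L) stop("Tajima's D requires n >= 2")
  if (n < 4L) warning("Tajima's D with n < 4 is unstable")
  if (S == 0L) return(NA_real_)
  k <- tajima_constants(n)
  (khat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D for a set of strains in an alignment
#'
#' Convenience wrapper: computes S and the mean pairwise difference on the
#' complete-deletion column set and applies [tajimas_d()].
#'
#' @inheritParams segregating_sites
#' @return Tajima's D, or `NA`.
#' @export
tajimas_d_aln <- function(aln, strains = NULL) {
  ti <- tajima_inputs(aln, strains)
  tajimas_d(ti$S, ti$khat, ti$n)
}

median_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else stats::median(x)
}

#' Per-gene population-genetic summary table
#'
#' One row per gene in the panel: within-species sample sizes, segregating
#' sites, pi and Tajima's D; between-species dxy and Hudson's Fst; per
#' species pi/dxy ratios; and, for in-frame nucleotide alignments, medians
#' of pairwise Nei-Gojobori dS and dN within each species and between
#' species, with the within/between dS and dN ratios (pooled within-species
#' median over between-species median). Species with fewer than two strains
#' at a gene get `NA` within-species fields.
#'
#' @param panel A [gene_panel()].
#' @param species_A,species_B Species labels as used in the alignments'
#'   `species_of` maps.
#' @param codon_stats Compute dS/dN medians (requires lengths divisible
#'   by 3).
#' @return data.frame, one row per gene.
#' @export
gene_summary <- function(panel, species_A = "speciesA", species_B = "speciesB",
                         codon_stats = TRUE) {
  rows <- lapply(names(panel$genes), function(gid) {
    aln <- panel$genes[[gid]]
    sa <- strains_of_species(aln, species_A)
    sb <- strains_of_species(aln, species_B)
    rec <- list(gene_id = gid, category = unname(panel$category_of[gid]),
                n_A = length(sa), n_B = length(sb))
    within <- function(strains) {
      if (length(strains) < 2L)
        return(list(S = NA_integer_, pi = NA_real_, D = NA_real_))
      ti <- tajima_inputs(aln, strains)
      list(S = ti$S, pi = suppressWarnings(nucleotide_diversity(aln, strains)),
           D = tajimas_d(ti$S, ti$khat, ti$n))
    }
    wa <- within(sa); wb <- within(sb)
    d <- if (length(sa) && length(sb))
      suppressWarnings(dxy(aln, sa, sb)) else NA_real_
    rec <- c(rec, list(
      S_A = wa$S, pi_A = wa$pi, tajima_A = wa$D,
      S_B = wb$S, pi_B = wb$pi, tajima_B = wb$D,
      dxy = d,
      fst = if (!is.na(d) && !is.na(wa$pi) && !is.na(wb$pi))
        hudson_fst(wa$pi, wb$pi, d) else NA_real_,
      pi_over_dxy_A = if (!is.na(d) && d > 0) wa$pi / d else NA_real_,
      pi_over_dxy_B = if (!is.na(d) && d > 0) wb$pi / d else NA_real_))
    if (codon_stats && aln$alphabet == "dna" && aln$length %% 3L == 0L) {
      ng_safe <- function(s1, s2) {
        tryCatch(suppressWarnings(ng86_pairwise(s1, s2)),
                 error = function(e) {
                   warning("gene '", gid, "': ", conditionMessage(e),
                           "; pair skipped", call. = FALSE)
                   list(dS = NA_real_, dN = NA_real_)
                 })
      }
      pair_stats <- function(ids1, ids2 = NULL) {
        ds <- c(); dn <- c()
        if (is.null(ids2)) {
          if (length(ids1) >= 2L)
            for (i in seq_along(ids1)[-length(ids1)])
              for (j in (i + 1L):length(ids1)) {
                p <- ng_safe(aln$seqs[[ids1[i]]], aln$seqs[[ids1[j]]])
                ds <- c(ds, p$dS); dn <- c(dn, p$dN)
              }
        } else {
          for (i in seq_along(ids1)) for (j in seq_along(ids2)) {
            p <- ng_safe(aln$seqs[[ids1[i]]], aln$seqs[[ids2[j]]])
            ds <- c(ds, p$dS); dn <- c(dn, p$dN)
          }
        }
        list(ds = ds, dn = dn)
      }
      wA <- pair_stats(sa); wB <- pair_stats(sb); btw <- pair_stats(sa, sb)
      ds_within <- c(wA$ds, wB$ds); dn_within <- c(wA$dn, wB$dn)
      rec <- c(rec, list(
        ds_within_A = median_or_na(wA$ds), ds_within_B = median_or_na(wB$ds),
        ds_within = median_or_na(ds_within),
        ds_between = median_or_na(btw$ds),
        dn_within_A = median_or_na(wA$dn), dn_within_B = median_or_na(wB$dn),
        dn_within = median_or_na(dn_within),
        dn_between = median_or_na(btw$dn)))
      rec$ds_ratio_wb <- if (!is.na(rec$ds_between) && rec$ds_between > 0)
        rec$ds_within / rec$ds_between else NA_real_
      rec$dn_ratio_wb <- if (!is.na(rec$dn_between) && rec$dn_between > 0)
        rec$dn_within / rec$dn_between else NA_real_
    }
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
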