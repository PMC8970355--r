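# Nei-Gojobori (1986) pairwise dS/dN with Jukes-Cantor correction.
#
# Synonymous sites per codon position are the fraction of the three
# one-step neighbours that are synonymous (changes to stop codons count as
# nonsynonymous), so syn + nonsyn sites always total 3 per codon. Multi-hit
# codon differences are averaged over all orderings of single steps;
# orderings passing through a stop codon are excluded and the weights of
# the remaining orderings renormalized. Codon pairs with every path blocked
# are skipped with a warning. No transition/transversion or codon-frequency
# weighting is applied (the plain equal-weight pathway estimator).

ng86_tables <- function() {
  if (!is.null(the$ng86)) return(the$ng86)
  gc <- genetic_code()
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  n64 <- length(codons)
  # synonymous site counts per codon (NA for stops)
  syn_sites <- stats::setNames(rep(NA_real_, n64), codons)
  for (cod in codons) {
    if (gc[cod] == "*") next
    s <- 0
    cv <- strsplit(cod, "", fixed = TRUE)[[1]]
    for (pos in 1:3) for (b in setdiff(bases, cv[pos])) {
      nb <- cv; nb[pos] <- b
      if (gc[paste(nb, collapse = "")] == gc[cod]) s <- s + 1 / 3
    }
    syn_sites[cod] <- s
  }
  # pathway-averaged syn/nonsyn difference counts per codon pair
  Sd <- matrix(NA_real_, n64, n64, dimnames = list(codons, codons))
  Nd <- Sd
  perms <- list(`1` = list(1L), `2` = list(1:2, 2:1),
                `3` = list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                           c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  for (i in seq_len(n64)) {
    if (gc[codons[i]] == "*") next
    ci <- strsplit(codons[i], "", fixed = TRUE)[[1]]
    for (j in seq_len(n64)) {
      if (gc[codons[j]] == "*") next
      cj <- strsplit(codons[j], "", fixed = TRUE)[[1]]
      dpos <- which(ci != cj)
      if (!length(dpos)) { Sd[i, j] <- 0; Nd[i, j] <- 0; next }
      sd_tot <- 0; nd_tot <- 0; nvalid <- 0L
      for (ord in perms[[as.character(length(dpos))]]) {
        cur <- ci; sd <- 0; nd <- 0; okpath <- TRUE
        for (p in dpos[ord]) {
          nxt <- cur; nxt[p] <- cj[p]
          aa1 <- gc[paste(cur, collapse = "")]
          aa2 <- gc[paste(nxt, collapse = "")]
          if (aa2 == "*") { okpath <- FALSE; break }
          if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        if (okpath) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
                      nvalid <- nvalid + 1L }
      }
      if (nvalid > 0L) { Sd[i, j] <- sd_tot / nvalid; Nd[i, j] <- nd_tot / nvalid }
    }
  }
  the$ng86 <- list(codons = codons, syn_sites = syn_sites, Sd = Sd, Nd = Nd)
  the$ng86
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Nei-Gojobori dS/dN between two in-frame coding sequences
#'
#' Codons containing a gap or `N` in either sequence are skipped pairwise;
#' internal stop codons are an error. The Jukes-Cantor correction is `NA`
#' (with a warning) when the proportion of differences reaches 3/4.
#'
#' @param seq1,seq2 In-frame nucleotide strings of equal length (multiple
#'   of 3).
#' @param quiet Suppress the blocked-codon and saturation warnings.
#' @return A list of class `ng86_pair`: `syn_sites` (pair-averaged S-bar),
#'   `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `pS`, `pN`, `dS`, `dN`,
#'   `n_codons` (compared codons).
#' @export
ng86_pairwise <- function(seq1, seq2, quiet = FALSE) {
  if (nchar(seq1) != nchar(seq2))
    stop("sequences differ in length: ", nchar(seq1), " vs ", nchar(seq2))
  tb <- ng86_tables()
  gc <- genetic_code()
  c1 <- split_codons(toupper(seq1))
  c2 <- split_codons(toupper(seq2))
  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  stops1 <- which(clean & gc[c1] == "*")
  if (length(stops1))
    stop("stop codon in seq1 at codon position ", stops1[1])
  stops2 <- which(clean & gc[c2] == "*")
  if (length(stops2))
    stop("stop codon in seq2 at codon position ", stops2[1])
  i1 <- match(c1[clean], tb$codons)
  i2 <- match(c2[clean], tb$codons)
  sd <- tb$Sd[cbind(i1, i2)]
  nd <- tb$Nd[cbind(i1, i2)]
  blocked <- is.na(sd)
  if (any(blocked) && !quiet)
    warning(sum(blocked), " codon pair(s) skipped: all mutational paths",
            " pass through a stop codon")
  keep <- !blocked
  n_codons <- sum(keep)
  if (n_codons == 0L)
    return(structure(list(syn_sites = 0, nonsyn_sites = 0, syn_diffs = 0,
                          nonsyn_diffs = 0, pS = NA_real_, pN = NA_real_,
                          dS = NA_real_, dN = NA_real_, n_codons = 0L),
                     class = "ng86_pair"))
  S_bar <- (sum(tb$syn_sites[i1[keep]]) + sum(tb$syn_sites[i2[keep]])) / 2
  N_bar <- 3 * n_codons - S_bar
  Sd_tot <- sum(sd[keep])
  Nd_tot <- sum(nd[keep])
  pS <- if (S_bar > 0) Sd_tot / S_bar else NA_real_
  pN <- if (N_bar > 0) Nd_tot / N_bar else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  if (!quiet && ((!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)))
    warning("proportion of differences >= 3/4: Jukes-Cantor correction undefined")
  structure(list(syn_sites = S_bar, nonsyn_sites = N_bar, syn_diffs = Sd_tot,
                 nonsyn_diffs = Nd_tot, pS = pS, pN = pN, dS = dS, dN = dN,
                 n_codons = n_codons),
            class = "ng86_pair")
}

#' @export
print.ng86_pair <- function(x, ...) {
  cat(sprintf(paste0("<ng86_pair> %d codons: S=%.3f N=%.3f Sd=%.3f Nd=%.3f",
                     "  dS=%s dN=%s\n"),
              x$n_codons, x$syn_sites, x$nonsyn_sites, x$syn_diffs,
              x$nonsyn_diffs, format(x$dS, digits = 4),
              format(x$dN, digits = 4)))
  invisible(x)
}
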