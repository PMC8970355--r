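# Pheromone-precursor detection near STE3 pheromone-receptor genes.
#
# Precursors are short ORFs whose peptide carries a C-terminal prenylation
# signal: CaaX (C, two aliphatic residues, any residue) or the CpaX
# variant with a polar residue (threonine by default) at position 2. The
# active pheromone is released by cleavage after the R of the rightmost
# ER/DR maturation dipeptide and runs to the motif cysteine inclusive.

ALIPHATIC <- c("A", "V", "L", "I")

#' Find short open reading frames on both strands
#'
#' All ATG-to-stop ORFs under the standard genetic code whose length,
#' including the stop codon, lies within `[min_bp, max_bp]`. Nested ORFs
#' (in-frame internal ATGs) are reported independently. Coordinates are
#' 1-based inclusive on the forward axis; minus-strand ORFs carry
#' `strand = "-"`.
#'
#' @param contig_seq DNA string (A/C/G/T/N).
#' @param min_bp,max_bp Inclusive ORF length bounds in bp.
#' @return data.frame with `start`, `end`, `strand`, `orf_len_bp`,
#'   `peptide` (without the stop).
#' @export
find_orfs <- function(contig_seq, min_bp = 100L, max_bp = 200L) {
  contig_seq <- toupper(contig_seq)
  if (grepl("[^ACGTN]", contig_seq)) stop("non-DNA characters in contig")
  gc <- genetic_code()
  Lc <- nchar(contig_seq)
  scan_strand <- function(s, strand) {
    out <- list()
    for (frame in 0:2) {
      starts <- seq(1L + frame, nchar(s) - 2L, by = 3L)
      if (!length(starts)) next
      cods <- substring(s, starts, starts + 2L)
      aa <- gc[cods]
      aa[is.na(aa)] <- "X"
      stop_idx <- which(aa == "*")
      atg_idx <- which(cods == "ATG")
      prev_stop <- 0L
      for (si in stop_idx) {
        atgs <- atg_idx[atg_idx > prev_stop & atg_idx < si]
        for (ai in atgs) {
          len_bp <- (si - ai + 1L) * 3L
          if (len_bp < min_bp || len_bp > max_bp) next
          s1 <- starts[ai]
          e1 <- starts[si] + 2L
          pep <- paste(aa[ai:(si - 1L)], collapse = "")
          if (strand == "+") {
            out[[length(out) + 1L]] <- data.frame(
              start = s1, end = e1, strand = "+", orf_len_bp = len_bp,
              peptide = pep, stringsAsFactors = FALSE)
          } else {
            out[[length(out) + 1L]] <- data.frame(
              start = Lc - e1 + 1L, end = Lc - s1 + 1L, strand = "-",
              orf_len_bp = len_bp, peptide = pep, stringsAsFactors = FALSE)
          }
        }
        prev_stop <- si
      }
    }
    out
  }
  hits <- c(scan_strand(contig_seq, "+"), scan_strand(revcomp(contig_seq), "-"))
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      orf_len_bp = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

#' Scan a peptide for the CaaX/CpaX prenylation motif and maturation site
#'
#' The last four residues are tested: position 1 must be C; positions 2-3
#' both aliphatic (`A`, `V`, `L`, `I`) give CaaX; otherwise a polar residue
#' (default set `{T}`) at position 2 with an aliphatic position 3 gives
#' CpaX. The maturation site is the rightmost ER or DR dipeptide strictly
#' upstream of the motif cysteine; the mature peptide runs from the
#' residue after that R through the motif C inclusive.
#'
#' @param peptide Amino-acid string (no stop).
#' @param polar_set Residues accepted at motif position 2 for CpaX.
#' @return List: `motif_kind` (`"CaaX"`, `"CpaX"` or `"none"`),
#'   `motif_residues`, `maturation` (`"ER"`, `"DR"` or `"none"`),
#'   `maturation_pos` (position of the dipeptide's first residue, or NA),
#'   `mature_peptide`, `mature_len`.
#' @export
scan_precursor <- function(peptide, polar_set = "T") {
  peptide <- toupper(peptide)
  n <- nchar(peptide)
  none <- list(motif_kind = "none", motif_residues = NA_character_,
               maturation = "none", maturation_pos = NA_integer_,
               mature_peptide = NA_character_, mature_len = NA_integer_)
  if (n < 6L) return(none)
  last4 <- strsplit(substr(peptide, n - 3L, n), "")[[1]]
  kind <- if (last4[1] != "C") "none"
  else if (last4[2] %in% ALIPHATIC && last4[3] %in% ALIPHATIC) "CaaX"
  else if (last4[2] %in% polar_set && last4[3] %in% ALIPHATIC) "CpaX"
  else "none"
  if (kind == "none") return(none)
  c_pos <- n - 3L
  res <- strsplit(peptide, "")[[1]]
  mat_pos <- NA_integer_
  mat_kind <- "none"
  for (p in seq_len(c_pos - 2L)) {  # dipeptide strictly upstream of the C
    dp <- paste0(res[p], res[p + 1L])
    if (dp %in% c("ER", "DR")) { mat_pos <- p; mat_kind <- dp }
  }
  mature <- if (!is.na(mat_pos)) substr(peptide, mat_pos + 2L, c_pos)
  else NA_character_
  list(motif_kind = kind,
       motif_residues = paste(last4, collapse = ""),
       maturation = mat_kind, maturation_pos = mat_pos,
       mature_peptide = mature,
       mature_len = if (is.na(mature)) NA_integer_ else nchar(mature))
}

interval_gap <- function(s1, e1, s2, e2) {
  if (e1 < s2) s2 - e1 - 1L else if (e2 < s1) s1 - e2 - 1L else 0L
}

#' Apply the STE3-proximity filter and produce verdicts
#'
#' Distance is the minimum gap in bp between the ORF interval and any STE3
#' feature interval on the same contig (0 if overlapping). A hit is
#' accepted iff the distance is at most `max_dist_bp` and a CaaX/CpaX
#' motif is present (the length filter was already enforced by
#' [find_orfs()]). Mature peptides outside 8-15 aa are accepted with a
#' warning flag, not rejected. If the contig carries no STE3 feature all
#' hits are rejected on distance, with a warning.
#'
#' @param hits data.frame of annotated ORFs (from the scanner).
#' @param ste3_features Feature data.frame (see [read_features()]) whose
#'   `kind == "STE3"` rows are used.
#' @param max_dist_bp Maximum ORF-to-STE3 gap in bp.
#' @param contig_name Contig the hits live on.
#' @return `hits` with `nearest_ste3_id`, `distance_bp`, `mature_len_warn`
#'   and `verdict` columns filled.
#' @export
proximity_filter <- function(hits, ste3_features, max_dist_bp = 5000L,
                             contig_name = NULL) {
  ste3 <- ste3_features[ste3_features$kind == "STE3", , drop = FALSE]
  if (!is.null(contig_name))
    ste3 <- ste3[ste3$contig == contig_name, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  if (!nrow(ste3)) {
    warning("no STE3 features on contig: all hits rejected on distance")
    hits$nearest_ste3_id <- NA_character_
    hits$distance_bp <- NA_integer_
    hits$verdict <- "rejected(distance)"
    return(hits)
  }
  for (i in seq_len(nrow(hits))) {
    gaps <- vapply(seq_len(nrow(ste3)), function(j)
      interval_gap(hits$start[i], hits$end[i], ste3$start[j], ste3$end[j]),
      integer(1))
    k <- which.min(gaps)
    hits$nearest_ste3_id[i] <- ste3$feature_id[k]
    hits$distance_bp[i] <- gaps[k]
    hits$verdict[i] <- if (hits$motif_kind[i] == "none") "rejected(motif)"
    else if (gaps[k] > max_dist_bp) "rejected(distance)"
    else "accepted"
    hits$mature_len_warn[i] <- hits$verdict[i] == "accepted" &&
      (is.na(hits$mature_len[i]) || hits$mature_len[i] < 8L ||
         hits$mature_len[i] > 15L)
  }
  hits
}

#' Scan a contig for pheromone-precursor ORFs near STE3 genes
#'
#' Pipeline: [find_orfs()] (length filter), [scan_precursor()] (motif and
#' maturation), [proximity_filter()] (STE3 distance). Output rows are
#' sorted by (start, end, strand) and are strand-symmetric: scanning the
#' reverse complement with mirrored features yields the same accepted set
#' with mirrored coordinates.
#'
#' @param contig_seq DNA string.
#' @param ste3_features Feature data.frame with `kind == "STE3"` rows.
#' @param min_bp,max_bp ORF length bounds (bp, including the stop codon).
#' @param max_dist_bp Maximum gap to the nearest STE3.
#' @param polar_set CpaX position-2 residue set.
#' @param contig_name Contig id used to select features and label output.
#' @return data.frame of candidate hits with motif annotation, nearest
#'   STE3, distance and verdict.
#' @export
scan_pheromones <- function(contig_seq, ste3_features, min_bp = 100L,
                            max_bp = 200L, max_dist_bp = 5000L,
                            polar_set = "T", contig_name = "contig_1") {
  orfs <- find_orfs(contig_seq, min_bp, max_bp)
  if (!nrow(orfs))
    return(data.frame(contig = character(), orf_start = integer(),
                      orf_end = integer(), strand = character(),
                      orf_len_bp = integer(), peptide = character(),
                      motif_kind = character(), motif_residues = character(),
                      maturation = character(), mature_peptide = character(),
                      mature_len = integer(), nearest_ste3_id = character(),
                      distance_bp = integer(), mature_len_warn = logical(),
                      verdict = character(), stringsAsFactors = FALSE))
  ann <- lapply(orfs$peptide, scan_precursor, polar_set = polar_set)
  hits <- data.frame(
    contig = contig_name,
    orf_start = orfs$start, orf_end = orfs$end, strand = orfs$strand,
    orf_len_bp = orfs$orf_len_bp, peptide = orfs$peptide,
    motif_kind = vapply(ann, `[[`, character(1), "motif_kind"),
    motif_residues = vapply(ann, `[[`, character(1), "motif_residues"),
    maturation = vapply(ann, `[[`, character(1), "maturation"),
    mature_peptide = vapply(ann, `[[`, character(1), "mature_peptide"),
    mature_len = vapply(ann, `[[`, integer(1), "mature_len"),
    nearest_ste3_id = NA_character_, distance_bp = NA_integer_,
    mature_len_warn = NA, verdict = NA_character_,
    stringsAsFactors = FALSE)
  names(hits)[names(hits) == "orf_start"] <- "orf_start"
  hits2 <- hits
  names(hits2)[names(hits2) %in% c("orf_start", "orf_end")] <- c("start", "end")
  hits2 <- proximity_filter(hits2, ste3_features, max_dist_bp, contig_name)
  names(hits2)[names(hits2) %in% c("start", "end")] <- c("orf_start", "orf_end")
  hits2[order(hits2$contig, hits2$orf_start, hits2$strand), , drop = FALSE]
}
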