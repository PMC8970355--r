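# Small shared utilities: genetic code access, translation, adjusted Rand.

the <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(the$gc)) {
    gc <- Biostrings::GENETIC_CODE
    the$gc <- stats::setNames(as.character(gc), names(gc))
  }
  the$gc
}

stop_codons <- function() names(genetic_code())[genetic_code() == "*"]

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# translate a gap-free in-frame DNA string; codons with N/- become X
translate_cds <- function(seq) {
  gc <- genetic_code()
  cods <- split_codons(seq)
  aa <- gc[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 means the two partitions agree up to
#' label permutation, 0 is the chance-level expectation.
#'
#' @param a,b Vectors of class labels over the same items (same length).
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)  # both partitions trivial
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
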