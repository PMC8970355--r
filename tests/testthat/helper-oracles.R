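# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately avoid the package's own code paths: distances come
# from ape::dist.dna, Tajima's D is a second transcription of the published
# formulas, NG86 counts come from direct path enumeration, connected
# components from igraph, ARI from mclust.

make_aln <- function(seqs, species = NULL, gene_id = "g", alphabet = "dna") {
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%02d", seq_along(seqs))
  if (is.null(species))
    species <- stats::setNames(rep("speciesA", length(seqs)), names(seqs))
  species_alignment(gene_id, seqs, species, alphabet)
}

random_aln <- function(n, L, miss_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(chars, L, replace = TRUE)
    if (miss_prob > 0) {
      k <- which(stats::runif(L) < miss_prob)
      s[k] <- sample(c("-", "N"), length(k), replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%02d", seq_len(n))
  seqs
}

# --- pi / dxy oracle via ape -------------------------------------------------

ape_pdist <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(tolower(seqs)), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m[m == "-"] <- "n"   # dist.dna treats n as missing under pairwise deletion
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "raw", pairwise.deletion = TRUE)
  as.matrix(d)
}

oracle_pi <- function(seqs) {
  d <- ape_pdist(seqs)
  mean(d[upper.tri(d)])
}

oracle_dxy <- function(seqs_A, seqs_B) {
  d <- ape_pdist(c(seqs_A, seqs_B))
  mean(d[names(seqs_A), names(seqs_B)])
}

# --- Tajima's D oracle: independent transcription of Tajima (1989) ----------

oracle_tajima <- function(S, khat, n) {
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1^2)
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- NG86 oracle: direct enumeration, no lookup tables ----------------------

oracle_ng86 <- function(seq1, seq2) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  syn_sites_codon <- function(cod) {
    cv <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) for (b in setdiff(bases, cv[p])) {
      nb <- cv; nb[p] <- b
      if (gc[[paste(nb, collapse = "")]] == gc[[cod]]) s <- s + 1 / 3
    }
    s
  }
  # recursive path enumeration between two codons
  paths <- function(from, to) {
    dpos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(dpos)) return(list(list(sd = 0, nd = 0)))
    res <- list()
    for (p in dpos) {
      nxt <- strsplit(from, "")[[1]]
      nxt[p] <- strsplit(to, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      if (gc[[nxt]] == "*") next
      step_syn <- gc[[from]] == gc[[nxt]]
      for (tail in paths(nxt, to))
        res[[length(res) + 1L]] <- list(sd = tail$sd + as.numeric(step_syn),
                                        nd = tail$nd + as.numeric(!step_syn))
    }
    res
  }
  c1 <- split3(seq1); c2 <- split3(seq2)
  Sbar <- 0; Sd <- 0; Nd <- 0; ncod <- 0
  for (i in seq_along(c1)) {
    if (grepl("[^ACGT]", c1[i]) || grepl("[^ACGT]", c2[i])) next
    pp <- paths(c1[i], c2[i])
    if (!length(pp)) next
    ncod <- ncod + 1
    Sbar <- Sbar + (syn_sites_codon(c1[i]) + syn_sites_codon(c2[i])) / 2
    Sd <- Sd + mean(vapply(pp, `[[`, numeric(1), "sd"))
    Nd <- Nd + mean(vapply(pp, `[[`, numeric(1), "nd"))
  }
  Nbar <- 3 * ncod - Sbar
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Sbar = Sbar, Nbar = Nbar, Sd = Sd, Nd = Nd,
       dS = jc(if (Sbar > 0) Sd / Sbar else NA_real_),
       dN = jc(if (Nbar > 0) Nd / Nbar else NA_real_))
}

random_cds_pair <- function(ncod, ndiff, seed) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  c1 <- sample(sense, ncod, replace = TRUE)
  c2 <- c1
  for (i in sample(ncod, min(ndiff, ncod))) c2[i] <- sample(sense, 1)
  list(s1 = paste(c1, collapse = ""), s2 = paste(c2, collapse = ""))
}

# --- HKA T oracle: dense grid minimizer of |g(T)| ---------------------------

oracle_hka_T <- function(inputs, grid = seq(0, 50, by = 1e-3)) {
  a_n <- vapply(inputs$nsam, function(n) sum(1 / (1:(n - 1))), numeric(1))
  g <- vapply(grid, function(Tt) {
    th <- (inputs$S + inputs$D) / (inputs$L_pol * a_n + inputs$L_div * (Tt + 1))
    abs(sum(th * inputs$L_div * (Tt + 1)) - sum(inputs$D))
  }, numeric(1))
  grid[which.min(g)]
}

# --- misc -------------------------------------------------------------------

sim_neutral_panel <- function(n_loci, seed, n_A = 10, n_B = 10, T_split = 10,
                              theta = 5, L = 500, mode = "nucleotide",
                              omega = 1) {
  genes <- list(); cats <- character()
  for (g in seq_len(n_loci)) {
    cfg <- sim_config(n_A = n_A, n_B = n_B, T_split = T_split, theta = theta,
                      L = L, mode = mode, omega = omega, seed = seed * 1000 + g)
    gid <- sprintf("g%02d", g)
    genes[[gid]] <- simulate_neutral_locus(cfg, gid)$alignment
    cats[gid] <- "background"
  }
  gene_panel(genes, cats)
}

translate_seqs <- function(aln) {
  vapply(aln$seqs, matloci:::translate_cds, character(1))
}
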