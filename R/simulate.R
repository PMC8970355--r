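# Synthetic-data generator: neutral two-species coalescent loci, balanced
# loci with k deep allelic lineages shared across species, and a planted
# pheromone-region fixture. Time is measured in units of 2N generations,
# so a pair of lineages in one population coalesces at rate 1 and mutations
# fall on a branch as Poisson(theta/2 * branch length), theta = 4*N*mu*L
# per locus. The model is finite-sites: a site can be hit repeatedly.

#' Simulation configuration
#'
#' @param n_A,n_B Samples per species.
#' @param T_split Species split time, units of 2N generations.
#' @param theta Per-locus population mutation rate 4*N*mu*L.
#' @param L Locus length in bp (multiple of 3 in codon mode).
#' @param mode `"nucleotide"` or `"codon"`. In codon mode a proposed change
#'   is always kept if synonymous, kept with probability `omega` if it
#'   changes the amino acid, and always rejected if it creates a stop.
#' @param omega Nonsynonymous retention probability in \[0, 1\].
#' @param k Number of balanced allelic lineages (balanced loci; >= 2).
#' @param d_bal Expected per-site divergence between lineage founders.
#' @param theta_within Per-locus theta for variation within one lineage.
#' @param seed Optional integer seed; identical seeds give identical loci.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_A = 10L, n_B = 10L, T_split = 5, theta = 5, L = 300L,
                       mode = c("nucleotide", "codon"), omega = 1,
                       k = 2L, d_bal = 0.3, theta_within = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_A >= 0L, n_B >= 0L, n_A + n_B >= 2L, T_split >= 0, theta >= 0,
            L >= 3L, omega >= 0, omega <= 1, k >= 2L, d_bal >= 0,
            theta_within >= 0)
  if (mode == "codon" && L %% 3L != 0L)
    stop("codon mode requires L to be a multiple of 3")
  structure(list(n_A = as.integer(n_A), n_B = as.integer(n_B),
                 T_split = T_split, theta = theta, L = as.integer(L),
                 mode = mode, omega = omega, k = as.integer(k),
                 d_bal = d_bal, theta_within = theta_within, seed = seed),
            class = "sim_config")
}

# ---- coalescent trees as parent/time tables --------------------------------

# Coalesce `active` node ids from time t0 until one lineage remains or t_end
# is reached. `st` is an environment holding parent, time, next_node.
coal_phase <- function(active, t0, t_end, st) {
  t <- t0
  while (length(active) > 1L) {
    j <- length(active)
    t_next <- t + stats::rexp(1L, rate = j * (j - 1) / 2)
    if (t_next > t_end) return(list(active = active, t = t_end))
    t <- t_next
    pair <- sample(active, 2L)
    node <- st$next_node
    st$next_node <- node + 1L
    st$parent[pair] <- node
    st$time[node] <- t
    active <- c(setdiff(active, pair), node)
  }
  list(active = active, t = t)
}

# Two-species coalescent: Kingman within each species until T_split, then
# lineages merge into the ancestral population.
coal_two_species <- function(n_A, n_B, T_split, labels) {
  n <- n_A + n_B
  st <- new.env()
  st$parent <- rep(NA_integer_, 2L * n - 1L)
  st$time <- numeric(2L * n - 1L)
  st$next_node <- n + 1L
  a <- coal_phase(seq_len(n_A), 0, T_split, st)
  b <- coal_phase(if (n_B > 0L) n_A + seq_len(n_B) else integer(), 0, T_split, st)
  anc <- coal_phase(c(a$active, b$active), T_split, Inf, st)
  root <- anc$active
  list(parent = st$parent[seq_len(st$next_node - 1L)],
       time = st$time[seq_len(st$next_node - 1L)],
       ntip = n, root = root, labels = labels)
}

coal_single <- function(n, labels) coal_two_species(n, 0L, 0, labels)

tree_newick <- function(tree, digits = 8) {
  kids <- split(seq_along(tree$parent)[!is.na(tree$parent)],
                tree$parent[!is.na(tree$parent)])
  rec <- function(node) {
    if (node <= tree$ntip) return(tree$labels[node])
    ch <- kids[[as.character(node)]]
    parts <- vapply(ch, function(c2) {
      paste0(rec(c2), ":", format(tree$time[node] - tree$time[c2],
                                  digits = digits, scientific = FALSE))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(tree$root), ";")
}

# ---- mutation machinery -----------------------------------------------------

random_dna <- function(L) sample(c("A", "C", "G", "T"), L, replace = TRUE)

# random stop-free in-frame coding sequence, as a base vector
random_cds <- function(L) {
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  cods <- sample(sense, L %/% 3L, replace = TRUE)
  strsplit(paste(cods, collapse = ""), "", fixed = TRUE)[[1]]
}

# apply n point mutations to base vector x; codon mode does omega thinning
# and rejects stop-creating changes outright
apply_mutations <- function(x, nmut, mode, omega) {
  if (nmut == 0L) return(x)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  L <- length(x)
  for (i in seq_len(nmut)) {
    site <- sample.int(L, 1L)
    new <- sample(setdiff(bases, x[site]), 1L)
    if (mode == "codon") {
      c0 <- (site - 1L) %/% 3L
      idx <- c0 * 3L + 1:3
      cod <- x[idx]
      newcod <- cod
      newcod[site - c0 * 3L] <- new
      aa_old <- gc[paste(cod, collapse = "")]
      aa_new <- gc[paste(newcod, collapse = "")]
      if (aa_new == "*") next
      if (aa_new != aa_old && omega < 1 && stats::runif(1) > omega) next
    }
    x[site] <- new
  }
  x
}

# drop sequences down a coalescent tree; returns ntip x L character matrix
evolve_on_tree <- function(tree, root_seq, theta, mode, omega) {
  L <- length(root_seq)
  nnode <- length(tree$parent)
  seqs <- vector("list", nnode)
  seqs[[tree$root]] <- root_seq
  ord <- order(tree$time[seq_len(nnode)], decreasing = TRUE)  # preorder by age
  for (node in ord) {
    if (node == tree$root) next
    par <- tree$parent[node]
    blen <- tree$time[par] - tree$time[node]
    nmut <- stats::rpois(1L, theta / 2 * blen)
    seqs[[node]] <- apply_mutations(seqs[[par]], nmut, mode, omega)
  }
  m <- do.call(rbind, seqs[seq_len(tree$ntip)])
  rownames(m) <- tree$labels
  m
}

sim_strain_labels <- function(cfg) {
  c(sprintf("A%02d", seq_len(cfg$n_A)), sprintf("B%02d", seq_len(cfg$n_B)))
}

sim_species_map <- function(cfg) {
  labs <- sim_strain_labels(cfg)
  stats::setNames(rep(c("speciesA", "speciesB"), c(cfg$n_A, cfg$n_B)), labs)
}

# ---- neutral locus ----------------------------------------------------------

#' Simulate a neutral locus under a two-species split
#'
#' Kingman coalescent within each species until `T_split`, after which the
#' surviving lineages coalesce in a single ancestral population. Mutations
#' are Poisson on branches; with `T_split = 0` this is a single panmictic
#' population. Expected per-site diversity within a species is `theta / L`
#' and expected cross-species divergence is `theta * (T_split + 1) / L`.
#'
#' @param cfg A [sim_config()].
#' @param gene_id Identifier stored on the alignment.
#' @return A list of class `simulated_locus` with fields `alignment`
#'   ([species_alignment()]), `genealogy` (Newick text), `truth_class_of`
#'   (`NULL` for neutral loci) and `is_balanced`.
#' @export
simulate_neutral_locus <- function(cfg, gene_id = "locus") {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  labs <- sim_strain_labels(cfg)
  tree <- coal_two_species(cfg$n_A, cfg$n_B, cfg$T_split, labs)
  root_seq <- if (cfg$mode == "codon") random_cds(cfg$L) else random_dna(cfg$L)
  m <- evolve_on_tree(tree, root_seq, cfg$theta, cfg$mode, cfg$omega)
  seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
  aln <- species_alignment(gene_id, seqs, sim_species_map(cfg), "dna")
  structure(list(alignment = aln, genealogy = tree_newick(tree),
                 truth_class_of = NULL, is_balanced = FALSE),
            class = "simulated_locus")
}

# ---- balanced locus ---------------------------------------------------------

# founder = ancestor with Binomial(L, d_bal) substitutions at distinct sites
make_founder <- function(anc, d_bal, mode, omega) {
  L <- length(anc)
  nsub <- stats::rbinom(1L, L, d_bal)
  if (nsub == 0L) return(anc)
  sites <- sample.int(L, nsub)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  x <- anc
  for (site in sites) {
    new <- sample(setdiff(bases, x[site]), 1L)
    if (mode == "codon") {
      c0 <- (site - 1L) %/% 3L
      idx <- c0 * 3L + 1:3
      newcod <- x[idx]
      newcod[site - c0 * 3L] <- new
      aa_old <- gc[paste(x[idx], collapse = "")]
      aa_new <- gc[paste(newcod, collapse = "")]
      if (aa_new == "*") next
      if (aa_new != aa_old && omega < 1 && stats::runif(1) > omega) next
    }
    x[site] <- new
  }
  x
}

#' Simulate a locus under long-term balancing selection
#'
#' `k` deep allelic lineages predate the species split: founder sequences
#' diverge from a common ancestor by `d_bal` per site, every strain of both
#' species draws a lineage uniformly at random, and within-lineage variation
#' is added by a neutral coalescent with `theta_within`, ignoring species
#' labels. The genealogy is a star of lineage subtrees with stem length
#' proportional to `d_bal` (an approximation of the structured coalescent
#' that is adequate for the targeted signatures: pi close to dxy, low Fst,
#' positive Tajima's D, species non-monophyly).
#'
#' @inheritParams simulate_neutral_locus
#' @return A `simulated_locus`; `truth_class_of` maps each strain to its
#'   lineage id.
#' @export
simulate_balanced_locus <- function(cfg, gene_id = "locus") {
  stopifnot(cfg$k >= 2L, cfg$d_bal >= 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  labs <- sim_strain_labels(cfg)
  n <- length(labs)
  if (cfg$k > n)
    warning("k = ", cfg$k, " lineages but only ", n,
            " strains: some lineages will be unsampled")
  lineage <- sample.int(cfg$k, n, replace = TRUE)
  names(lineage) <- labs
  anc <- if (cfg$mode == "codon") random_cds(cfg$L) else random_dna(cfg$L)
  seqs <- character(0)
  sub_newicks <- character(0)
  for (lin in sort(unique(lineage))) {
    members <- labs[lineage == lin]
    founder <- make_founder(anc, cfg$d_bal, cfg$mode, cfg$omega)
    if (length(members) == 1L) {
      seqs[members] <- paste(founder, collapse = "")
      sub_newicks <- c(sub_newicks, members)
    } else {
      tr <- coal_single(length(members), members)
      m <- evolve_on_tree(tr, founder, cfg$theta_within, cfg$mode, cfg$omega)
      seqs[rownames(m)] <- apply(m, 1L, paste, collapse = "")
      nwk <- sub(";$", "", tree_newick(tr))
      sub_newicks <- c(sub_newicks, nwk)
    }
  }
  seqs <- seqs[labs]
  stem <- max(cfg$d_bal, 1e-8)
  genealogy <- paste0("(", paste0(sub_newicks, ":", format(stem, scientific = FALSE),
                                  collapse = ","), ");")
  aln <- species_alignment(gene_id, seqs, sim_species_map(cfg), "dna")
  structure(list(alignment = aln, genealogy = genealogy,
                 truth_class_of = lineage, is_balanced = TRUE),
            class = "simulated_locus")
}

# ---- panels -----------------------------------------------------------------

#' Simulate a gene panel of neutral background and balanced mating loci
#'
#' Per-gene seeds are derived from the master seed (`seed + gene index`) so
#' the panel is reproducible gene by gene.
#'
#' @param n_neutral,n_balanced Number of neutral (category `background`)
#'   and balanced (category `mating`) genes.
#' @param cfg_neutral,cfg_balanced [sim_config()]s for the two locus kinds;
#'   their `seed` fields are overridden by the derived per-gene seeds.
#' @param seed Master integer seed.
#' @return A list with `panel` (a [gene_panel()] whose `tree_of` holds the
#'   true genealogies), `truth` (data.frame gene_id, category, is_balanced)
#'   and `class_truth` (named list gene_id -> strain lineage ids for
#'   balanced genes).
#' @export
simulate_panel <- function(n_neutral, n_balanced, cfg_neutral = sim_config(),
                           cfg_balanced = sim_config(mode = "codon"),
                           seed = 1L) {
  if (n_neutral + n_balanced == 0L) stop("empty panel requested")
  genes <- list()
  trees <- character()
  class_truth <- list()
  idx <- 0L
  truth <- data.frame(gene_id = character(), category = character(),
                      is_balanced = logical(), stringsAsFactors = FALSE)
  for (i in seq_len(n_neutral)) {
    idx <- idx + 1L
    gid <- sprintf("bg_%03d", i)
    cfg <- cfg_neutral
    cfg$seed <- seed + idx
    loc <- simulate_neutral_locus(cfg, gid)
    genes[[gid]] <- loc$alignment
    trees[[gid]] <- loc$genealogy
    truth <- rbind(truth, data.frame(gene_id = gid, category = "background",
                                     is_balanced = FALSE))
  }
  for (i in seq_len(n_balanced)) {
    idx <- idx + 1L
    gid <- sprintf("mat_%02d", i)
    cfg <- cfg_balanced
    cfg$seed <- seed + idx
    loc <- simulate_balanced_locus(cfg, gid)
    genes[[gid]] <- loc$alignment
    trees[[gid]] <- loc$genealogy
    class_truth[[gid]] <- loc$truth_class_of
    truth <- rbind(truth, data.frame(gene_id = gid, category = "mating",
                                     is_balanced = TRUE))
  }
  cat_of <- stats::setNames(truth$category, truth$gene_id)
  list(panel = gene_panel(genes, cat_of, trees), truth = truth,
       class_truth = class_truth)
}

# ---- pheromone-region fixture ----------------------------------------------

aa_codon <- function(aa) {
  gc <- genetic_code()
  vapply(aa, function(a) sample(names(gc)[gc == a], 1L), character(1))
}

# build precursor ORF DNA (incl. TAA stop): M D ... [E/D]R ...9aa... C a a X
# filler avoids M (no nested in-frame starts) and R (unique maturation site)
precursor_orf_dna <- function(orf_bp, motif = c("CVIA", "CTIS"),
                              maturation = c("ER", "DR")) {
  motif <- match.arg(motif)
  maturation <- match.arg(maturation)
  n_aa <- orf_bp %/% 3L - 1L  # minus stop codon
  stopifnot(n_aa >= 16L)
  filler_pool <- c("G", "S", "T", "A", "V", "L", "I", "P", "F", "N", "Q",
                   "H", "K", "W", "Y")
  head_len <- n_aa - 4L - 9L - 2L - 2L  # M D [head] mat(2) mid(9) motif(4)
  pep <- c("M", "D", sample(filler_pool, head_len, replace = TRUE),
           strsplit(maturation, "")[[1]],
           sample(filler_pool, 9L, replace = TRUE),
           strsplit(motif, "")[[1]])
  paste0(paste(aa_codon(pep), collapse = ""), "TAA")
}

# plain ORF of orf_bp with no CaaX/CpaX terminus
plain_orf_dna <- function(orf_bp) {
  n_aa <- orf_bp %/% 3L - 1L
  filler_pool <- c("G", "S", "P", "F", "N", "Q", "H", "K", "W", "Y")
  pep <- c("M", sample(filler_pool, n_aa - 5L, replace = TRUE), "C", "G", "G", "S")
  paste0(paste(aa_codon(pep), collapse = ""), "TAA")
}

insert_at <- function(contig, start, dna) {
  substr(contig, start, start + nchar(dna) - 1L) <- dna
  contig
}

#' Plant a pheromone-region fixture with known ground truth
#'
#' Builds a ~50 kb random contig carrying two STE3 placeholder features,
#' two true pheromone-precursor ORFs (one canonical CaaX, one CpaX, on
#' opposite strands, within 5 kb of an STE3) and four decoys that each
#' violate exactly one scanner filter (too short, too long, too distant,
#' no motif). The generator guarantees by construction that the scanner's
#' accepted set equals the planted truth: if a random background ORF
#' happens to pass all filters the background is resampled (deterministic
#' sub-seeds derived from `seed`).
#'
#' @param seed Integer seed.
#' @param contig_len Contig length in bp.
#' @return A list with `contig` (DNA string), `features` (STE3 feature
#'   data.frame as in [read_features()]) and `truth` (data.frame of planted
#'   ORFs with coordinates, strand, class and expected verdict).
#' @export
plant_pheromone_fixture <- function(seed = 1L, contig_len = 50000L) {
  features <- data.frame(
    contig = "contig_1",
    start = c(10000L, 30000L), end = c(11200L, 31300L),
    strand = c("+", "-"),
    feature_id = c("STE3.2", "STE3.4"),
    kind = "STE3", stringsAsFactors = FALSE)
  plants <- list(
    list(id = "true_caax", start = 13200L, bp = 150L, strand = "+",
         kind = "precursor", motif = "CVIA", maturation = "ER",
         verdict = "accepted"),
    list(id = "true_cpax", start = 27400L, bp = 162L, strand = "-",
         kind = "precursor", motif = "CTIS", maturation = "DR",
         verdict = "accepted"),
    list(id = "decoy_short", start = 14500L, bp = 90L, strand = "+",
         kind = "short", verdict = "rejected_length"),
    list(id = "decoy_long", start = 32500L, bp = 300L, strand = "+",
         kind = "long", verdict = "rejected_length"),
    list(id = "decoy_distant", start = 44000L, bp = 150L, strand = "+",
         kind = "precursor", motif = "CVIA", maturation = "ER",
         verdict = "rejected_distance"),
    list(id = "decoy_nomotif", start = 16000L, bp = 150L, strand = "+",
         kind = "plain", verdict = "rejected_motif"))
  for (attempt in 0:49) {
    set.seed(seed + attempt * 1000L)
    contig <- paste(random_dna(contig_len), collapse = "")
    truth <- data.frame(feature_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        class = character(), expected_verdict = character(),
                        stringsAsFactors = FALSE)
    for (p in plants) {
      dna <- switch(p$kind,
        precursor = precursor_orf_dna(p$bp, p$motif, p$maturation),
        short = {  # 90 bp, valid CaaX motif, fails only the length filter
          pep <- c("M", "D", sample(c("G","S","P","F","N","Q"), 17L, TRUE),
                   "E", "R", sample(c("G","S","P","F","N","Q"), 4L, TRUE),
                   "C", "V", "I", "A")
          paste0(paste(aa_codon(pep), collapse = ""), "TAA")
        },
        long = precursor_orf_dna(p$bp, "CVIA", "ER"),
        plain = plain_orf_dna(p$bp))
      if (p$strand == "-") dna <- revcomp(dna)
      contig <- insert_at(contig, p$start, dna)
      truth <- rbind(truth, data.frame(
        feature_id = p$id, start = p$start, end = p$start + p$bp - 1L,
        strand = p$strand, class = p$id,
        expected_verdict = p$verdict, stringsAsFactors = FALSE))
    }
    hits <- scan_pheromones(contig, features, contig_name = "contig_1")
    acc <- hits[hits$verdict == "accepted", c("orf_start", "orf_end", "strand")]
    want <- truth[truth$expected_verdict == "accepted",
                  c("start", "end", "strand")]
    key <- function(s, e, st) paste(s, e, st)
    if (setequal(key(acc$orf_start, acc$orf_end, acc$strand),
                 key(want$start, want$end, want$strand))) {
      return(list(contig = contig, features = features, truth = truth))
    }
  }
  stop("could not build a clean pheromone fixture")  # not reached in practice
}
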