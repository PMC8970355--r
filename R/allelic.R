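# Amino-acid identity matrices, allelic-class clustering at the 86% AAI
# threshold, NJ trees on AAI distances, clade concordance, and reciprocal
# monophyly.

#' Pairwise percent amino-acid identity matrix
#'
#' Identity between two aligned proteins is 100 x (columns with identical
#' non-gap residues) / (columns where at least one of the pair has a
#' non-gap residue): gap-vs-residue counts as a mismatch, gap-vs-gap
#' columns are excluded from the denominator.
#'
#' @param aln A protein [species_alignment()], or a named character vector
#'   of aligned protein sequences.
#' @return Symmetric matrix of percent identities (diagonal 100), class
#'   `aai_matrix`.
#' @export
pairwise_aai <- function(aln) {
  seqs <- if (inherits(aln, "species_alignment")) aln$seqs else aln
  if (!length(seqs)) stop("empty alignment")
  m <- do.call(rbind, strsplit(unname(toupper(seqs)), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    scored <- m[i, ] != "-" | m[j, ] != "-"
    if (!any(scored)) { out[i, j] <- out[j, i] <- NA_real_; next }
    match_ <- m[i, ] == m[j, ] & m[i, ] != "-"
    out[i, j] <- out[j, i] <- 100 * sum(match_ & scored) / sum(scored)
  }
  structure(out, class = c("aai_matrix", "matrix", "array"))
}

#' Allelic-class clustering at an AAI threshold
#'
#' Single-linkage: two strains belong to one allelic class iff they are
#' connected by a chain of pairs each with AAI >= `tau` (inclusive
#' boundary). Class labels are canonical: numbered by decreasing class
#' size, ties broken by the lexicographically smallest member, so the
#' output is invariant to input order.
#'
#' @param matrix An `aai_matrix` from [pairwise_aai()].
#' @param tau Identity threshold in percent, in (0, 100\].
#' @param linkage `"single"` (default, connected components of the
#'   thresholded graph) or `"average"` (UPGMA cut at 100 - tau).
#' @return A list of class `allelic_classification`: `class_of` (named
#'   integer vector), `n_classes`, `tau`, `linkage`.
#' @export
aai_cluster <- function(matrix, tau = 86.0, linkage = c("single", "average")) {
  linkage <- match.arg(linkage)
  if (tau <= 0 || tau > 100) stop("tau must be in (0, 100]")
  ids <- rownames(matrix)
  n <- length(ids)
  if (linkage == "single") {
    adj <- matrix >= tau
    adj[is.na(adj)] <- FALSE
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
      if (comp[s] != 0L) next
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  } else {
    hc <- stats::hclust(stats::as.dist(100 - matrix), method = "average")
    comp <- stats::cutree(hc, h = 100 - tau)
  }
  # canonical labels: by decreasing size, ties by smallest member id
  sizes <- table(comp)
  first_member <- vapply(names(sizes), function(cl)
    min(ids[comp == as.integer(cl)]), character(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  class_of <- stats::setNames(unname(relabel[as.character(comp)]), ids)
  structure(list(class_of = class_of, n_classes = length(sizes), tau = tau,
                 linkage = linkage),
            class = "allelic_classification")
}

#' @export
print.allelic_classification <- function(x, ...) {
  cat(sprintf("<allelic_classification> %d strains in %d class(es) at AAI >= %g%% (%s linkage)\n",
              length(x$class_of), x$n_classes, x$tau, x$linkage))
  invisible(x)
}

#' Neighbor-joining tree from an AAI matrix
#'
#' Saitou-Nei NJ (via [ape::nj()]) on the distance `d = (100 - AAI)/100`.
#'
#' @param matrix An `aai_matrix`.
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(matrix) {
  if (nrow(matrix) < 3L) stop("NJ needs at least 3 taxa")
  d <- (100 - unclass(matrix)) / 100
  ape::nj(stats::as.dist(d))
}

# tips descending from each internal node; every edge bipartition of the
# unrooted tree appears as some clade set of the stored (arbitrary-rooted)
# representation, or as its complement
node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  lapply(pp, function(idx) tree$tip.label[idx])
}

is_split <- function(tree, set) {
  tips <- tree$tip.label
  set <- intersect(set, tips)
  if (length(set) <= 1L || length(set) >= length(tips) - 1L) return(TRUE)
  sets <- node_tip_sets(tree)
  comp <- setdiff(tips, set)
  for (s in sets) {
    if (setequal(s, set) || setequal(s, comp)) return(TRUE)
  }
  FALSE
}

#' Concordance of allelic classes with a tree
#'
#' A class is concordant iff its strains form a clade on the tree under
#' some rooting, i.e. the strain set or its complement is a monophyletic
#' group of the unrooted tree. Singleton classes and classes covering all
#' but one tip are trivially concordant.
#'
#' @param classification An `allelic_classification` from [aai_cluster()].
#' @param tree An [ape::phylo] tree or Newick text covering exactly the
#'   classified strains.
#' @return Named logical vector, one flag per class label.
#' @export
clade_concordance <- function(classification, tree) {
  if (!inherits(tree, "phylo")) tree <- read_newick(tree)
  strains <- names(classification$class_of)
  extra <- setdiff(tree$tip.label, strains)
  miss <- setdiff(strains, tree$tip.label)
  if (length(extra) || length(miss))
    stop("tree/classification leaf mismatch; only in tree: ",
         paste(extra, collapse = ", "), "; only in classification: ",
         paste(miss, collapse = ", "))
  classes <- sort(unique(classification$class_of))
  out <- vapply(classes, function(cl) {
    is_split(tree, strains[classification$class_of == cl])
  }, logical(1))
  stats::setNames(out, classes)
}

#' Reciprocal monophyly of species on a gene tree
#'
#' With an outgroup, the tree is rooted on it and each species (the
#' outgroup's species excluded) is tested for monophyly of its tips. With
#' `outgroup = NULL` the unrooted criterion is used: a species is
#' monophyletic iff its tips form one side of a bipartition (a clade under
#' some rooting).
#'
#' @param tree [ape::phylo] or Newick text.
#' @param species_of Named character vector tip label -> species.
#' @param outgroup Optional tip label to root on.
#' @return List with `per_species` (named logical) and `overall` (all
#'   species monophyletic).
#' @export
reciprocal_monophyly <- function(tree, species_of, outgroup = NULL) {
  if (!inherits(tree, "phylo")) tree <- read_newick(tree)
  if (!is.null(outgroup)) {
    if (!(outgroup %in% tree$tip.label))
      stop("outgroup '", outgroup, "' not in tree")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    tree <- ape::drop.tip(tree, outgroup)
    species_of <- species_of[setdiff(names(species_of), outgroup)]
  }
  miss <- setdiff(tree$tip.label, names(species_of))
  if (length(miss)) stop("no species label for tip(s): ", paste(miss, collapse = ", "))
  species <- sort(unique(species_of[tree$tip.label]))
  per <- vapply(species, function(sp) {
    tips <- names(species_of)[species_of == sp]
    tips <- intersect(tips, tree$tip.label)
    if (length(tips) <= 1L) return(TRUE)
    if (is.null(outgroup)) is_split(tree, tips)
    else ape::is.monophyletic(tree, tips)
  }, logical(1))
  list(per_species = stats::setNames(per, species), overall = all(per))
}
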