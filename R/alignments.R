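# Shared in-memory data model: per-gene species alignments and gene panels.

DNA_RESIDUES <- c("A", "C", "G", "T", "N", "-")
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X", "-")

#' Construct a per-gene species alignment
#'
#' The unit all downstream statistics consume: one gene, aligned sequences
#' for strains of (usually) two sister species, plus a strain -> species map.
#'
#' @param gene_id Gene identifier.
#' @param seqs Named character vector of aligned sequences (names are strain
#'   ids). Sequences are uppercased; all must have equal length. The gap
#'   character is `-`; `N` (DNA) and `X` (protein) are treated as missing
#'   data by the statistics.
#' @param species_of Named character vector mapping every strain id in
#'   `seqs` to a species label.
#' @param alphabet `"dna"` or `"protein"`.
#' @return An object of class `species_alignment` with fields `gene_id`,
#'   `seqs`, `species_of`, `alphabet`, `length`.
#' @export
species_alignment <- function(gene_id, seqs, species_of, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) == 0L) stop("alignment for gene '", gene_id, "' is empty")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named by strain id")
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) stop("duplicate strain ids: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths for gene '", gene_id, "': ",
         paste(sprintf("%s=%d", names(seqs), lens), collapse = ", "))
  missing_sp <- setdiff(names(seqs), names(species_of))
  if (length(missing_sp))
    stop("no species label for strain(s): ", paste(missing_sp, collapse = ", "))
  allowed <- if (alphabet == "dna") DNA_RESIDUES else AA_RESIDUES
  for (id in names(seqs)) {
    res <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    bad <- which(!(res %in% allowed))
    if (length(bad))
      stop("illegal ", alphabet, " residue '", res[bad[1]], "' at position ",
           bad[1], " in strain '", id, "'")
  }
  structure(
    list(gene_id = gene_id, seqs = seqs,
         species_of = species_of[names(seqs)], alphabet = alphabet,
         length = unname(lens[1])),
    class = "species_alignment"
  )
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("<species_alignment> gene '%s': %d strains x %d columns (%s)\n",
              x$gene_id, length(x$seqs), x$length, x$alphabet))
  tab <- table(x$species_of)
  cat("  species:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
  invisible(x)
}

# strains x columns character matrix
aln_matrix <- function(aln, strains = NULL) {
  seqs <- if (is.null(strains)) aln$seqs else {
    miss <- setdiff(strains, names(aln$seqs))
    if (length(miss)) stop("strain(s) not in alignment: ", paste(miss, collapse = ", "))
    aln$seqs[strains]
  }
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

missing_chars <- function(alphabet) {
  if (alphabet == "dna") c("N", "-") else c("X", "-")
}

strains_of_species <- function(aln, species) {
  names(aln$species_of)[aln$species_of == species]
}

#' Construct a gene panel
#'
#' A collection of per-gene alignments with a gene category (mating,
#' flanking or background) and optional per-gene Newick trees.
#'
#' @param genes Named list of [species_alignment()] objects (names are
#'   gene ids).
#' @param category_of Named character vector gene id -> one of `"mating"`,
#'   `"flanking"`, `"background"`; required for every gene.
#' @param tree_of Optional named character vector gene id -> Newick text;
#'   its names must be a subset of the gene ids.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(genes, category_of, tree_of = NULL) {
  if (is.null(names(genes)) || any(names(genes) == ""))
    stop("genes must be a named list")
  miss <- setdiff(names(genes), names(category_of))
  if (length(miss)) stop("missing category for gene(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(category_of[names(genes)]), c("mating", "flanking", "background"))
  if (length(bad)) stop("unknown gene category: ", paste(bad, collapse = ", "))
  if (!is.null(tree_of)) {
    extra <- setdiff(names(tree_of), names(genes))
    if (length(extra)) stop("tree for unknown gene(s): ", paste(extra, collapse = ", "))
  }
  structure(list(genes = genes, category_of = category_of[names(genes)],
                 tree_of = tree_of),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  tab <- table(x$category_of)
  cat(sprintf("<gene_panel> %d genes (%s); %d with trees\n", length(x$genes),
              paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "),
              length(x$tree_of)))
  invisible(x)
}
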