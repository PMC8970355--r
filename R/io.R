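# Readers and writers for the external formats the pipeline touches.
#
# Conventions: all file coordinates are 1-based inclusive (GFF3 style);
# internal column indices are plain R 1-based vectors. The only gap
# character accepted is '-' ('.' is rejected at validation).

#' Read a (multi-)FASTA file
#'
#' Sequences are uppercased and returned in file order. Intended for
#' alignments: when `aligned = TRUE` (default) unequal record lengths are
#' an error.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`; residues are validated against
#'   the alphabet (gap `-` allowed, `N`/`X` allowed as missing).
#' @param aligned Require all records to have equal length.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein"), aligned = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate FASTA id(s) in ", path, ": ",
                        paste(dup, collapse = ", "))
  seqs <- stats::setNames(toupper(as.character(set)), ids)
  lens <- nchar(seqs)
  if (aligned && length(unique(lens)) != 1L)
    stop("unequal record lengths in ", path, ": ",
         paste(sprintf("%s=%d", ids, lens), collapse = ", "))
  allowed <- if (alphabet == "dna") DNA_RESIDUES else AA_RESIDUES
  for (id in ids) {
    res <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    bad <- which(!(res %in% allowed))
    if (length(bad))
      stop("illegal ", alphabet, " residue '", res[bad[1]], "' at position ",
           bad[1], " in record '", id, "' of ", path)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] with validation: unique leaf
#' labels, parse failures surfaced as errors. Absent branch lengths stay
#' absent (`NULL` edge.length), they are not coerced to 0.
#'
#' @param path_or_text A file path or a literal Newick string (detected by
#'   the presence of `(`/`;`).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path_or_text) {
  is_text <- grepl("[(;]", path_or_text)
  tr <- if (is_text) {
    tryCatch(ape::read.tree(text = path_or_text),
             error = function(e) NULL, warning = function(w) NULL)
  } else {
    if (!file.exists(path_or_text)) stop("no such file: ", path_or_text)
    tryCatch(ape::read.tree(path_or_text),
             error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("failed to parse Newick: ", substr(path_or_text, 1, 60))
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  tr
}

#' Read a strain metadata table
#'
#' TSV with fixed columns `strain_id`, `species`, `specimen_id`,
#' `continent`; extra columns are preserved but ignored by the pipeline.
#'
#' @param path Path to the TSV.
#' @return A data.frame with one row per strain.
#' @export
read_strain_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("strain_id", "species", "specimen_id", "continent")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("strain metadata lacks column(s): ", paste(miss, collapse = ", "))
  dup <- unique(df$strain_id[duplicated(df$strain_id)])
  if (length(dup)) stop("duplicate strain_id(s): ", paste(dup, collapse = ", "))
  df
}

#' Read a gene panel from a manifest
#'
#' The manifest is a TSV with columns `gene_id`, `fasta_path`, `category`
#' and optionally `newick_path`; relative paths are resolved against the
#' manifest's directory. Every referenced file must exist and every gene's
#' strains must appear in the metadata table when one is given.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param meta Optional strain metadata data.frame from
#'   [read_strain_meta()]; if `NULL`, species labels default to the strain
#'   id prefix before the first underscore.
#' @param alphabet Alphabet of the per-gene FASTA files.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(manifest_path, meta = NULL, alphabet = "dna") {
  if (!file.exists(manifest_path)) stop("no such file: ", manifest_path)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "fasta_path", "category")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(man$category), c("mating", "flanking", "background"))
  if (length(bad)) stop("unknown category in manifest: ", paste(bad, collapse = ", "))
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  genes <- list()
  trees <- character()
  for (i in seq_len(nrow(man))) {
    fp <- resolve(man$fasta_path[i])
    if (!file.exists(fp)) stop("manifest references absent FASTA: ", man$fasta_path[i])
    seqs <- read_fasta(fp, alphabet)
    if (!is.null(meta)) {
      unknown <- setdiff(names(seqs), meta$strain_id)
      if (length(unknown))
        stop("gene '", man$gene_id[i], "' has strain(s) absent from metadata: ",
             paste(unknown, collapse = ", "))
      sp <- stats::setNames(meta$species, meta$strain_id)[names(seqs)]
    } else {
      sp <- stats::setNames(sub("_.*$", "", names(seqs)), names(seqs))
    }
    genes[[man$gene_id[i]]] <- species_alignment(man$gene_id[i], seqs, sp, alphabet)
    if ("newick_path" %in% names(man) && !is.na(man$newick_path[i]) &&
        nzchar(man$newick_path[i])) {
      np <- resolve(man$newick_path[i])
      if (!file.exists(np)) stop("manifest references absent Newick: ", man$newick_path[i])
      trees[[man$gene_id[i]]] <- paste(readLines(np, warn = FALSE), collapse = "")
    }
  }
  gene_panel(genes, stats::setNames(man$category, man$gene_id),
             if (length(trees)) trees else NULL)
}

#' Read gene features from a GFF3-style TSV
#'
#' Columns `contig`, `start`, `end`, `strand`, `feature_id`, `kind`
#' (`STE3`, `ORF` or `other`); coordinates 1-based inclusive.
#'
#' @param path Path to the TSV.
#' @return data.frame of features.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "strand", "feature_id", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  validate_features(df)
  df
}

validate_features <- function(df) {
  if (any(df$start < 1L | df$start > df$end))
    stop("invalid feature interval(s): require 1 <= start <= end")
  bad <- setdiff(unique(df$strand), c("+", "-"))
  if (length(bad)) stop("invalid strand value(s): ", paste(bad, collapse = ", "))
  invisible(df)
}

#' Write a data.frame as TSV with NA rendered as "NA"
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
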