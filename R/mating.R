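# Mating-genotype assignment from per-gene allelic classes, mating-type
# enumeration, cross-compatibility prediction, and unfolding of parental
# (dikaryon) genotypes from sibling monokaryons.
#
# Conventions: the MATA locus holds two homeodomain complexes, alpha
# (aHD1 + aHD2) and beta (bHD1 + bHD2); the MATB locus holds the pheromone
# receptors STE3.2 and STE3.4. A "complex class" is the joint
# (HD1 class, HD2 class) pair label -- pairs are compared as tuples, never
# per gene.

MATING_GENES <- c("aHD1", "aHD2", "bHD1", "bHD2", "STE3.2", "STE3.4")

pair_label <- function(c1, c2) {
  ifelse(is.na(c1) | is.na(c2), NA_character_, paste(c1, c2, sep = "/"))
}

#' Assign per-strain mating genotypes from allelic classifications
#'
#' @param classifications Named list with (a subset of) entries `aHD1`,
#'   `aHD2`, `bHD1`, `bHD2`, `STE3.2`, `STE3.4`; each is either an
#'   `allelic_classification` from [aai_cluster()] or a named vector
#'   strain id -> class label. A gene absent for a strain yields a missing
#'   component (e.g. a lost bHD1 leaves the beta complex missing; the
#'   strain is still typeable through alpha).
#' @param meta Strain metadata data.frame (columns `strain_id`, `species`,
#'   optionally `specimen_id`); strains present in no classification are
#'   excluded with a warning.
#' @return data.frame of class `mating_genotypes`: one row per strain with
#'   per-gene classes, complex labels `alpha`, `beta`, receptor classes
#'   `ste32`, `ste34`, and a `typeable` flag (at least one HD complex and
#'   at least one receptor present).
#' @export
assign_genotypes <- function(classifications, meta) {
  cls <- lapply(classifications, function(x) {
    if (inherits(x, "allelic_classification")) x$class_of else x
  })
  unknown <- setdiff(names(cls), MATING_GENES)
  if (length(unknown)) stop("unknown mating gene(s): ", paste(unknown, collapse = ", "))
  seen <- unique(unlist(lapply(cls, names)))
  absent <- setdiff(meta$strain_id, seen)
  if (length(absent))
    warning("strain(s) present in no classification excluded: ",
            paste(absent, collapse = ", "))
  strains <- intersect(meta$strain_id, seen)
  get_class <- function(gene, strain) {
    v <- cls[[gene]]
    if (is.null(v) || !(strain %in% names(v))) NA_character_
    else as.character(v[[strain]])
  }
  rows <- lapply(strains, function(s) {
    g <- vapply(MATING_GENES, get_class, character(1), strain = s)
    alpha <- pair_label(g[["aHD1"]], g[["aHD2"]])
    beta <- pair_label(g[["bHD1"]], g[["bHD2"]])
    data.frame(strain_id = s,
               species = meta$species[match(s, meta$strain_id)],
               specimen_id = if ("specimen_id" %in% names(meta))
                 meta$specimen_id[match(s, meta$strain_id)] else NA_character_,
               aHD1 = g[["aHD1"]], aHD2 = g[["aHD2"]],
               bHD1 = g[["bHD1"]], bHD2 = g[["bHD2"]],
               alpha = alpha, beta = beta,
               ste32 = g[["STE3.2"]], ste34 = g[["STE3.4"]],
               typeable = (!is.na(alpha) || !is.na(beta)) &&
                 (!is.na(g[["STE3.2"]]) || !is.na(g[["STE3.4"]])),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) stop("no strains with any classification")
  out <- do.call(rbind, rows)
  dup <- out$strain_id[duplicated(out$strain_id)]
  if (length(dup)) stop("contradictory duplicate strain rows: ",
                        paste(unique(dup), collapse = ", "))
  class(out) <- c("mating_genotypes", "data.frame")
  out
}

#' Enumerate mating types from genotypes
#'
#' Counts the distinct observed alpha-complex, beta-complex, STE3.2 and
#' STE3.4 classes and predicts type counts by free combinatorics, the
#' field's convention: `n_MATA = n_alpha * n_beta`, `n_MATB = n_ste32 *
#' n_ste34`, `n_types = n_MATA * n_MATB`. Strains missing a component are
#' excluded from that component's census only.
#'
#' @param genotypes A `mating_genotypes` data.frame.
#' @param scope `"pooled"` (all strains together) or `"species"` (one
#'   census per species).
#' @return For `"pooled"`, a list of class `type_census`; for
#'   `"species"`, a named list of such censuses.
#' @export
enumerate_types <- function(genotypes, scope = c("pooled", "species")) {
  scope <- match.arg(scope)
  if (!nrow(genotypes) || !any(genotypes$typeable))
    stop("no typeable strains")
  census_of <- function(g) {
    nun <- function(x) length(unique(x[!is.na(x)]))
    n_alpha <- nun(g$alpha); n_beta <- nun(g$beta)
    n_ste32 <- nun(g$ste32); n_ste34 <- nun(g$ste34)
    # a component never observed in the data set is an absent locus, not a
    # zero factor (e.g. the beta complex when bHD genes are missing)
    prod_present <- function(...) {
      f <- c(...)
      f <- f[f > 0L]
      if (!length(f)) 0L else prod(f)
    }
    mata_obs <- unique(stats::na.omit(paste(g$alpha, g$beta, sep = "|")[
      !is.na(g$alpha) & !is.na(g$beta)]))
    matb_obs <- unique(stats::na.omit(paste(g$ste32, g$ste34, sep = "|")[
      !is.na(g$ste32) & !is.na(g$ste34)]))
    structure(list(n_strains = nrow(g),
                   n_alpha = n_alpha, n_beta = n_beta,
                   n_MATA = prod_present(n_alpha, n_beta),
                   n_ste32 = n_ste32, n_ste34 = n_ste34,
                   n_MATB = prod_present(n_ste32, n_ste34),
                   n_types = prod_present(n_alpha, n_beta) *
                     prod_present(n_ste32, n_ste34),
                   observed_MATA = length(mata_obs),
                   observed_MATB = length(matb_obs)),
              class = "type_census")
  }
  if (scope == "pooled") return(census_of(genotypes))
  lapply(split(genotypes, genotypes$species), census_of)
}

#' @export
print.type_census <- function(x, ...) {
  cat(sprintf("<type_census> %d strains\n", x$n_strains))
  cat(sprintf("  MATA: %d alpha x %d beta = %d predicted (%d observed)\n",
              x$n_alpha, x$n_beta, x$n_MATA, x$observed_MATA))
  cat(sprintf("  MATB: %d STE3.2 x %d STE3.4 = %d predicted (%d observed)\n",
              x$n_ste32, x$n_ste34, x$n_MATB, x$observed_MATB))
  cat(sprintf("  mating types: %d\n", x$n_types))
  invisible(x)
}

#' Predict compatibility of a cross between two genotypes
#'
#' A cross is compatible iff at least one MATA complex (alpha or beta) AND
#' at least one pheromone receptor (STE3.2 or STE3.4) differ, where
#' "differs" requires both values present and unequal. If the decision
#' hinges on a missing component the verdict is `indeterminate`. Crossing
#' a strain with itself is `incompatible` (all components equal), not an
#' error. Genotypic compatibility across species is necessary but not
#' sufficient (pre-zygotic barriers act between species); inter-species
#' verdicts carry a cautionary note.
#'
#' @param g1,g2 Single rows of a `mating_genotypes` data.frame (or
#'   one-row data.frames with the same columns).
#' @return List with `verdict` (`"compatible"`, `"incompatible"`,
#'   `"indeterminate"`), `reason`, and `interspecies` flag.
#' @export
predict_compatibility <- function(g1, g2) {
  comp3 <- function(a, b) {   # TRUE / FALSE / NA (missing somewhere)
    if (is.na(a) || is.na(b)) return(NA)
    a != b
  }
  da <- comp3(g1$alpha, g2$alpha); db <- comp3(g1$beta, g2$beta)
  d2 <- comp3(g1$ste32, g2$ste32); d4 <- comp3(g1$ste34, g2$ste34)
  or3 <- function(x, y) {     # three-valued OR
    if (isTRUE(x) || isTRUE(y)) TRUE
    else if (is.na(x) || is.na(y)) NA
    else FALSE
  }
  mata_diff <- or3(da, db)
  matb_diff <- or3(d2, d4)
  decided <- function(flag, names, vals)
    paste(names[which(vapply(vals, isTRUE, logical(1)))], collapse = "+")
  verdict <- if (isTRUE(mata_diff) && isTRUE(matb_diff)) "compatible"
  else if (isFALSE(mata_diff) || isFALSE(matb_diff)) "incompatible"
  else "indeterminate"
  reason <- switch(verdict,
    compatible = paste0("MATA differs at ",
                        decided(mata_diff, c("alpha", "beta"), list(da, db)),
                        "; MATB differs at ",
                        decided(matb_diff, c("STE3.2", "STE3.4"), list(d2, d4))),
    incompatible = paste0(
      if (isFALSE(mata_diff)) "MATA identical" else "",
      if (isFALSE(mata_diff) && isFALSE(matb_diff)) " and " else "",
      if (isFALSE(matb_diff)) "MATB identical" else ""),
    indeterminate = "decision hinges on a missing component")
  inter <- !is.na(g1$species) && !is.na(g2$species) && g1$species != g2$species
  if (inter && verdict == "compatible")
    reason <- paste0(reason, " [inter-species cross: genotypic compatibility",
                     " is necessary, not sufficient]")
  list(verdict = verdict, reason = reason, interspecies = inter)
}

#' Unfold the parental dikaryon genotype from sibling monokaryons
#'
#' Sibling monokaryotic strains isolated from one dikaryotic specimen
#' carry at most two distinct classes per gene (one per parental nucleus).
#' Per gene this reports the set of observed classes; the parental
#' composition is complete iff two distinct classes are seen for the MATA
#' components and for the MATB components. More than two distinct classes
#' at a gene violates the single-dikaryon origin and is an error.
#'
#' @param genotypes `mating_genotypes` rows for the siblings of one
#'   specimen.
#' @return List with `per_gene` (named list of class sets over
#'   `alpha`, `beta`, `ste32`, `ste34`), `complete` (logical), and
#'   `n_siblings`. With fewer than two siblings completeness is
#'   necessarily unresolved (`complete = FALSE`).
#' @export
unfold_parental <- function(genotypes) {
  if (!nrow(genotypes)) stop("no sibling genotypes given")
  genes <- c(aHD1 = "aHD1", aHD2 = "aHD2", bHD1 = "bHD1", bHD2 = "bHD2",
             STE3.2 = "ste32", STE3.4 = "ste34")
  per_gene <- lapply(genes, function(cc) {
    v <- unique(stats::na.omit(genotypes[[cc]]))
    if (length(v) > 2L)
      stop("gene '", cc, "' shows ", length(v),
           " distinct classes among siblings: inconsistent with a single",
           " dikaryotic parent")
    sort(v)
  })
  mata_complete <- any(vapply(per_gene[c("aHD1", "aHD2", "bHD1", "bHD2")],
                              length, 1L) == 2L)
  matb_complete <- any(vapply(per_gene[c("STE3.2", "STE3.4")], length, 1L) == 2L)
  list(per_gene = per_gene,
       complete = nrow(genotypes) >= 2L && mata_complete && matb_complete,
       n_siblings = nrow(genotypes))
}
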