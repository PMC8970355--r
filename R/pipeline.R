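# End-to-end pipeline orchestrator: simulate (or load) a gene panel,
# compute per-gene statistics, fit the multilocus HKA test, classify
# mating-gene proteins into allelic classes, enumerate mating types, run
# the pheromone scan (optional) and the outlier scan, writing every
# intermediate table to the output directory.

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  cfg <- utils::modifyList(list(
    seed = 1L, out_dir = "matloci_run", tau = 86, q = 0.01, min_flags = 2L,
    species = c("speciesA", "speciesB"), focal = "speciesA",
    simulate = list(n_neutral = 100L, n_balanced = 4L),
    pheromone = NULL, panel_manifest = NULL, meta = NULL,
    gene_roles = NULL), config)
  if (cfg$tau <= 0 || cfg$tau > 100) stop("config error: tau must be in (0, 100]")
  if (cfg$q <= 0 || cfg$q > 0.5) stop("config error: q must be in (0, 0.5]")
  if (length(cfg$species) != 2L) stop("config error: exactly two species labels")
  if (!(cfg$focal %in% cfg$species)) stop("config error: focal not in species")
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load a panel from a manifest), per-gene statistics
#' ([gene_summary()]), multilocus HKA ([hka_test()]) with per-locus
#' partials merged into the statistics table, allelic-class clustering of
#' every mating gene at `tau` ([aai_cluster()] on translated proteins),
#' mating-type census ([enumerate_types()]; mating genes are mapped onto
#' the locus roles aHD1, aHD2, STE3.2, STE3.4, bHD1, bHD2 in that order
#' unless `config$gene_roles` names them explicitly), optional pheromone
#' scan, and the outlier scan ([outlier_scan()]). All intermediate TSVs, a
#' machine-readable run manifest and a human log are written under
#' `config$out_dir`.
#'
#' @param config A list or YAML path; recognised fields: `seed`,
#'   `out_dir`, `simulate` (`n_neutral`, `n_balanced`, plus optional
#'   `neutral`/`balanced` [sim_config()] argument lists), or
#'   `panel_manifest` + `meta` to load data; `species`, `focal`, `tau`,
#'   `q`, `min_flags`, `gene_roles`, `pheromone` (list with `contig_fasta`
#'   and `features_tsv`).
#' @return Invisibly, a list with the outlier report, census, HKA fit and
#'   output directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("matloci %s pipeline run, %s", as.character(utils::packageVersion("matloci")),
       format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logf("master seed: %d", cfg$seed)

  # --- panel ---------------------------------------------------------------
  if (!is.null(cfg$panel_manifest)) {
    panel <- stage("load_panel", {
      meta <- if (!is.null(cfg$meta)) read_strain_meta(cfg$meta) else NULL
      read_gene_panel(cfg$panel_manifest, meta)
    })
    class_truth <- NULL
  } else {
    sim <- stage("simulate", {
      ncfg <- do.call(sim_config, cfg$simulate$neutral %||% list())
      bcfg <- do.call(sim_config, utils::modifyList(list(mode = "codon"),
                                                    cfg$simulate$balanced %||% list()))
      simulate_panel(cfg$simulate$n_neutral, cfg$simulate$n_balanced,
                     ncfg, bcfg, seed = cfg$seed)
    })
    panel <- sim$panel
    class_truth <- sim$class_truth
    write_tsv(sim$truth, file.path(cfg$out_dir, "truth.tsv"))
  }
  logf("panel: %d genes", length(panel$genes))

  # --- per-gene statistics -------------------------------------------------
  stats <- stage("stats", gene_summary(panel, cfg$species[1], cfg$species[2]))
  write_tsv(stats, file.path(cfg$out_dir, "stats.tsv"))

  # --- multilocus HKA ------------------------------------------------------
  other <- setdiff(cfg$species, cfg$focal)
  hka <- stage("hka", {
    inp <- suppressWarnings(build_hka_input(panel, cfg$focal, other))
    suppressWarnings(hka_test(inp))
  })
  write_tsv(hka$table, file.path(cfg$out_dir, "hka.tsv"))
  logf("HKA: X2 = %.3f, df = %d, p = %.3g, T_hat = %.3f",
       hka$X2, hka$df, hka$p_value, hka$T_hat)
  stats$partial_hka <- unname(hka$partials[stats$gene_id])

  # --- allelic classes for mating genes ------------------------------------
  mating_genes <- names(panel$genes)[panel$category_of == "mating"]
  class_dir <- file.path(cfg$out_dir, "classes")
  dir.create(class_dir, showWarnings = FALSE)
  classifications <- list()
  for (gid in mating_genes) {
    aln <- panel$genes[[gid]]
    if (aln$alphabet == "dna" && aln$length %% 3L != 0L) next
    prot <- if (aln$alphabet == "dna")
      vapply(aln$seqs, translate_cds, character(1)) else aln$seqs
    cl <- stage(paste0("classify:", gid),
                aai_cluster(pairwise_aai(prot), tau = cfg$tau))
    classifications[[gid]] <- cl
    write_tsv(data.frame(strain_id = names(cl$class_of),
                         class = unname(cl$class_of)),
              file.path(class_dir, paste0(gid, ".classes.tsv")))
  }
  logf("classified %d mating gene(s) at tau = %g%%",
       length(classifications), cfg$tau)

  # --- mating census -------------------------------------------------------
  census <- NULL
  if (length(classifications)) {
    roles <- cfg$gene_roles %||% {
      order_pref <- c("aHD1", "aHD2", "STE3.2", "STE3.4", "bHD1", "bHD2")
      n <- min(length(classifications), length(order_pref))
      stats::setNames(names(classifications)[seq_len(n)], order_pref[seq_len(n)])
    }
    aln1 <- panel$genes[[roles[[1]]]]
    meta <- data.frame(strain_id = names(aln1$species_of),
                       species = unname(aln1$species_of),
                       stringsAsFactors = FALSE)
    cls_by_role <- stats::setNames(
      lapply(names(roles), function(r) classifications[[roles[[r]]]]),
      names(roles))
    geno <- stage("mating", assign_genotypes(cls_by_role, meta))
    census <- enumerate_types(geno, "pooled")
    census_df <- as.data.frame(census[setdiff(names(census), character(0))])
    write_tsv(census_df, file.path(cfg$out_dir, "census.tsv"))
    write_tsv(geno, file.path(cfg$out_dir, "genotypes.tsv"))
    logf("census: %d predicted mating types", census$n_types)
  }

  # --- pheromone scan (optional) ------------------------------------------
  if (!is.null(cfg$pheromone)) {
    ph <- stage("pheromone", {
      contig <- read_fasta(cfg$pheromone$contig_fasta, "dna", aligned = FALSE)
      feats <- read_features(cfg$pheromone$features_tsv)
      scan_pheromones(contig[[1]], feats, contig_name = names(contig)[1])
    })
    write_tsv(ph, file.path(cfg$out_dir, "pheromone_hits.tsv"))
    logf("pheromone scan: %d accepted hit(s)", sum(ph$verdict == "accepted"))
  }

  # --- outlier scan --------------------------------------------------------
  report <- stage("outlier_scan",
                  outlier_scan(stats, q = cfg$q, min_flags = cfg$min_flags))
  write_tsv(report, file.path(cfg$out_dir, "outliers.tsv"))
  logf("outlier scan: %d candidate(s)", sum(report$candidate))

  # --- machine-readable manifest -------------------------------------------
  manifest <- list(
    package = "matloci",
    version = as.character(utils::packageVersion("matloci")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "run_manifest.yaml"))

  invisible(list(report = report, census = census, hka = hka, stats = stats,
                 class_truth = class_truth, out_dir = cfg$out_dir))
}
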