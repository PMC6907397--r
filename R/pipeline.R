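# Pipeline orchestration: the three stages (simulate, reconcile, wgd) as
# functions over a single YAML-able config, writing TSV outputs with a
# manifest of checksums so a fixed seed reproduces byte-identical runs.

default_config <- function() {
  list(
    seed = 1,
    n_chromosomes = 13, genes_per_chromosome = 100, gene_length = 300,
    wgd_events = list(
      list(ks_mean = 1.71, ks_sd = 0.35, retention_rate = 0.4),
      list(ks_mean = 0.61, ks_sd = 0.15, retention_rate = 0.5)
    ),
    background_dup_rate = 0, rearrangement_rate = 0,
    target_scaffold_n50 = 5000, chimera_count = 23, inversion_count = 3,
    n_progeny = 110, markers_per_chromosome = 50,
    chromosome_length_cM = 100, missing_rate = 0.05,
    min_call_rate = 0.90, r_max = 0.35, lod_min = 3.0,
    max_gap_genes = 40, min_anchors = 5, ks_cap = 3,
    sizer_alpha = 0.05, sizer_bins = 401, k_range = 1:5
  )
}

#' Load a pipeline configuration
#'
#' Reads a YAML file and fills unset keys with package defaults; a `seed` is
#' mandatory.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied last.
#' @return Config list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  assert_that(!is.null(cfg$seed), "config: seed is mandatory")
  cfg
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

manifest <- function(outdir, files) {
  tibble(file = files,
         md5 = unname(tools::md5sum(file.path(outdir, files))))
}

#' Run the simulation stage
#'
#' Generates a genome with planted WGDs, a corrupted assembly, a proximity
#' ordering with planted inversions, and a pseudo-testcross genotype table;
#' writes FASTA/GFF3/TSV outputs plus truth tables and a checksum manifest.
#'
#' @param config Config list from [load_config()].
#' @param outdir Output directory (created).
#' @return Invisibly, a list with the in-memory stage objects and the
#'   manifest.
#' @export
run_simulate <- function(config, outdir) {
  assert_that(!is.null(config$seed), "run_simulate(): seed is mandatory")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(
    n_chromosomes = config$n_chromosomes,
    genes_per_chromosome = config$genes_per_chromosome,
    gene_length = config$gene_length,
    wgd_events = config$wgd_events,
    background_dup_rate = config$background_dup_rate,
    rearrangement_rate = config$rearrangement_rate,
    seed = config$seed
  )
  sim <- simulate_wgd_genome(cfg)
  fr <- fragment_and_corrupt(sim$genome, sim$truth,
                             target_scaffold_n50 = config$target_scaffold_n50,
                             chimera_count = config$chimera_count,
                             seed = config$seed)
  po <- simulate_proximity_ordering(fr$assembly, fr$truth,
                                    inversion_count = config$inversion_count,
                                    seed = config$seed)
  gt <- simulate_cross(sim$genome, n_progeny = config$n_progeny,
                       markers_per_chromosome = config$markers_per_chromosome,
                       chromosome_length_cM = config$chromosome_length_cM,
                       missing_rate = config$missing_rate,
                       truth = po$truth, seed = config$seed)

  write_scaffolds(
    tibble(scaffold_id = sim$genome$chromosomes$chrom,
           sequence = sim$genome$chromosomes$sequence),
    file.path(outdir, "genome.fasta"))
  write_gene_gff3(sim$genome$genes, file.path(outdir, "genes.gff3"))
  write_scaffolds(
    tibble(scaffold_id = sim$genome$genes$gene_id,
           sequence = sim$genome$genes$cds),
    file.path(outdir, "cds.fasta"))
  write_scaffolds(fr$assembly, file.path(outdir, "assembly.fasta"))
  write_tsv_quiet(po$ordering, file.path(outdir, "proximity_ordering.tsv"))
  calls <- as_tibble(gt$calls, rownames = "marker_id")
  write_tsv_quiet(left_join(gt$markers, calls, by = "marker_id"),
                  file.path(outdir, "genotypes.tsv"))
  write_tsv_quiet(po$truth$duplicate_pairs,
                  file.path(outdir, "truth_duplicate_pairs.tsv"))
  write_tsv_quiet(po$truth$chimeric_joins,
                  file.path(outdir, "truth_chimeric_joins.tsv"))
  write_tsv_quiet(
    po$truth$planted_inversions |>
      mutate(scaffolds = map_chr(.data$scaffolds, paste, collapse = ",")),
    file.path(outdir, "truth_planted_inversions.tsv"))
  write_tsv_quiet(po$truth$scaffold_origin,
                  file.path(outdir, "truth_scaffold_origin.tsv"))
  files <- c("genome.fasta", "genes.gff3", "cds.fasta", "assembly.fasta",
             "proximity_ordering.tsv", "genotypes.tsv",
             "truth_duplicate_pairs.tsv", "truth_chimeric_joins.tsv",
             "truth_planted_inversions.tsv", "truth_scaffold_origin.tsv")
  mf <- manifest(outdir, files)
  write_tsv_quiet(mf, file.path(outdir, "manifest.tsv"))
  invisible(list(genome = sim$genome, truth = po$truth,
                 assembly = fr$assembly, ordering = po$ordering,
                 genotypes = gt, manifest = mf))
}

#' Read a genotype TSV back into a genotype table
#'
#' @param path Genotype TSV written by [run_simulate()].
#' @return A `genotype_table`.
#' @export
read_genotypes <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("marker_id", "chrom", "position_bp", "position_cM",
                 "scaffold_id", "scaffold_position")
  meta <- select(d, dplyr::any_of(meta_cols))
  calls <- as.matrix(select(d, -dplyr::any_of(meta_cols)))
  rownames(calls) <- d$marker_id
  structure(list(markers = meta, calls = calls, n_progeny = ncol(calls)),
            class = "genotype_table")
}

#' Run the reconciliation stage
#'
#' Builds the linkage map from the genotype table, reconciles the proximity
#' ordering against it, and writes the final ordering, accounting,
#' split-report TSVs and corrected pseudochromosome FASTA.
#'
#' @param config Config list.
#' @param indir Directory holding [run_simulate()] outputs (or equivalently
#'   formatted real inputs).
#' @param outdir Output directory.
#' @return Invisibly, the `reconciled_assembly`.
#' @export
run_reconcile <- function(config, indir, outdir) {
  for (f in c("genotypes.tsv", "proximity_ordering.tsv", "assembly.fasta")) {
    assert_that(file.exists(file.path(indir, f)),
                paste0("run_reconcile(): missing input ", f))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gt <- read_genotypes(file.path(indir, "genotypes.tsv"))
  ordering <- readr::read_tsv(file.path(indir, "proximity_ordering.tsv"),
                              show_col_types = FALSE)
  assembly <- read_scaffolds(file.path(indir, "assembly.fasta"))
  lmap <- build_linkage_map(gt, min_call_rate = config$min_call_rate,
                            r_max = config$r_max, lod_min = config$lod_min)
  rec <- reconcile(ordering, lmap, assembly)
  write_tsv_quiet(select(rec$scaffolds, "lg_id", "rank", "scaffold_id",
                         "orientation", "tier"),
                  file.path(outdir, "final_ordering.tsv"))
  write_tsv_quiet(rec$accounting, file.path(outdir, "accounting.tsv"))
  write_tsv_quiet(
    rec$split_report |>
      mutate(cut_positions = map_chr(.data$cut_positions, paste,
                                     collapse = ",")),
    file.path(outdir, "split_report.tsv"))
  write_tsv_quiet(lmap, file.path(outdir, "linkage_map.tsv"))
  # corrected pseudochromosomes
  seqs <- rec$assembly
  pseudo <- purrr::map(
    sort(unique(rec$scaffolds$lg_id[!is.na(rec$scaffolds$lg_id)])),
    function(lg) {
      ord <- rec$scaffolds |>
        filter(.data$lg_id == lg, !is.na(.data$rank)) |>
        arrange(.data$rank) |>
        left_join(select(seqs, "scaffold_id", "sequence"), by = "scaffold_id")
      build_pseudochromosome(ord, lg_id = lg)
    })
  write_scaffolds(
    tibble(scaffold_id = map_chr(pseudo, "lg_id"),
           sequence = map_chr(pseudo, "sequence")),
    file.path(outdir, "pseudochromosomes.fasta"))
  invisible(rec)
}

#' Run the WGD-detection stage on one or more genomes
#'
#' For each genome: paranome Ks, SiZer map, mixture fit, SiZer-matched
#' components; then cross-genome peak matching into shared WGD calls and,
#' when an ortholog sample is supplied, placement relative to speciation.
#'
#' @param genomes Named list of `wgd_genome` objects (or gene tables with
#'   `cds`).
#' @param hits Named list (same names) of paralog hit tibbles.
#' @param config Config list.
#' @param ortholog_samples Optional named list of ortholog Ks vectors, one
#'   per speciation comparison.
#' @param outdir Optional output directory for TSV reports.
#' @return List of class `wgd_report`: per-genome results, `calls`,
#'   `placements`.
#' @export
run_wgd <- function(genomes, hits, config = load_config(),
                    ortholog_samples = NULL, outdir = NULL) {
  assert_that(length(genomes) >= 1, "run_wgd(): no genomes")
  per_genome <- purrr::imap(genomes, function(gen, name) {
    ks <- paranome_ks(gen, hits[[name]], ks_cap = config$ks_cap)
    if (length(ks) < 20) {
      return(list(genome = name, ks = ks, components = tibble(),
                  message = "no duplication signal"))
    }
    map <- sizer_map(ks, alpha = config$sizer_alpha, bins = config$sizer_bins,
                     range = c(0, config$ks_cap))
    fit <- fit_gaussian_mixture(ks, k_range = config$k_range,
                                seed = config$seed)
    comp <- match_components_to_sizer(fit, map)
    list(genome = name, ks = ks, sizer = map, fit = fit, components = comp)
  })
  reported <- purrr::imap_dfr(per_genome, function(res, name) {
    if (nrow(res$components) == 0) return(tibble())
    res$components |>
      filter(.data$flag == "wgd_candidate") |>
      mutate(genome = name) |>
      select("genome", "mean")
  })
  calls <- if (nrow(reported) > 0) {
    match_peaks_across_genomes(reported)
  } else {
    tibble(call_id = character(0), ks_mean = numeric(0),
           n_genomes = integer(0), genomes = list(), shared = logical(0))
  }
  placements <- tibble()
  if (!is.null(ortholog_samples) && nrow(calls) > 0) {
    placements <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
      purrr::imap_dfr(ortholog_samples, function(os, lab) {
        place_wgd_relative_to_speciation(calls$ks_mean[i], os, label = lab) |>
          mutate(call_id = calls$call_id[i])
      })
    })
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_quiet(calls |> mutate(genomes = map_chr(.data$genomes, paste,
                                                      collapse = ",")),
                    file.path(outdir, "wgd_calls.tsv"))
    if (nrow(placements) > 0) {
      write_tsv_quiet(placements, file.path(outdir, "wgd_placements.tsv"))
    }
  }
  structure(list(per_genome = per_genome, calls = calls,
                 placements = placements),
            class = "wgd_report")
}
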