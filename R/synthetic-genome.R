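# Synthetic genomes with planted whole-genome duplications and planted
# assembly errors. The generator is first-class: every downstream stage is
# validated against the truth tables it emits.
#
# A genome is a list (class "wgd_genome") with
#   genes: tibble gene_id, chrom, start, end, strand, order_index, cds
#   chromosomes: tibble chrom, length, sequence
# Truth tables (class "wgd_truth") carry duplicate_pairs, chimeric_joins,
# planted_inversions and scaffold_origin, filled in as stages run.

#' Simulation configuration
#'
#' Carrier for the generating parameters of [simulate_wgd_genome()]. Defaults
#' describe the study conditions the package is validated under: a
#' 13-chromosome diploid with two ancient WGDs whose Ks depths sit at 0.61 and
#' 1.71 substitutions/site (the two peak ages recovered for *Rhododendron*-type
#' genomes), with the older event applied first.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Genes per chromosome before duplication.
#' @param gene_length CDS length in bp (multiple of 3).
#' @param intergenic_length Spacer between consecutive genes in bp.
#' @param wgd_events List of `list(ks_mean=, ks_sd=, retention_rate=)`, applied
#'   in the order given (put the oldest event first).
#' @param background_dup_rate Expected background (small-scale) duplications
#'   per gene; their Ks is drawn from Exponential(mean 0.15), giving the
#'   recent, non-WGD peak near the origin.
#' @param rearrangement_rate Expected reciprocal translocations per chromosome.
#' @param seed Integer seed; all randomness flows from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 13, genes_per_chromosome = 100,
                       gene_length = 300, intergenic_length = 100,
                       wgd_events = list(
                         list(ks_mean = 1.71, ks_sd = 0.35, retention_rate = 0.4),
                         list(ks_mean = 0.61, ks_sd = 0.15, retention_rate = 0.5)
                       ),
                       background_dup_rate = 0, rearrangement_rate = 0,
                       seed = 1) {
  assert_that(gene_length %% 3 == 0, "gene_length must be a multiple of 3")
  assert_that(n_chromosomes >= 1 && genes_per_chromosome >= 1,
              "counts must be positive")
  for (ev in wgd_events) {
    assert_that(ev$retention_rate >= 0 && ev$retention_rate <= 1,
                "retention_rate must lie in [0, 1]")
    assert_that(ev$ks_mean > 0, "ks_mean must be > 0")
    assert_that(ev$ks_sd > 0, "ks_sd must be > 0")
  }
  assert_that(background_dup_rate >= 0 && rearrangement_rate >= 0,
              "rates must be non-negative")
  structure(
    list(n_chromosomes = n_chromosomes,
         genes_per_chromosome = genes_per_chromosome,
         gene_length = gene_length, intergenic_length = intergenic_length,
         wgd_events = wgd_events, background_dup_rate = background_dup_rate,
         rearrangement_rate = rearrangement_rate, seed = seed),
    class = "sim_config"
  )
}

empty_truth <- function() {
  structure(
    list(
      duplicate_pairs = tibble(gene_a = character(0), gene_b = character(0),
                               true_ks = numeric(0), origin_event = character(0)),
      chimeric_joins = tibble(scaffold_id = character(0),
                              junction_position = integer(0),
                              chrom_left = character(0), chrom_right = character(0)),
      planted_inversions = tibble(cluster_id = character(0),
                                  first_index = integer(0), last_index = integer(0),
                                  scaffolds = list()),
      scaffold_origin = tibble(scaffold_id = character(0), chrom = character(0),
                               start = integer(0), end = integer(0),
                               strand = character(0))
    ),
    class = "wgd_truth"
  )
}

random_cds <- function(n_codons, sense_codons) {
  paste(sample(sense_codons, n_codons, replace = TRUE), collapse = "")
}

# Normal(mean, sd) truncated at 0 by rejection
rnorm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out <= 0)
  }
  out
}

# Mutate `cds` at synonymous one-step choices (random walk over synonymous
# neighbours) until NG86 pS against the original reaches the target implied by
# true_ks through the inverted Jukes-Cantor relation pS = 3/4 (1 - e^{-4/3 Ks}).
# Keeps the duplicate's amino-acid sequence intact so Ka stays ~0 and true_ks
# is recoverable by ng86_ks().
mutate_to_ks <- function(cds, ks_target) {
  if (ks_target <= 0) return(cds)
  tabs <- ng86_tables()
  target_ps <- 0.75 * (1 - exp(-4 / 3 * ks_target))
  ca <- split_codons(cds)
  cb <- ca
  idx_a <- match(ca, tabs$codons)
  sa <- sum(tabs$syn_sites[idx_a])
  sb <- sa
  sd_per <- numeric(length(ca))
  sd_tot <- 0
  n <- length(ca)
  max_iter <- 60L * n
  for (it in seq_len(max_iter)) {
    if (sd_tot / ((sa + sb) / 2) >= target_ps) break
    j <- sample.int(n, 1)
    nb <- tabs$syn_neighbors[[cb[j]]]
    if (length(nb) == 0) next
    new_codon <- nb[sample.int(length(nb), 1)]
    sb <- sb - tabs$syn_sites[[cb[j]]] + tabs$syn_sites[[new_codon]]
    cb[j] <- new_codon
    new_sd <- tabs$sd[idx_a[j], match(new_codon, tabs$codons)]
    sd_tot <- sd_tot + new_sd - sd_per[j]
    sd_per[j] <- new_sd
  }
  paste(cb, collapse = "")
}

layout_chromosomes <- function(genes, gene_length, intergenic_length) {
  genes <- genes |>
    group_by(.data$chrom) |>
    mutate(order_index = row_number(),
           start = (row_number() - 1L) *
             as.integer(gene_length + intergenic_length) + 1L +
             as.integer(intergenic_length %/% 2),
           end = .data$start + as.integer(gene_length) - 1L) |>
    ungroup()
  genes
}

build_chromosome_sequences <- function(genes, gene_length, intergenic_length) {
  genes |>
    group_by(.data$chrom) |>
    summarise(sequence = {
      n <- dplyr::n()
      unit <- gene_length + intergenic_length
      total <- n * unit
      chars <- strsplit(random_dna(total), "")[[1]]
      for (i in seq_len(n)) {
        s <- .data$start[i]
        chars[s:(s + gene_length - 1L)] <- strsplit(.data$cds[i], "")[[1]]
      }
      paste(chars, collapse = "")
    }, .groups = "drop") |>
    mutate(length = nchar(.data$sequence))
}

#' Simulate a genome with planted whole-genome duplications
#'
#' Builds a multi-chromosome genome of protein-coding genes, then applies each
#' configured WGD event in turn: every gene is retained in duplicate with
#' probability `retention_rate`, duplicated genes are laid out collinearly on a
#' new chromosome copy, and each duplicate pair receives a true Ks drawn from
#' Normal(ks_mean, ks_sd) truncated at 0, realised in the duplicate's CDS by
#' synonymous-site substitution (see [ng86_ks()] for the estimator that
#' recovers it). Background duplications add tandem copies with small Ks.
#'
#' @param config A [sim_config()].
#' @return List with elements `genome` (class `wgd_genome`) and `truth`
#'   (class `wgd_truth`; `duplicate_pairs` filled).
#' @export
simulate_wgd_genome <- function(config) {
  assert_that(inherits(config, "sim_config"),
              "simulate_wgd_genome() expects a sim_config")
  with_seed(derive_seed(config$seed, 1L), {
    tabs <- ng86_tables()
    sense <- tabs$codons[tabs$aa != "*"]
    n_codons <- config$gene_length / 3

    genes <- tidyr::expand_grid(
      chrom = sprintf("chr%02d", seq_len(config$n_chromosomes)),
      g = seq_len(config$genes_per_chromosome)
    ) |>
      mutate(gene_id = sprintf("%s_g%04d", .data$chrom, .data$g),
             strand = sample(c("+", "-"), dplyr::n(), replace = TRUE),
             cds = map_chr(seq_len(dplyr::n()),
                           function(i) random_cds(n_codons, sense))) |>
      select(-"g")

    truth <- empty_truth()
    pairs <- list()

    for (ev_i in seq_along(config$wgd_events)) {
      ev <- config$wgd_events[[ev_i]]
      src_chroms <- unique(genes$chrom)
      dup_rows <- list()
      for (ch in src_chroms) {
        sub <- filter(genes, .data$chrom == ch)
        keep <- runif(nrow(sub)) < ev$retention_rate
        if (!any(keep)) next
        sub <- sub[keep, , drop = FALSE]
        new_ch <- sprintf("%s_w%d", ch, ev_i)
        ks <- rnorm_pos(nrow(sub), ev$ks_mean, ev$ks_sd)
        dup <- sub |>
          mutate(parent_id = .data$gene_id,
                 gene_id = sprintf("%s_w%d", .data$gene_id, ev_i),
                 chrom = new_ch,
                 true_ks = ks)
        dup$cds <- map_chr(seq_len(nrow(dup)), function(i) {
          mutate_to_ks(dup$cds[i], dup$true_ks[i])
        })
        dup_rows[[length(dup_rows) + 1L]] <- dup
      }
      if (length(dup_rows) > 0) {
        dup <- bind_rows(dup_rows)
        pairs[[length(pairs) + 1L]] <- tibble(
          gene_a = dup$parent_id, gene_b = dup$gene_id,
          true_ks = dup$true_ks, origin_event = sprintf("wgd%d", ev_i)
        )
        genes <- bind_rows(genes, select(dup, -"parent_id", -"true_ks"))
      }
    }

    # background small-scale duplications: tandem copies at recent Ks
    if (config$background_dup_rate > 0) {
      n_dup <- rpois(1, config$background_dup_rate * nrow(genes))
      if (n_dup > 0) {
        src <- genes[sample.int(nrow(genes), min(n_dup, nrow(genes))), ]
        ks <- rexp(nrow(src), rate = 1 / 0.15)
        bg <- src |>
          mutate(parent_id = .data$gene_id,
                 gene_id = paste0(.data$gene_id, "_t"),
                 true_ks = ks)
        bg$cds <- map_chr(seq_len(nrow(bg)), function(i) {
          mutate_to_ks(bg$cds[i], bg$true_ks[i])
        })
        pairs[[length(pairs) + 1L]] <- tibble(
          gene_a = bg$parent_id, gene_b = bg$gene_id,
          true_ks = bg$true_ks, origin_event = "background"
        )
        genes <- bind_rows(genes, select(bg, -"parent_id", -"true_ks"))
      }
    }

    # reciprocal terminal translocations between random chromosome pairs
    if (config$rearrangement_rate > 0) {
      chroms <- unique(genes$chrom)
      n_tr <- rpois(1, config$rearrangement_rate * length(chroms) / 2)
      for (i in seq_len(n_tr)) {
        pair <- sample(chroms, 2)
        a_genes <- which(genes$chrom == pair[1])
        b_genes <- which(genes$chrom == pair[2])
        if (length(a_genes) < 4 || length(b_genes) < 4) next
        ka <- sample.int(length(a_genes) - 2, 1)
        kb <- sample.int(length(b_genes) - 2, 1)
        tail_a <- a_genes[(length(a_genes) - ka + 1):length(a_genes)]
        tail_b <- b_genes[(length(b_genes) - kb + 1):length(b_genes)]
        genes$chrom[tail_a] <- pair[2]
        genes$chrom[tail_b] <- pair[1]
      }
    }

    # deterministic within-chromosome order: original order of appearance
    genes <- layout_chromosomes(genes, config$gene_length,
                                config$intergenic_length)
    chromosomes <- build_chromosome_sequences(genes, config$gene_length,
                                              config$intergenic_length)
    truth$duplicate_pairs <- if (length(pairs)) bind_rows(pairs) else
      truth$duplicate_pairs

    genome <- structure(
      list(genes = genes, chromosomes = chromosomes, config = config),
      class = "wgd_genome"
    )
    list(genome = genome, truth = truth)
  })
}

#' Plant a segmental duplication onto several chromosomes
#'
#' Copies a run of consecutive genes from a source chromosome onto each of a
#' set of target chromosomes (appended at the chromosome end, preserving gene
#' order), retaining each gene with probability `retention`. Used to plant
#' regions of known syntenic depth.
#'
#' @param genome A `wgd_genome`.
#' @param truth Matching `wgd_truth`.
#' @param chrom Source chromosome id.
#' @param start_gene First gene (order index) of the segment.
#' @param n_genes Segment length in genes.
#' @param to_chroms Character vector of target chromosomes.
#' @param retention Per-gene retention probability on each copy.
#' @param ks Ks depth assigned to the copies.
#' @param seed Integer seed.
#' @return List `genome`, `truth` with the copies and their duplicate pairs.
#' @export
duplicate_segment <- function(genome, truth, chrom, start_gene, n_genes,
                              to_chroms, retention = 0.8, ks = 0.6, seed = 1) {
  with_seed(derive_seed(seed, 9L), {
    src <- genome$genes |>
      filter(.data$chrom == !!chrom,
             .data$order_index >= start_gene,
             .data$order_index < start_gene + n_genes)
    assert_that(nrow(src) > 0, "duplicate_segment(): empty source segment")
    new_pairs <- list()
    genes <- genome$genes
    for (tc in to_chroms) {
      keep <- runif(nrow(src)) < retention
      if (!any(keep)) next
      sub <- src[keep, , drop = FALSE]
      copy <- sub |>
        mutate(parent_id = .data$gene_id,
               gene_id = sprintf("%s_c%s", .data$gene_id, tc),
               chrom = tc,
               order_index = 100000L + .data$order_index,
               true_ks = rnorm_pos(dplyr::n(), ks, 0.05))
      copy$cds <- map_chr(seq_len(nrow(copy)), function(i) {
        mutate_to_ks(copy$cds[i], copy$true_ks[i])
      })
      new_pairs[[length(new_pairs) + 1L]] <- tibble(
        gene_a = copy$parent_id, gene_b = copy$gene_id,
        true_ks = copy$true_ks, origin_event = "segmental"
      )
      genes <- bind_rows(genes, select(copy, -"parent_id", -"true_ks"))
    }
    cfg <- genome$config
    genes <- genes |>
      group_by(.data$chrom) |>
      arrange(.data$order_index, .by_group = TRUE) |>
      ungroup()
    genes <- layout_chromosomes(genes, cfg$gene_length, cfg$intergenic_length)
    genome$genes <- genes
    genome$chromosomes <- build_chromosome_sequences(
      genes, cfg$gene_length, cfg$intergenic_length)
    truth$duplicate_pairs <- bind_rows(truth$duplicate_pairs,
                                       bind_rows(new_pairs))
    list(genome = genome, truth = truth)
  })
}
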