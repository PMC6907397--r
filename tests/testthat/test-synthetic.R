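test_that("simulation config rejects invalid parameters", {
  expect_error(sim_config(gene_length = 301), "multiple of 3")
  expect_error(sim_config(wgd_events = list(
    list(ks_mean = 0.6, ks_sd = 0.1, retention_rate = 1.2))), "retention")
  expect_error(sim_config(wgd_events = list(
    list(ks_mean = -1, ks_sd = 0.1, retention_rate = 0.5))), "ks_mean")
  expect_error(sim_config(background_dup_rate = -0.1), "non-negative")
})

test_that("gene counts follow retention exactly at the boundaries", {
  # no events, no background: no duplicate pairs at all
  none <- simulate_wgd_genome(sim_config(n_chromosomes = 2,
                                         genes_per_chromosome = 10,
                                         wgd_events = list(), seed = 1))
  expect_equal(nrow(none$truth$duplicate_pairs), 0)
  expect_equal(nrow(none$genome$genes), 20)

  # retention 1.0 doubles the gene count exactly: 13 x 100 x 2 = 2,600
  full <- simulate_wgd_genome(sim_config(
    n_chromosomes = 13, genes_per_chromosome = 100,
    wgd_events = list(list(ks_mean = 0.3, ks_sd = 0.05,
                           retention_rate = 1.0)),
    seed = 2))
  expect_equal(nrow(full$genome$genes), 2600)
  expect_equal(nrow(full$truth$duplicate_pairs), 1300)

  # retention 0 leaves the genome untouched
  zero <- simulate_wgd_genome(sim_config(
    n_chromosomes = 2, genes_per_chromosome = 10,
    wgd_events = list(list(ks_mean = 0.3, ks_sd = 0.05,
                           retention_rate = 0)),
    seed = 3))
  expect_equal(nrow(zero$genome$genes), 20)
})

test_that("two planted events give a bimodal true-Ks distribution", {
  sim <- fixture("bimodal_sim", function() {
    simulate_wgd_genome(sim_config(n_chromosomes = 13,
                                   genes_per_chromosome = 40, seed = 6))
  })
  tks <- sim$truth$duplicate_pairs$true_ks
  expect_gt(length(tks), 400)
  kd <- ks_kde(tks, bandwidth = 0.12)
  dens <- kd$density
  is_peak <- which(dens > dplyr::lag(dens, default = 0) &
                     dens > dplyr::lead(dens, default = 0))
  modes <- kd$x[is_peak][order(-dens[is_peak])][1:2]
  expect_lt(min(abs(modes - 0.61)), 0.1)
  expect_lt(min(abs(modes - 1.71)), 0.2)
})

test_that("fragmentation plants verifiable chimeric joins", {
  sim <- simulate_wgd_genome(sim_config(n_chromosomes = 4,
                                        genes_per_chromosome = 40,
                                        wgd_events = list(), seed = 9))
  clean <- fragment_and_corrupt(sim$genome, sim$truth, chimera_count = 0,
                                seed = 9)
  expect_equal(nrow(clean$truth$chimeric_joins), 0)
  expect_equal(anyDuplicated(clean$truth$scaffold_origin$scaffold_id), 0)

  bad <- fragment_and_corrupt(sim$genome, sim$truth, chimera_count = 5,
                              seed = 9)
  joins <- bad$truth$chimeric_joins
  expect_equal(nrow(joins), 5)
  seqs <- stats::setNames(bad$assembly$sequence, bad$assembly$scaffold_id)
  for (i in seq_len(nrow(joins))) {
    s <- seqs[[joins$scaffold_id[i]]]
    p <- joins$junction_position[i]
    expect_equal(substr(s, p, p), "N")
    expect_false(substr(s, p - 1, p - 1) == "N")
    expect_false(substr(s, p + 1, p + 1) == "N")
    expect_false(joins$chrom_left[i] == joins$chrom_right[i])
  }

  expect_error(fragment_and_corrupt(sim$genome, sim$truth,
                                    target_scaffold_n50 = 1e9),
               "longest chromosome")
})

test_that("proximity ordering plants reversible inversions", {
  world <- fixture("small_world", small_reconcile_world)
  sim <- world$sim
  fr <- fragment_and_corrupt(sim$genome, sim$truth, chimera_count = 0,
                             seed = 1)
  id_po <- simulate_proximity_ordering(fr$assembly, fr$truth,
                                       inversion_count = 0, seed = 1)
  expect_equal(nrow(id_po$truth$planted_inversions), 0)
  # identity ordering: order follows true position within every cluster
  base <- id_po$ordering

  inv_po <- simulate_proximity_ordering(fr$assembly, fr$truth,
                                        inversion_count = 3, seed = 1)
  plant <- inv_po$truth$planted_inversions
  expect_equal(nrow(plant), 3)
  changed <- inv_po$ordering |>
    dplyr::inner_join(base, by = "scaffold_id", suffix = c("", "_true"))
  moved <- changed$scaffold_id[changed$order_index !=
                                 changed$order_index_true |
                                 changed$orientation != changed$orientation_true]
  expect_setequal(moved, unlist(plant$scaffolds))
  # re-reversing each planted segment restores the true order
  for (k in seq_len(nrow(plant))) {
    seg <- plant$scaffolds[[k]]
    got <- changed[match(seg, changed$scaffold_id), ]
    expect_equal(got$order_index, rev(sort(got$order_index)))
    expect_equal(rev(got$order_index), got$order_index_true)
    expect_true(all(got$orientation == "-"))
  }
})

test_that("cross simulation reproduces Haldane recombination fractions", {
  g <- fixture("cross_genome", function() {
    simulate_wgd_genome(sim_config(n_chromosomes = 2,
                                   genes_per_chromosome = 20,
                                   wgd_events = list(), seed = 12))$genome
  })
  # two markers 10 cM apart, many progeny
  gt <- simulate_cross(g, n_progeny = 10000, markers_per_chromosome = 2,
                       chromosome_length_cM = 10, missing_rate = 0, seed = 1)
  rows <- which(gt$markers$chrom == "chr01")
  r_hat <- recombination_fraction(gt$calls[rows[1], ], gt$calls[rows[2], ])$r
  r_true <- (1 - exp(-0.2)) / 2
  se <- sqrt(r_true * (1 - r_true) / 10000)
  expect_lt(abs(r_hat - r_true), 3 * se)

  # markers at identical position: no recombinants
  gt0 <- simulate_cross(g, n_progeny = 200, markers_per_chromosome = 2,
                        chromosome_length_cM = 0, missing_rate = 0, seed = 2)
  rows0 <- which(gt0$markers$chrom == "chr01")
  expect_equal(recombination_fraction(gt0$calls[rows0[1], ],
                                      gt0$calls[rows0[2], ])$r, 0)

  # markers on different chromosomes assort independently (r ~ 0.5)
  cross_rows <- c(which(gt$markers$chrom == "chr01")[1],
                  which(gt$markers$chrom == "chr02")[1])
  r_free <- recombination_fraction(gt$calls[cross_rows[1], ],
                                   gt$calls[cross_rows[2], ])$r
  expect_gt(r_free, 0.45)
})

test_that("Ks mixture sampler honours weights, truncation and errors", {
  ks <- sample_ks_mixture(list(c(1.0, 0.61, 0.15)), 20000, seed = 1)
  expect_length(ks, 20000)
  expect_true(all(ks > 0))
  expect_lt(abs(mean(ks) - 0.61), 3 * 0.15 / sqrt(20000))

  expect_length(sample_ks_mixture(list(c(1, 0.5, 0.1)), 0), 0)
  expect_error(sample_ks_mixture(list(c(0.5, 0.5, 0.1), c(0.6, 1.5, 0.1)),
                                 100),
               "sum to 1")
  expect_error(sample_ks_mixture(list(c(1, 0.5, 0)), 100), "sds")
})

test_that("one seed drives everything: identical reruns, different streams", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 10,
                    wgd_events = list(), seed = 42)
  a <- simulate_wgd_genome(cfg)
  b <- simulate_wgd_genome(cfg)
  expect_identical(a$genome$genes, b$genome$genes)
  c2 <- simulate_wgd_genome(sim_config(n_chromosomes = 2,
                                       genes_per_chromosome = 10,
                                       wgd_events = list(), seed = 43))
  expect_false(identical(a$genome$genes$cds, c2$genome$genes$cds))
})
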