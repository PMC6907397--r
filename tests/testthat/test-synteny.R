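# gene tables and hit tables built directly for chaining tests
toy_genes <- function(n, chrom = "c1") {
  tibble::tibble(gene_id = sprintf("%s_g%03d", chrom, 1:n), chrom = chrom,
                 order_index = 1:n,
                 start = (1:n) * 1000L, end = (1:n) * 1000L + 500L,
                 strand = "+")
}

diag_hits <- function(ga, gb, ia, ib) {
  tibble::tibble(gene_a = ga$gene_id[ia], gene_b = gb$gene_id[ib],
                 score = 100, evalue = 1e-20)
}

test_that("anchor filtering applies the e-value cutoff and de-duplication", {
  ga <- toy_genes(10)
  hits <- tibble::tibble(
    gene_a = c("c1_g001", "c1_g002", "c1_g003", "c1_g004", "c1_g001"),
    gene_b = c("c1_g005", "c1_g006", "c1_g003", "c1_g008", "c1_g005"),
    score = 100,
    evalue = c(1e-5, 1e-3, 1e-20, 1e-6, 1e-7))
  out <- filter_anchors(hits, ga)
  # 1e-5 kept, 1e-3 dropped, self-hit dropped, symmetric duplicate collapsed
  expect_equal(nrow(out), 2)
  expect_false(any(out$gene_a == out$gene_b))
  expect_equal(sum(out$gene_a == "c1_g001" & out$gene_b == "c1_g005"), 1)

  expect_error(filter_anchors(tibble::tibble(gene_a = "nope", gene_b = "c1_g001",
                                             score = 1, evalue = 1e-9), ga),
               "unknown gene")
})

test_that("chaining respects the anchor minimum and the gene-gap ceiling", {
  ga <- toy_genes(120, "c1")
  gb <- toy_genes(120, "c2")
  mk_anchor <- function(ia, ib) {
    filter_anchors(diag_hits(ga, gb, ia, ib), ga, gb)
  }

  # 10 consecutive anchors: one parallel block
  b1 <- chain_collinear_blocks(mk_anchor(1:10, 1:10))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$n_anchors, 10L)
  expect_equal(b1$orientation, "parallel")

  # 4-anchor diagonal: below the 5-anchor minimum, no block
  expect_equal(nrow(chain_collinear_blocks(mk_anchor(1:4, 1:4))), 0)

  # two 5-anchor diagonals separated by > 40 genes never merge
  ia <- c(1:5, 48:52)
  b2 <- chain_collinear_blocks(mk_anchor(ia, ia))
  expect_equal(nrow(b2), 2)
  expect_true(all(b2$n_anchors == 5))

  # the same pattern with a small gap merges (gap penalty < anchor gain)
  ia3 <- c(1:5, 8:12)
  b3 <- chain_collinear_blocks(mk_anchor(ia3, ia3))
  expect_equal(nrow(b3), 1)
  expect_equal(b3$n_anchors, 10L)

  # antiparallel block: descending order on side b
  b4 <- chain_collinear_blocks(mk_anchor(1:8, 8:1))
  expect_equal(nrow(b4), 1)
  expect_equal(b4$orientation, "antiparallel")

  # no anchors, no blocks
  expect_equal(nrow(chain_collinear_blocks(mk_anchor(integer(0), integer(0)))), 0)
})

test_that("chain scores equal the exhaustive-enumeration optimum", {
  ga <- toy_genes(60, "c1")
  gb <- toy_genes(60, "c2")
  set.seed(41)
  for (trial in 1:5) {
    n <- sample(6:10, 1)
    ia <- sort(sample(1:30, n))
    ib <- sample(1:30, n)
    anch <- filter_anchors(diag_hits(ga, gb, ia, ib), ga, gb)
    blocks <- chain_collinear_blocks(anch, min_anchors = 2)
    oracle <- oracle_best_chain(ia, ib)
    if (oracle$len >= 2) {
      expect_equal(max(blocks$score), oracle$score, tolerance = 1e-9)
    } else {
      expect_equal(nrow(blocks), 0)
    }
  }
})

test_that("cross-genome blocks are symmetric in the comparison direction", {
  ga <- toy_genes(50, "c1")
  gb <- toy_genes(50, "c2")
  ia <- c(2:11, 30:36)
  ib <- c(5:14, 36:30)
  ab <- chain_collinear_blocks(filter_anchors(diag_hits(ga, gb, ia, ib),
                                              ga, gb))
  ba <- chain_collinear_blocks(filter_anchors(
    tibble::tibble(gene_a = gb$gene_id[ib], gene_b = ga$gene_id[ia],
                   score = 100, evalue = 1e-20), gb, ga))
  expect_equal(nrow(ab), nrow(ba))
  key <- function(b) {
    o <- order(b$n_anchors)
    paste(b$n_anchors[o], b$orientation[o])
  }
  expect_equal(key(ab), key(ba))
  # canonical sides make the two directions identical span for span
  expect_setequal(ab$start_a, ba$start_a)
  expect_setequal(ab$start_b, ba$start_b)
})

test_that("tightening chain thresholds never adds anchors to blocks", {
  ga <- toy_genes(100, "c1")
  gb <- toy_genes(100, "c2")
  set.seed(51)
  anchors_in_blocks <- function(blocks) {
    if (nrow(blocks) == 0) return(0L)
    sum(blocks$n_anchors)
  }
  for (trial in 1:3) {
    n <- 40
    ia <- sort(sample(1:100, n))
    ib <- sample(1:100, n)
    anch <- filter_anchors(diag_hits(ga, gb, ia, ib), ga, gb)
    base <- anchors_in_blocks(chain_collinear_blocks(anch, max_gap_genes = 40,
                                                     min_anchors = 5))
    tighter_gap <- anchors_in_blocks(
      chain_collinear_blocks(anch, max_gap_genes = 15, min_anchors = 5))
    higher_min <- anchors_in_blocks(
      chain_collinear_blocks(anch, max_gap_genes = 40, min_anchors = 8))
    expect_lte(tighter_gap, base)
    expect_lte(higher_min, base)
  }
})

test_that("windowed syntenic depth counts overlapping homologous regions", {
  world <- fixture("depth_world", function() {
    cfg <- sim_config(n_chromosomes = 6, genes_per_chromosome = 100,
                      wgd_events = list(), seed = 1)
    sim <- simulate_wgd_genome(cfg)
    duplicate_segment(sim$genome, sim$truth, chrom = "chr01",
                      start_gene = 20, n_genes = 30,
                      to_chroms = paste0("chr0", 2:6),
                      retention = 0.8, ks = 0.6, seed = 1)
  })
  anch <- filter_anchors(truth_anchors(world$truth, world$genome),
                         world$genome$genes)
  blocks <- chain_collinear_blocks(anch)
  dep <- syntenic_depth(blocks, world$genome$genes)
  expect_equal(max(dep$windows$depth), 5)
  by_chr <- dep$by_chromosome
  expect_equal(by_chr$max_depth[by_chr$chrom == "chr01"], 5)
  expect_true(all(by_chr$max_depth[by_chr$chrom != "chr01"] == 1))
  expect_true(all(dep$histogram$fraction >= 0 & dep$histogram$fraction <= 1))
  expect_equal(sum(dep$histogram$fraction), 1)

  # no blocks: all depths zero
  dep0 <- syntenic_depth(blocks[0, ], world$genome$genes)
  expect_true(all(dep0$windows$depth == 0))
})

test_that("syntenic coverage is the anchored-gene length fraction", {
  genes <- toy_genes(20)
  # equal-length genes, half of them anchored through one block
  fake_block <- tibble::tibble(
    block_id = "b1", chrom_a = "c1", chrom_b = "c1",
    orientation = "parallel", n_anchors = 5L, score = 50,
    start_a = 1L, end_a = 10L, start_b = 1L, end_b = 10L,
    order_span_a = list(c(1, 5)), order_span_b = list(c(6, 10)),
    anchors = list(tibble::tibble(gene_a = genes$gene_id[1:5],
                                  gene_b = genes$gene_id[6:10])))
  expect_equal(syntenic_coverage(fake_block, genes), 0.5)
  expect_equal(syntenic_coverage(fake_block[0, ], genes), 0)
  all_in <- fake_block
  all_in$anchors <- list(tibble::tibble(gene_a = genes$gene_id,
                                        gene_b = genes$gene_id))
  expect_equal(syntenic_coverage(all_in, genes), 1)
  expect_error(syntenic_coverage(fake_block, genes[0, ]), "zero total")
})

test_that("planted WGD segments are recovered as syntenic blocks", {
  sim <- fixture("synteny_wgd", function() {
    simulate_wgd_genome(sim_config(
      n_chromosomes = 4, genes_per_chromosome = 60,
      wgd_events = list(list(ks_mean = 0.6, ks_sd = 0.1,
                             retention_rate = 0.8)),
      seed = 19))
  })
  anch <- filter_anchors(truth_anchors(sim$truth, sim$genome),
                         sim$genome$genes)
  blocks <- chain_collinear_blocks(anch)
  # each duplicated chromosome arm of >= 10 retained genes yields a block
  expect_gte(nrow(blocks), 4)
  anchored <- unique(unlist(purrr::map(blocks$anchors, function(a) {
    c(a$gene_a, a$gene_b)
  })))
  dup_genes <- unique(c(sim$truth$duplicate_pairs$gene_a,
                        sim$truth$duplicate_pairs$gene_b))
  expect_gte(mean(dup_genes %in% anchored), 0.9)
})
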