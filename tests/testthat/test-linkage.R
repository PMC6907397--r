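test_that("marker call-rate filter applies the at-least-90% rule inclusively", {
  n <- 110
  make_row <- function(n_called) {
    c(rep("a", n_called), rep("-", n - n_called))
  }
  calls <- rbind(make_row(99), make_row(98), make_row(0))
  rownames(calls) <- c("keep_99", "drop_98", "drop_0")
  gt <- gt_from_calls(calls)
  out <- filter_markers(gt, 0.90)
  # 99/110 = 0.9 exactly meets "at least 90%"; 98/110 falls below
  expect_equal(rownames(out$calls), "keep_99")

  # het_parent flag drops homozygous-parent markers
  gt2 <- gt_from_calls(rbind(make_row(110), make_row(110)))
  gt2$markers$het_parent <- c(TRUE, FALSE)
  expect_equal(nrow(filter_markers(gt2)$calls), 1)
})

test_that("recombination fraction is phase-resolved over complete pairs", {
  x <- rep(c("a", "b"), 5)
  expect_equal(recombination_fraction(x, x)$r, 0)

  y <- x
  y[1] <- ifelse(x[1] == "a", "b", "a")
  est <- recombination_fraction(x, y)
  expect_equal(est$r, 0.1)
  expect_equal(est$n_informative, 10)

  # fully complementary vectors are completely linked in repulsion
  comp <- ifelse(x == "a", "b", "a")
  expect_equal(recombination_fraction(x, comp)$r, 0)

  # missing entries shrink the informative count, never count as recombinant
  z <- x
  z[1:3] <- "-"
  est2 <- recombination_fraction(x, z)
  expect_equal(est2$n_informative, 7)
  expect_equal(est2$r, 0)

  all_missing <- rep("-", 10)
  expect_true(is.na(recombination_fraction(x, all_missing)$r))
})

test_that("Haldane distance matches its closed form and inverts the simulator", {
  expect_equal(haldane_distance(0), 0)
  expect_equal(haldane_distance(0.25), -50 * log(0.5))
  expect_equal(haldane_distance(0.25), 34.657, tolerance = 1e-4)
  expect_error(haldane_distance(0.5), "unlinked")

  # round trip with the simulator's map function, d = -50 ln(1 - 2r)
  d <- c(0.5, 5, 20, 80, 150)
  expect_equal(haldane_distance(haldane_fraction(d)), d, tolerance = 1e-9)
  r <- c(0, 0.05, 0.2, 0.45)
  expect_equal(haldane_fraction(haldane_distance(r)), r, tolerance = 1e-9)
})

test_that("marker grouping recovers planted chromosomes and degenerate cases", {
  world <- fixture("two_chrom_cross", function() {
    cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 50,
                      wgd_events = list(), seed = 4)
    sim <- simulate_wgd_genome(cfg)
    simulate_cross(sim$genome, n_progeny = 110,
                   markers_per_chromosome = 30, seed = 4)
  })
  grp <- group_markers(filter_markers(world))
  expect_equal(grp$n_groups, 2)
  truth_chrom <- world$markers$chrom[match(grp$groups$marker_id,
                                           world$markers$marker_id)]
  expect_equal(length(unique(paste(grp$groups$lg_id, truth_chrom))), 2)

  # all-identical vectors form a single group
  calls <- calls_from_strings(rep(paste(rep(c("a", "b"), 10), collapse = ""), 5))
  grp2 <- group_markers(gt_from_calls(calls))
  expect_equal(grp2$n_groups, 1)
  expect_equal(nrow(grp2$groups), 5)
})

test_that("completely linked markers collapse into consensus blocks", {
  p1 <- paste(rep(c("a", "b"), 10), collapse = "")
  p2 <- paste(rep(c("b", "a"), 10), collapse = "")  # phase flip of p1
  p3 <- paste(c(rep("a", 10), rep("b", 10)), collapse = "")
  calls <- calls_from_strings(c(p1, p2, p1, p3, p3))
  gt <- gt_from_calls(calls)
  coll <- collapse_blocks(gt, rownames(calls))
  # p1/p2/p1 co-segregate (p2 by phase flip); p3 pair is the second block
  expect_equal(length(unique(coll$blocks$block_id)), 2)
  sizes <- sort(table(coll$blocks$block_id))
  expect_equal(unname(as.integer(sizes)), c(2, 3))

  # one crossover in one progeny separates two blocks
  q1 <- paste(rep("a", 10), collapse = "")
  q2 <- paste(c(rep("a", 9), "b"), collapse = "")
  coll2 <- collapse_blocks(gt_from_calls(calls_from_strings(c(q1, q2))),
                           c("m01", "m02"))
  expect_equal(length(unique(coll2$blocks$block_id)), 2)

  # all distinct vectors: one block per marker
  set.seed(2)
  distinct <- vapply(1:4, function(i) {
    paste(sample(c("a", "b"), 40, TRUE), collapse = "")
  }, character(1))
  coll3 <- collapse_blocks(gt_from_calls(calls_from_strings(distinct)),
                           sprintf("m%02d", 1:4))
  expect_equal(length(unique(coll3$blocks$block_id)), 4)
})

test_that("block ordering matches the exhaustive oracle and planted maps", {
  # single block sits at 0 cM
  calls <- calls_from_strings(paste(rep("a", 20), collapse = ""))
  coll <- collapse_blocks(gt_from_calls(calls), "m01")
  ord <- order_blocks(coll)
  expect_equal(ord$position_cM, 0)

  # randomized small instances: Held-Karp order equals exhaustive minimum
  set.seed(31)
  for (trial in 1:5) {
    n_blocks <- sample(3:6, 1)
    pat <- matrix(sample(c("a", "b"), n_blocks * 60, TRUE), nrow = n_blocks)
    rownames(pat) <- sprintf("blk_%02d", seq_len(n_blocks))
    fake <- list(patterns = pat)
    ord <- order_blocks(fake)
    D <- wgdmap:::pairwise_linkage(pat)$r
    path <- match(ord$block_id, rownames(pat))
    achieved <- sum(D[cbind(path[-n_blocks], path[-1])])
    expect_equal(achieved, oracle_best_order(D), tolerance = 1e-12)
  }

  # planted blocks at 0/10/20/30 cM come back in order (or reversed)
  sim <- fixture("order_sim", function() {
    cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 30,
                      wgd_events = list(), seed = 8)
    g <- simulate_wgd_genome(cfg)$genome
    simulate_cross(g, n_progeny = 400, markers_per_chromosome = 4,
                   chromosome_length_cM = 30, missing_rate = 0, seed = 8)
  })
  coll <- collapse_blocks(sim, sim$markers$marker_id)
  ord <- order_blocks(coll)
  first_marker <- coll$blocks$marker_id[match(ord$block_id,
                                              coll$blocks$block_id)]
  pos <- sim$markers$position_cM[match(first_marker, sim$markers$marker_id)]
  expect_true(all(diff(pos) > 0) || all(diff(pos) < 0))
})

test_that("full linkage map pipeline maps filtered markers into ordered blocks", {
  world <- fixture("small_world", small_reconcile_world)
  lmap <- build_linkage_map(world$gt)
  expect_equal(length(unique(lmap$lg_id)), 6)
  expect_true(all(c("lg_id", "block_index", "position_cM", "marker_id",
                    "scaffold_id", "scaffold_position") %in% names(lmap)))
  # positions are non-decreasing within each group in block order
  lm2 <- lmap[order(lmap$lg_id, lmap$block_index), ]
  for (sub in split(lm2, lm2$lg_id)) {
    expect_true(all(diff(sub$position_cM) >= -1e-9))
  }
})
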