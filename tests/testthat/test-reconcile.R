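make_lmap <- function(...) {
  tibble::tribble(...)
}

test_that("scaffold anchoring assigns clean scaffolds and records conflicts", {
  lmap <- make_lmap(
    ~lg_id, ~block_index, ~position_cM, ~marker_id, ~scaffold_id, ~scaffold_position,
    "LG02", 1L, 0,  "m1", "scfA", 100L,
    "LG02", 2L, 5,  "m2", "scfA", 900L,
    "LG02", 3L, 9,  "m3", "scfA", 1500L,
    "LG02", 4L, 12, "m4", "scfB", 200L,
    "LG07", 1L, 0,  "m5", "scfB", 4000L
  )
  res <- assign_scaffolds_to_lgs(lmap)
  expect_equal(res$assignment$lg_id[res$assignment$scaffold_id == "scfA"],
               "LG02")
  expect_equal(unique(res$conflicts$scaffold_id), "scfB")
  expect_setequal(res$conflicts$lg_id, c("LG02", "LG07"))
  # coordinate ranges carried for the splitter
  expect_equal(res$conflicts$start[res$conflicts$lg_id == "LG02"], 200L)
})

test_that("chimeric scaffolds split at a lone N, preferring it over runs", {
  left <- strrep("ACGT", 250)   # 1000 bp
  right <- strrep("GTCA", 250)  # 1000 bp
  conflict <- tibble::tibble(scaffold_id = "chi", lg_id = c("LG01", "LG02"),
                             start = c(50, 1400), end = c(900, 1900),
                             n_markers = c(3L, 3L))

  # exactly one lone N in the boundary interval
  seq1 <- paste0(left, "N", right)
  res <- split_chimeric_scaffold("chi", seq1, conflict)
  expect_true(res$report$resolved)
  expect_equal(res$subscaffolds$scaffold_id, c("chi_1", "chi_2"))
  expect_equal(res$subscaffolds$sequence, c(left, right))
  expect_equal(res$subscaffolds$lg_id, c("LG01", "LG02"))
  expect_equal(res$report$cut_positions[[1]], 1001)

  # no N anywhere in the interval: unresolved, no split
  seq2 <- paste0(left, "GG", right)
  res2 <- split_chimeric_scaffold("chi", seq2, conflict)
  expect_false(res2$report$resolved)
  expect_equal(nrow(res2$subscaffolds), 1)

  # a lone N is preferred over a 50-N run that comes first
  seq3 <- paste0(substr(left, 1, 950), strrep("N", 50), "ACGTACGTAC", "N",
                 right)
  conflict3 <- conflict
  conflict3$end[1] <- 900
  conflict3$start[2] <- 1100
  res3 <- split_chimeric_scaffold("chi", seq3, conflict3)
  expect_true(res3$report$resolved)
  cut <- res3$report$cut_positions[[1]]
  expect_equal(substr(seq3, cut, cut), "N")
  expect_equal(cut, 1011)  # the lone N, not the run midpoint

  # the junction N is removed from both pieces
  expect_false(grepl("N", paste(res$subscaffolds$sequence, collapse = "")))
})

test_that("cluster-LG matching maximises shared bp with reported purity", {
  lens <- tibble::tibble(scaffold_id = sprintf("s%02d", 1:12),
                         length = rep(1000L, 12))
  ordering <- tibble::tibble(
    scaffold_id = sprintf("s%02d", 1:12),
    cluster_id = rep(c("c1", "c2", "c3"), each = 4),
    order_index = rep(1:4, 3), orientation = "+")
  # identical partition up to labels
  assignment <- tibble::tibble(
    scaffold_id = sprintf("s%02d", 1:12),
    lg_id = rep(c("LGb", "LGc", "LGa"), each = 4))
  res <- map_clusters_to_lgs(ordering, assignment, lens)
  expect_equal(res$lg_id[match(c("c1", "c2", "c3"), res$cluster_id)],
               c("LGb", "LGc", "LGa"))
  expect_true(all(res$purity == 1))

  # brute-force optimal assignment check on random shared-bp matrices
  set.seed(17)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (trial in 1:4) {
    W <- matrix(runif(16), 4, 4)
    got <- wgdmap:::assignment_max(W)
    got_val <- sum(W[cbind(1:4, got)])
    best <- max(vapply(perms(1:4), function(p) sum(W[cbind(1:4, p)]),
                       numeric(1)))
    expect_equal(got_val, best, tolerance = 1e-12)
  }

  # 60/40 bp split maps to the majority LG with purity 0.6
  ord2 <- tibble::tibble(scaffold_id = paste0("t", 1:5), cluster_id = "c1",
                         order_index = 1:5, orientation = "+")
  asg2 <- tibble::tibble(scaffold_id = paste0("t", 1:5),
                         lg_id = c("LG1", "LG1", "LG1", "LG2", "LG2"))
  res2 <- map_clusters_to_lgs(ord2, asg2,
                              tibble::tibble(scaffold_id = paste0("t", 1:5),
                                             length = rep(1000L, 5)))
  expect_equal(res2$lg_id, "LG1")
  expect_equal(res2$purity, 0.6)
})

test_that("ordering concordance equals the pair-counting oracle", {
  expect_equal(wgdmap:::kendall_tau_b(1:10, 1:10), 1)
  expect_equal(wgdmap:::kendall_tau_b(1:10, 10:1), -1)

  set.seed(23)
  for (trial in 1:5) {
    n <- sample(8:20, 1)
    x <- sample(n)
    y <- sample(seq_len(n %/% 2), n, replace = TRUE)  # heavy ties
    expect_equal(wgdmap:::kendall_tau_b(x, y), oracle_tau_b(x, y),
                 tolerance = 1e-12)
  }
  # tie-free case agrees with the standard implementation
  x <- sample(30); y <- sample(30)
  expect_equal(wgdmap:::kendall_tau_b(x, y),
               unname(cor(x, y, method = "kendall")), tolerance = 1e-12)

  # one reversed 4-scaffold segment in a 20-scaffold group
  po_rank <- 1:20
  lg_rank <- 1:20
  lg_rank[8:11] <- 11:8
  expect_equal(wgdmap:::kendall_tau_b(po_rank, lg_rank),
               oracle_tau_b(po_rank, lg_rank), tolerance = 1e-12)
})

test_that("inversion detection flags planted reversals, never rank ties", {
  ordering <- tibble::tibble(
    scaffold_id = sprintf("s%02d", 1:10), cluster_id = "c1",
    order_index = 1:10, orientation = "+")
  lmap <- tibble::tibble(
    lg_id = "LG01", block_index = 1:10, position_cM = seq(0, 45, 5),
    marker_id = sprintf("mk%02d", 1:10),
    scaffold_id = sprintf("s%02d", 1:10),
    scaffold_position = 100L)
  corr <- tibble::tibble(cluster_id = "c1", lg_id = "LG01")

  expect_equal(nrow(detect_inversions(ordering, lmap, corr)), 0)

  # plant a reversal of s04..s06 in the proximity order
  ord_inv <- ordering
  ord_inv$order_index[4:6] <- 6:4
  inv <- detect_inversions(ord_inv, lmap, corr)
  expect_equal(nrow(inv), 1)
  expect_setequal(inv$scaffolds[[1]], c("s04", "s05", "s06"))

  # two scaffolds sharing one linkage block are not evidence of inversion
  lmap_tie <- lmap
  lmap_tie$block_index[4:5] <- 4L
  ord_swap <- ordering
  ord_swap$order_index[4:5] <- c(5, 4)
  expect_equal(nrow(detect_inversions(ord_swap, lmap_tie, corr)), 0)
})

test_that("reconciliation corrects planted errors end to end", {
  world <- fixture("small_world", small_reconcile_world)
  lmap <- fixture("small_world_lmap", function() build_linkage_map(world$gt))
  rec <- reconcile(world$ordering, lmap, world$assembly)

  # every planted chimera is split within 1 kb of the true junction
  joins <- world$truth$chimeric_joins
  splits <- rec$split_report
  expect_true(all(splits$resolved))
  hit <- vapply(seq_len(nrow(joins)), function(i) {
    k <- match(joins$scaffold_id[i], splits$scaffold_id)
    if (is.na(k)) return(FALSE)
    any(abs(splits$cut_positions[[k]] - joins$junction_position[i]) <= 1000)
  }, logical(1))
  expect_true(all(hit))

  # all planted multiscaffold inversions are corrected: concordance perfect
  expect_true(all(rec$concordance$tau == 1))
  expect_equal(nrow(rec$inversions),
               nrow(world$truth$planted_inversions))

  # tier accounting conserves scaffold count and bp
  total_row <- function(s) rec$accounting$value[rec$accounting$statistic == s]
  expect_equal(total_row("Total scaffolds in final assembly"),
               nrow(rec$scaffolds))
  expect_equal(total_row("Total bp clustered") +
                 total_row("Total bp unclustered"),
               sum(rec$scaffolds$length))

  # idempotence: reconciling the corrected output changes nothing
  ord2 <- rec$scaffolds |>
    dplyr::filter(!is.na(.data$lg_id)) |>
    dplyr::select("scaffold_id", "cluster_id", order_index = "rank",
                  "orientation")
  rec2 <- reconcile(ord2, rec$linkage_map, rec$assembly)
  expect_equal(nrow(rec2$inversions), 0)
  expect_equal(sum(rec2$split_report$resolved), 0)
  expect_true(all(rec2$concordance$tau == 1))
})

test_that("planted-error recovery holds across seeds", {
  n_seeds <- 6
  junction_ok <- 0
  junction_all <- 0
  inversions_ok <- TRUE
  for (seed in seq_len(n_seeds)) {
    w <- small_reconcile_world(seed = seed + 100, chimera_count = 6,
                               inversion_count = 2)
    lmap <- build_linkage_map(w$gt)
    rec <- reconcile(w$ordering, lmap, w$assembly)
    joins <- w$truth$chimeric_joins
    junction_all <- junction_all + nrow(joins)
    junction_ok <- junction_ok + sum(vapply(seq_len(nrow(joins)), function(i) {
      k <- match(joins$scaffold_id[i], rec$split_report$scaffold_id)
      !is.na(k) && rec$split_report$resolved[k] &&
        any(abs(rec$split_report$cut_positions[[k]] -
                  joins$junction_position[i]) <= 1000)
    }, logical(1)))
    inversions_ok <- inversions_ok && all(rec$concordance$tau == 1)
  }
  expect_gte(junction_ok / junction_all, 0.95)
  expect_true(inversions_ok)
})
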