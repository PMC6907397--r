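# Pseudo-testcross linkage analysis: marker filtering, pairwise recombination
# fractions with phase resolution, LOD-gated grouping into linkage groups,
# collapse of completely linked markers into blocks, and block ordering by
# minimum adjacent recombination with cumulative Haldane positions.

#' Filter markers by call rate
#'
#' Retains markers genotyped in at least `min_call_rate` of the progeny
#' (default 90%, the conventional pseudo-testcross inclusion rule). If the
#' marker table carries a logical `het_parent` column, markers not flagged
#' heterozygous in the mapping parent are dropped as uninformative.
#'
#' @param gt A `genotype_table`.
#' @param min_call_rate Minimum fraction of non-missing calls.
#' @return Filtered `genotype_table`.
#' @export
filter_markers <- function(gt, min_call_rate = 0.90) {
  assert_that(min_call_rate > 0 && min_call_rate <= 1,
              "min_call_rate must lie in (0, 1]")
  called <- rowMeans(gt$calls != "-")
  keep <- called >= min_call_rate
  if ("het_parent" %in% names(gt$markers)) {
    keep <- keep & gt$markers$het_parent
  }
  gt$markers <- gt$markers[keep, , drop = FALSE]
  gt$calls <- gt$calls[keep, , drop = FALSE]
  gt
}

# Pairwise recombination fractions, informative counts and LOD scores for all
# marker pairs at once (phase-unknown: r = min(m, n-m)/n). Returns matrices.
pairwise_linkage <- function(calls) {
  A <- (calls == "a") * 1
  B <- (calls == "b") * 1
  M <- (calls != "-") * 1
  n_inf <- M %*% t(M)
  disc <- A %*% t(B) + B %*% t(A)
  m <- pmin(disc, n_inf - disc)
  r <- ifelse(n_inf > 0, m / n_inf, NA_real_)
  # LOD of linkage at r-hat vs independence (r = 0.5)
  r_safe <- pmin(pmax(r, 1e-12), 0.5)
  lod <- m * log10(r_safe) + (n_inf - m) * log10(1 - r_safe) +
    n_inf * log10(2)
  lod[n_inf == 0] <- NA_real_
  list(r = r, lod = lod, n_informative = n_inf, m = m)
}

#' Recombination fraction between two genotype vectors
#'
#' Phase-unknown pseudo-testcross estimate over pairwise-complete entries:
#' with `m` discordant calls among `n` informative progeny,
#' `r = min(m, n - m) / n` (the `min` resolves the unknown linkage phase).
#'
#' @param x,y Character vectors over `"a"`, `"b"`, `"-"` of equal length.
#' @return One-row tibble `r`, `n_informative`, `lod`; `r` is `NA` when no
#'   informative pair exists.
#' @export
recombination_fraction <- function(x, y) {
  assert_that(length(x) == length(y),
              "recombination_fraction(): vectors must have equal length")
  pl <- pairwise_linkage(rbind(x, y))
  tibble(r = pl$r[1, 2], n_informative = pl$n_informative[1, 2],
         lod = pl$lod[1, 2])
}

#' Haldane map distance from a recombination fraction
#'
#' `d = -50 * ln(1 - 2r)` centimorgans; the inverse of the no-interference
#' recombination model used by the cross simulator.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Distance(s) in cM.
#' @export
haldane_distance <- function(r) {
  assert_that(all(r >= 0 & r < 0.5),
              "haldane_distance(): r must lie in [0, 0.5) (r >= 0.5 is unlinked)")
  -50 * log(1 - 2 * r)
}

#' Recombination fraction implied by a Haldane map distance
#'
#' @param d Distance(s) in cM.
#' @return Recombination fraction(s).
#' @export
haldane_fraction <- function(d) {
  (1 - exp(-2 * d / 100)) / 2
}

#' Group markers into linkage groups
#'
#' Builds a graph with an edge between two markers when their pairwise
#' recombination fraction is at most `r_max` *and* the LOD for linkage is at
#' least `lod_min`; linkage groups are the connected components. With many
#' markers the number of unlinked pairs tested is large enough that a few
#' spurious edges pass any per-pair threshold, so an edge is additionally
#' required to be corroborated by a common neighbour whenever both endpoints
#' have other links (triangle support): a genuine within-chromosome edge
#' shares many neighbours, a chance edge between chromosomes shares none.
#' Singleton markers are reported separately rather than counted as groups.
#'
#' `lod_min` is a comparison-wise threshold: because all marker pairs are
#' tested, it is applied genome-wide by adding `log10(n_pairs)` (a Bonferroni
#' correction on the likelihood-ratio scale) when `genomewide = TRUE`, so that
#' the expected number of chance edges stays below one regardless of marker
#' count.
#'
#' @param gt A filtered `genotype_table`.
#' @param r_max Maximum recombination fraction for an edge.
#' @param lod_min Minimum (comparison-wise) LOD score for an edge.
#' @param triangle_support Require common-neighbour corroboration (default
#'   `TRUE`).
#' @param genomewide Apply the multiple-testing correction to `lod_min`
#'   (default `TRUE`).
#' @return List: `groups` tibble (`marker_id`, `lg_id`), `singletons`
#'   character vector, `n_groups`.
#' @export
group_markers <- function(gt, r_max = 0.35, lod_min = 3.0,
                          triangle_support = TRUE, genomewide = TRUE) {
  pl <- pairwise_linkage(gt$calls)
  n_mark <- nrow(gt$calls)
  lod_eff <- lod_min +
    if (genomewide && n_mark > 2) log10(choose(n_mark, 2)) else 0
  adj <- !is.na(pl$r) & pl$r <= r_max & pl$lod >= lod_eff
  diag(adj) <- FALSE
  if (triangle_support && nrow(adj) > 2) {
    a_num <- adj * 1
    common <- a_num %*% a_num
    deg <- rowSums(a_num)
    uncorroborated <- adj & common == 0 &
      outer(deg > 1, deg > 1, "&")
    adj <- adj & !uncorroborated
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  ids <- gt$markers$marker_id
  keep <- sizes > 1
  # stable lg ids ordered by component size (largest first)
  big <- sort(unique(comp$membership[keep]))
  size_order <- big[order(-comp$csize[big])]
  lg_of <- setNames(sprintf("LG%02d", seq_along(size_order)), size_order)
  list(
    groups = tibble(marker_id = ids[keep],
                    lg_id = unname(lg_of[as.character(comp$membership[keep])])),
    singletons = ids[!keep],
    n_groups = length(size_order)
  )
}

#' Collapse completely linked markers into blocks
#'
#' Markers within a linkage group with zero observed recombinants among
#' informative progeny (r = 0) are merged into one block; each block's
#' segregation pattern is the phase-aligned majority consensus of its members.
#'
#' @param gt A `genotype_table`.
#' @param marker_ids Markers of one linkage group.
#' @return List: `blocks` tibble (`block_id`, `marker_id`), `patterns`
#'   character matrix (block x progeny consensus).
#' @export
collapse_blocks <- function(gt, marker_ids) {
  rows <- match(marker_ids, gt$markers$marker_id)
  assert_that(!anyNA(rows), "collapse_blocks(): unknown marker id")
  calls <- gt$calls[rows, , drop = FALSE]
  pl <- pairwise_linkage(calls)
  adj <- !is.na(pl$r) & pl$r == 0 & pl$n_informative > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  blocks <- tibble(marker_id = marker_ids,
                   block = comp) |>
    group_by(.data$block) |>
    mutate(block_id = paste0("blk_", min(.data$marker_id))) |>
    ungroup() |>
    select("block_id", "marker_id")
  patterns <- do.call(rbind, lapply(split(seq_along(marker_ids), comp),
                                    function(ix) {
    sub <- calls[ix, , drop = FALSE]
    # align phases to the first member before taking the majority call
    ref <- sub[1, ]
    if (nrow(sub) > 1) {
      for (k in 2:nrow(sub)) {
        ok <- sub[k, ] != "-" & ref != "-"
        if (sum(ok) > 0 && mean(sub[k, ok] != ref[ok]) > 0.5) {
          sub[k, ] <- chartr("ab", "ba", sub[k, ])
        }
      }
    }
    apply(sub, 2, function(col) {
      col <- col[col != "-"]
      if (length(col) == 0) "-" else names(sort(table(col), decreasing = TRUE))[1]
    })
  }))
  rownames(patterns) <- vapply(split(marker_ids, comp),
                               function(m) paste0("blk_", min(m)), character(1))
  list(blocks = blocks, patterns = patterns)
}

# exact minimum-path order by Held-Karp dynamic programming (open path TSP)
held_karp_path <- function(D) {
  n <- nrow(D)
  if (n == 1) return(1L)
  full <- bitwShiftL(1L, n) - 1L
  cost <- matrix(Inf, 2^n, n)
  parent <- matrix(NA_integer_, 2^n, n)
  for (i in seq_len(n)) cost[bitwShiftL(1L, i - 1L) + 1L, i] <- 0
  for (mask in seq_len(full)) {
    for (i in seq_len(n)) {
      if (!bitwAnd(mask, bitwShiftL(1L, i - 1L))) next
      c0 <- cost[mask + 1L, i]
      if (!is.finite(c0)) next
      for (j in seq_len(n)) {
        if (bitwAnd(mask, bitwShiftL(1L, j - 1L))) next
        nm <- bitwOr(mask, bitwShiftL(1L, j - 1L))
        nc <- c0 + D[i, j]
        if (nc < cost[nm + 1L, j]) {
          cost[nm + 1L, j] <- nc
          parent[nm + 1L, j] <- i
        }
      }
    }
  }
  last <- which.min(cost[full + 1L, ])
  path <- integer(n)
  mask <- full
  for (k in n:1) {
    path[k] <- last
    prev <- parent[mask + 1L, last]
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, last - 1L)))
    last <- prev
  }
  path
}

greedy_two_opt <- function(D) {
  n <- nrow(D)
  # nearest-neighbour construction from the endpoint of the smallest distance
  start <- which(D == min(D[upper.tri(D)]), arr.ind = TRUE)[1, 1]
  path <- start
  left <- setdiff(seq_len(n), start)
  while (length(left) > 0) {
    nxt <- left[which.min(D[path[length(path)], left])]
    path <- c(path, nxt)
    left <- setdiff(left, nxt)
  }
  path_cost <- function(p) sum(D[cbind(p[-length(p)], p[-1])])
  best <- path_cost(path)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        cand <- path
        cand[i:j] <- rev(cand[i:j])
        cc <- path_cost(cand)
        if (cc < best - 1e-12) {
          path <- cand
          best <- cc
          improved <- TRUE
        }
      }
    }
  }
  path
}

#' Order marker blocks along a linkage group
#'
#' Finds the block order minimising the sum of adjacent recombination
#' fractions: exhaustively optimal (Held-Karp dynamic programming) for up to
#' `exact_max` blocks, nearest-neighbour construction with 2-opt refinement
#' beyond that. Positions are cumulative Haldane distances from the first
#' block. The order is canonicalised so the lexicographically smaller endpoint
#' block id comes first (a linkage group and its reversal are equivalent).
#'
#' @param collapsed Output of [collapse_blocks()].
#' @param exact_max Largest block count solved exactly (default 10).
#' @return Tibble `block_index`, `block_id`, `position_cM`, `r_prev`.
#' @export
order_blocks <- function(collapsed, exact_max = 10) {
  pat <- collapsed$patterns
  n <- nrow(pat)
  if (n == 1) {
    return(tibble(block_index = 1L, block_id = rownames(pat),
                  position_cM = 0, r_prev = NA_real_))
  }
  pl <- pairwise_linkage(pat)
  D <- pl$r
  D[is.na(D)] <- 0.5
  path <- if (n <= exact_max) held_karp_path(D) else greedy_two_opt(D)
  ids <- rownames(pat)[path]
  if (ids[length(ids)] < ids[1]) {
    path <- rev(path)
    ids <- rev(ids)
  }
  r_adj <- D[cbind(path[-length(path)], path[-1])]
  r_for_pos <- pmin(r_adj, 0.49999)
  tibble(
    block_index = seq_len(n),
    block_id = ids,
    position_cM = cumsum(c(0, haldane_distance(r_for_pos))),
    r_prev = c(NA_real_, r_adj)
  )
}

#' Build a complete linkage map from a genotype table
#'
#' Convenience pipeline: [filter_markers()] then [group_markers()],
#' [collapse_blocks()] and [order_blocks()] per group.
#'
#' @param gt A `genotype_table`.
#' @param min_call_rate,r_max,lod_min Stage parameters (see the stage
#'   functions).
#' @return Tibble `lg_id`, `block_index`, `position_cM`, `marker_id`,
#'   `scaffold_id`, `scaffold_position` - one row per mapped marker.
#' @export
build_linkage_map <- function(gt, min_call_rate = 0.90, r_max = 0.35,
                              lod_min = 3.0) {
  gt <- filter_markers(gt, min_call_rate)
  grp <- group_markers(gt, r_max = r_max, lod_min = lod_min)
  purrr::map_dfr(unique(grp$groups$lg_id), function(lg) {
    ids <- grp$groups$marker_id[grp$groups$lg_id == lg]
    coll <- collapse_blocks(gt, ids)
    ord <- order_blocks(coll)
    coll$blocks |>
      left_join(ord, by = "block_id") |>
      left_join(select(gt$markers, "marker_id", "scaffold_id",
                       "scaffold_position"),
                by = "marker_id") |>
      mutate(lg_id = lg) |>
      select("lg_id", "block_index", "position_cM", "marker_id",
             "scaffold_id", "scaffold_position") |>
      arrange(.data$block_index, .data$marker_id)
  })
}
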