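# Reconciling a proximity-guided scaffold ordering with a linkage map:
# anchor scaffolds to LGs through their markers, split chimeric scaffolds at
# single-N junctions, match proximity clusters to LGs by shared bp, measure
# ordering concordance (Kendall tau-b), detect and correct multiscaffold
# inversions, and emit a tiered assembly with conservation accounting.

#' Anchor scaffolds to linkage groups via their markers
#'
#' Each scaffold is assigned to the linkage group its markers map to;
#' scaffolds whose markers hit more than one LG are reported as conflicts
#' together with the per-LG coordinate range of their markers (the evidence
#' used to split chimeras).
#'
#' @param lmap Linkage map tibble from [build_linkage_map()].
#' @return List: `assignment` tibble (`scaffold_id`, `lg_id`, `n_markers`),
#'   `conflicts` tibble (`scaffold_id`, `lg_id`, `start`, `end`, `n_markers`).
#' @export
assign_scaffolds_to_lgs <- function(lmap) {
  assert_that(!anyNA(lmap$scaffold_id),
              "assign_scaffolds_to_lgs(): marker with unknown scaffold")
  per <- lmap |>
    group_by(.data$scaffold_id, .data$lg_id) |>
    summarise(start = min(.data$scaffold_position),
              end = max(.data$scaffold_position),
              n_markers = dplyr::n(), .groups = "drop")
  n_lgs <- per |> count(.data$scaffold_id, name = "n_lg")
  clean <- per |>
    inner_join(filter(n_lgs, .data$n_lg == 1), by = "scaffold_id") |>
    select("scaffold_id", "lg_id", "n_markers")
  conflicts <- per |>
    inner_join(filter(n_lgs, .data$n_lg > 1), by = "scaffold_id") |>
    select("scaffold_id", "lg_id", "start", "end", "n_markers") |>
    arrange(.data$scaffold_id, .data$start)
  list(assignment = clean, conflicts = conflicts)
}

# lone N: an N whose neighbours are not N
find_lone_ns <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  is_n <- chars == "N"
  n <- length(chars)
  if (!any(is_n)) return(integer(0))
  prev_n <- c(FALSE, is_n[-n])
  next_n <- c(is_n[-1], FALSE)
  which(is_n & !prev_n & !next_n)
}

#' Split a chimeric scaffold at N positions between conflicting LG ranges
#'
#' For each boundary interval between adjacent per-LG marker ranges the cut is
#' placed at a lone N (an N whose neighbours are not N) when one exists -
#' single N's are the signature of misjoins in the source assemblies this
#' models - otherwise at the midpoint of the first N-run in the interval. The
#' junction N is removed from both subscaffolds. If an interval contains no N
#' at all the scaffold is left unsplit and flagged unresolved.
#'
#' @param scaffold_id Scaffold name.
#' @param sequence Scaffold sequence.
#' @param conflict Conflict rows for this scaffold from
#'   [assign_scaffolds_to_lgs()] (>= 2 LGs with disjoint coordinate ranges).
#' @return List: `subscaffolds` tibble (`scaffold_id`, `sequence`, `lg_id`,
#'   `offset` of the piece start in the original scaffold), `report` one-row
#'   tibble (`scaffold_id`, `n_pieces`, `cut_positions` list, `resolved`).
#' @export
split_chimeric_scaffold <- function(scaffold_id, sequence, conflict) {
  conflict <- arrange(conflict, .data$start)
  assert_that(nrow(conflict) >= 2,
              "split_chimeric_scaffold(): need >= 2 conflicting LG ranges")
  assert_that(all(conflict$start[-1] > conflict$end[-nrow(conflict)]),
              "split_chimeric_scaffold(): LG ranges must be disjoint")
  chars <- strsplit(toupper(sequence), "")[[1]]
  lone <- find_lone_ns(sequence)
  cuts <- integer(0)
  resolved <- TRUE
  for (k in seq_len(nrow(conflict) - 1)) {
    lo <- conflict$end[k] + 1L
    hi <- conflict$start[k + 1] - 1L
    if (hi < lo) { resolved <- FALSE; next }
    in_lone <- lone[lone >= lo & lone <= hi]
    if (length(in_lone) > 0) {
      cuts <- c(cuts, in_lone[1])
      next
    }
    seg <- substr(sequence, lo, hi)
    runs <- find_n_runs(seg, min_len = 1)
    if (nrow(runs) == 0) { resolved <- FALSE; next }
    cuts <- c(cuts, lo + as.integer((runs$start[1] + runs$end[1]) %/% 2) - 1L)
  }
  if (!resolved || length(cuts) == 0) {
    return(list(
      subscaffolds = tibble(scaffold_id = scaffold_id, sequence = sequence,
                            lg_id = NA_character_, offset = 1L),
      report = tibble(scaffold_id = scaffold_id, n_pieces = 1L,
                      cut_positions = list(integer(0)), resolved = FALSE)
    ))
  }
  bounds_start <- c(1L, cuts + 1L)
  bounds_end <- c(cuts - 1L, length(chars))
  pieces <- tibble(
    scaffold_id = sprintf("%s_%d", scaffold_id, seq_along(bounds_start)),
    sequence = substring(sequence, bounds_start, bounds_end),
    offset = bounds_start
  )
  # each piece inherits the LG of the marker ranges it contains
  piece_end <- bounds_end
  pieces$lg_id <- vapply(seq_len(nrow(pieces)), function(i) {
    inside <- conflict$start >= bounds_start[i] & conflict$end <= piece_end[i]
    if (!any(inside)) NA_character_ else conflict$lg_id[which(inside)[1]]
  }, character(1))
  list(
    subscaffolds = select(pieces, "scaffold_id", "sequence", "lg_id", "offset"),
    report = tibble(scaffold_id = scaffold_id, n_pieces = nrow(pieces),
                    cut_positions = list(cuts), resolved = TRUE)
  )
}

#' Apply chimera splitting across an assembly
#'
#' Runs [split_chimeric_scaffold()] on every conflicted scaffold and returns
#' the corrected assembly plus an updated scaffold -> LG assignment.
#'
#' @param assembly Scaffold tibble (`scaffold_id`, `sequence`).
#' @param anchoring Output of [assign_scaffolds_to_lgs()].
#' @return List: `assembly` (corrected scaffold tibble), `assignment`
#'   (tibble `scaffold_id`, `lg_id`), `split_report` tibble.
#' @export
resolve_chimeras <- function(assembly, anchoring) {
  conflicts <- anchoring$conflicts
  reports <- list()
  new_rows <- list()
  drop <- character(0)
  extra_assign <- list()
  for (sid in unique(conflicts$scaffold_id)) {
    row <- match(sid, assembly$scaffold_id)
    assert_that(!is.na(row), paste0("resolve_chimeras(): unknown scaffold ", sid))
    res <- split_chimeric_scaffold(sid, assembly$sequence[row],
                                   filter(conflicts, .data$scaffold_id == sid))
    reports[[sid]] <- res$report
    if (res$report$resolved) {
      drop <- c(drop, sid)
      new_rows[[sid]] <- res$subscaffolds
      extra_assign[[sid]] <- res$subscaffolds |>
        filter(!is.na(.data$lg_id)) |>
        select("scaffold_id", "lg_id")
    }
  }
  out <- assembly |> filter(!(.data$scaffold_id %in% drop))
  if (length(new_rows) > 0) {
    nr <- bind_rows(new_rows) |>
      mutate(length = nchar(.data$sequence)) |>
      select("scaffold_id", "sequence", "length")
    out <- bind_rows(out, nr)
  }
  assignment <- bind_rows(
    anchoring$assignment |> select("scaffold_id", "lg_id"),
    bind_rows(extra_assign)
  )
  list(assembly = out, assignment = assignment,
       split_report = if (length(reports)) bind_rows(reports) else
         tibble(scaffold_id = character(0), n_pieces = integer(0),
                cut_positions = list(), resolved = logical(0)))
}

# exact max-weight one-to-one assignment by bitmask DP over the smaller side
assignment_max <- function(W) {
  nr <- nrow(W); nc <- ncol(W)
  flip <- nr > nc
  if (flip) W <- t(W)
  n1 <- nrow(W); n2 <- ncol(W)
  full <- bitwShiftL(1L, n2) - 1L
  prev <- rep(-Inf, full + 1L); prev[1] <- 0
  back <- vector("list", n1)
  for (i in seq_len(n1)) {
    cur <- rep(-Inf, full + 1L)
    pick <- rep(NA_integer_, full + 1L)
    from <- rep(NA_integer_, full + 1L)
    for (mask in 0:full) {
      if (!is.finite(prev[mask + 1L])) next
      # leave row i unmatched
      if (prev[mask + 1L] > cur[mask + 1L]) {
        cur[mask + 1L] <- prev[mask + 1L]
        pick[mask + 1L] <- 0L
        from[mask + 1L] <- mask
      }
      for (j in seq_len(n2)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit)) next
        nm <- bitwOr(mask, bit)
        val <- prev[mask + 1L] + W[i, j]
        if (val > cur[nm + 1L]) {
          cur[nm + 1L] <- val
          pick[nm + 1L] <- j
          from[nm + 1L] <- mask
        }
      }
    }
    back[[i]] <- list(pick = pick, from = from)
    prev <- cur
  }
  mask <- which.max(prev) - 1L
  match_of <- rep(NA_integer_, n1)
  for (i in n1:1) {
    p <- back[[i]]$pick[mask + 1L]
    match_of[i] <- if (is.na(p) || p == 0L) NA_integer_ else p
    mask <- back[[i]]$from[mask + 1L]
  }
  if (flip) {
    # rows of the original matrix were columns here: invert the matching
    inv <- rep(NA_integer_, ncol(W))
    for (i in seq_along(match_of)) if (!is.na(match_of[i])) inv[match_of[i]] <- i
    return(inv)
  }
  match_of
}

#' Match proximity clusters to linkage groups by shared bp
#'
#' One-to-one correspondence maximising total shared scaffold bp (exact
#' optimal assignment); per pair the purity (shared bp / cluster bp) is
#' reported. Clusters with no overlap to any LG are returned unmatched.
#'
#' @param ordering Proximity ordering tibble (`scaffold_id`, `cluster_id`, ...).
#' @param assignment Scaffold -> LG tibble (`scaffold_id`, `lg_id`).
#' @param scaffold_lengths Tibble `scaffold_id`, `length`.
#' @return Tibble `cluster_id`, `lg_id` (NA if unmatched), `shared_bp`,
#'   `cluster_bp`, `purity`.
#' @export
map_clusters_to_lgs <- function(ordering, assignment, scaffold_lengths) {
  dat <- ordering |>
    left_join(scaffold_lengths, by = "scaffold_id") |>
    left_join(assignment, by = "scaffold_id")
  cluster_bp <- dat |>
    group_by(.data$cluster_id) |>
    summarise(cluster_bp = sum(as.numeric(.data$length)), .groups = "drop")
  shared <- dat |>
    filter(!is.na(.data$lg_id)) |>
    group_by(.data$cluster_id, .data$lg_id) |>
    summarise(shared_bp = sum(as.numeric(.data$length)), .groups = "drop")
  assert_that(nrow(shared) > 0,
              "map_clusters_to_lgs(): no scaffold assigned by both methods")
  clusters <- sort(unique(dat$cluster_id))
  lgs <- sort(unique(shared$lg_id))
  W <- matrix(0, length(clusters), length(lgs),
              dimnames = list(clusters, lgs))
  W[cbind(match(shared$cluster_id, clusters), match(shared$lg_id, lgs))] <-
    shared$shared_bp
  m <- assignment_max(W)
  res <- tibble(cluster_id = clusters,
                lg_id = ifelse(is.na(m), NA_character_, lgs[m]))
  res$shared_bp <- map_dbl(seq_len(nrow(res)), function(i) {
    if (is.na(res$lg_id[i])) 0 else W[i, res$lg_id[i]]
  })
  res$lg_id[res$shared_bp == 0] <- NA_character_
  res |>
    left_join(cluster_bp, by = "cluster_id") |>
    mutate(purity = ifelse(is.na(.data$lg_id), NA_real_,
                           .data$shared_bp / .data$cluster_bp))
}

# A linkage group and its reversal are the same map: align block ranks to the
# proximity order's direction before looking for local inversions.
align_ranks <- function(order_index, block_rank) {
  tau <- kendall_tau_b(order_index, block_rank)
  if (!is.na(tau) && tau < 0) -block_rank else block_rank
}

# Kendall tau-b by explicit pair counting (handles ties on either side)
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) {
    dx <- x[i] - x[(i + 1):n]
    dy <- y[i] - y[(i + 1):n]
    s <- sign(dx) * sign(dy)
    conc <- conc + sum(s > 0)
    disc <- disc + sum(s < 0)
    tx <- tx + sum(dx == 0 & dy != 0)
    ty <- ty + sum(dy == 0 & dx != 0)
  }
  denom <- sqrt((conc + disc + tx) * (conc + disc + ty))
  if (denom == 0) return(NA_real_)
  (conc - disc) / denom
}

# per-LG table of commonly placed scaffolds: proximity rank vs linkage block rank
shared_order_table <- function(ordering, lmap, correspondence) {
  block_rank <- lmap |>
    filter(!is.na(.data$scaffold_id)) |>
    group_by(.data$lg_id, .data$scaffold_id) |>
    summarise(block_rank = min(.data$block_index), .groups = "drop")
  ordering |>
    inner_join(select(correspondence, "cluster_id", "lg_id"),
               by = "cluster_id") |>
    filter(!is.na(.data$lg_id), !is.na(.data$order_index)) |>
    inner_join(block_rank, by = c("lg_id", "scaffold_id")) |>
    arrange(.data$lg_id, .data$order_index)
}

#' Concordance between proximity and linkage orderings
#'
#' For every LG the scaffolds placed by both methods are ranked by proximity
#' order against linkage block order (scaffolds in one block are order-tied)
#' and Kendall tau-b is computed over the comparable pairs, with the list of
#' discordant adjacent pairs.
#'
#' @param ordering Proximity ordering tibble.
#' @param lmap Linkage map tibble.
#' @param correspondence Cluster/LG correspondence from
#'   [map_clusters_to_lgs()].
#' @return Tibble `lg_id`, `n_shared`, `tau`, `discordant_adjacent` (list of
#'   scaffold-id pairs). `tau` is `NA` where < 2 scaffolds are shared.
#' @export
compare_orderings <- function(ordering, lmap, correspondence) {
  shared <- shared_order_table(ordering, lmap, correspondence)
  purrr::map_dfr(unique(correspondence$lg_id[!is.na(correspondence$lg_id)]),
                 function(lg) {
    sub <- filter(shared, .data$lg_id == lg)
    if (nrow(sub) < 2) {
      return(tibble(lg_id = lg, n_shared = nrow(sub), tau = NA_real_,
                    discordant_adjacent = list(character(0))))
    }
    tau <- kendall_tau_b(sub$order_index, sub$block_rank)
    adj_disc <- which(diff(sub$block_rank) < 0)
    disc_pairs <- map(adj_disc, function(i) sub$scaffold_id[c(i, i + 1)])
    tibble(lg_id = lg, n_shared = nrow(sub), tau = tau,
           discordant_adjacent = list(disc_pairs))
  })
}

#' Detect multiscaffold inversions of the proximity order against the map
#'
#' Maximal runs (in proximity order) of at least `min_segment` scaffolds whose
#' linkage block ranks never increase and decrease at least once; rank ties
#' (co-segregating scaffolds) never break a run but are not evidence on their
#' own. A run is reported only if reversing it strictly increases the number
#' of concordant adjacent pairs in its LG.
#'
#' @param ordering,lmap,correspondence As in [compare_orderings()].
#' @param min_segment Minimum scaffolds per inversion (default 2: single
#'   swaps are below the map's resolution).
#' @return Tibble `lg_id`, `cluster_id`, `first_order`, `last_order`,
#'   `scaffolds` (list).
#' @export
detect_inversions <- function(ordering, lmap, correspondence, min_segment = 2) {
  shared <- shared_order_table(ordering, lmap, correspondence)
  concordant_pairs <- function(ranks) sum(diff(ranks) >= 0)
  # candidate reversals for one orientation of the map: maximal non-increasing
  # runs whose reversal strictly improves adjacent concordance
  scan_runs <- function(ranks, n) {
    segs <- list()
    corrected <- ranks
    i <- 1
    while (i < n) {
      if (corrected[i + 1] <= corrected[i]) {
        j <- i + 1
        while (j < n && corrected[j + 1] <= corrected[j]) j <- j + 1
        if (j - i + 1 >= min_segment && any(diff(corrected[i:j]) < 0)) {
          trial <- corrected
          trial[i:j] <- rev(trial[i:j])
          if (concordant_pairs(trial) > concordant_pairs(corrected)) {
            segs[[length(segs) + 1L]] <- c(i, j)
            corrected <- trial
          }
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    list(segs = segs, score = concordant_pairs(corrected))
  }
  purrr::map_dfr(unique(shared$lg_id), function(lg) {
    sub <- filter(shared, .data$lg_id == lg)
    n <- nrow(sub)
    if (n < min_segment) return(tibble())
    # a linkage group and its reversal are the same map: evaluate both
    # orientations and keep the one whose corrected order is most
    # concordant (ties: fewer reversals)
    fwd <- scan_runs(sub$block_rank, n)
    rev_ <- scan_runs(-sub$block_rank, n)
    pick <- if (rev_$score > fwd$score ||
                  (rev_$score == fwd$score &&
                     length(rev_$segs) < length(fwd$segs))) rev_ else fwd
    purrr::map_dfr(pick$segs, function(ij) {
      tibble(
        lg_id = lg, cluster_id = sub$cluster_id[ij[1]],
        first_order = sub$order_index[ij[1]],
        last_order = sub$order_index[ij[2]],
        scaffolds = list(sub$scaffold_id[ij[1]:ij[2]])
      )
    })
  })
}

flip_orientation <- function(o) {
  vapply(o, function(x) switch(x, "+" = "-", "-" = "+", x), character(1))
}

#' Reconcile a proximity ordering with a linkage map
#'
#' Base order and orientation come from the proximity ordering; chimeric
#' scaffolds are split first, detected inversion segments are reversed (order
#' and orientations flipped, `?` stays `?`), and every scaffold is placed in a
#' confidence tier: `both_consistent` (ordered by both methods, no residual
#' adjacent discordance), `proximity_only` (ordered by proximity, absent from
#' the map), `clustered_unordered`, or `unclustered`.
#'
#' @param ordering Proximity ordering tibble (`scaffold_id`, `cluster_id`,
#'   `order_index` - `NA` for clustered-but-unordered scaffolds -
#'   `orientation`).
#' @param lmap Linkage map tibble from [build_linkage_map()].
#' @param assembly Scaffold tibble (`scaffold_id`, `sequence` or `length`).
#' @return List of class `reconciled_assembly`: `scaffolds` tibble (`lg_id`,
#'   `rank`, `scaffold_id`, `orientation`, `tier`), `accounting` tibble,
#'   `inversions`, `correspondence`, `concordance`, `split_report`.
#' @export
reconcile <- function(ordering, lmap, assembly) {
  if (!"length" %in% names(assembly)) {
    assembly$length <- nchar(assembly$sequence)
  }
  anchoring <- assign_scaffolds_to_lgs(lmap)
  chim <- resolve_chimeras(assembly, anchoring)
  assembly2 <- chim$assembly

  # markers on split pieces keep their block positions: remap the linkage map's
  # scaffold ids onto the split pieces by coordinate
  lmap2 <- lmap
  if (nrow(chim$split_report) > 0) {
    for (k in which(chim$split_report$resolved)) {
      sid <- chim$split_report$scaffold_id[k]
      cuts <- chim$split_report$cut_positions[[k]]
      bs <- c(1L, cuts + 1L)
      rows <- which(lmap2$scaffold_id == sid)
      piece <- findInterval(lmap2$scaffold_position[rows], bs)
      lmap2$scaffold_position[rows] <-
        lmap2$scaffold_position[rows] - bs[piece] + 1L
      lmap2$scaffold_id[rows] <- sprintf("%s_%d", sid, piece)
    }
  }
  anchoring2 <- assign_scaffolds_to_lgs(lmap2)

  # split pieces replace their parent at the parent's slot in the ordering,
  # ordered by offset
  ordering2 <- ordering
  if (nrow(chim$split_report) > 0) {
    for (k in which(chim$split_report$resolved)) {
      sid <- chim$split_report$scaffold_id[k]
      row <- which(ordering2$scaffold_id == sid)
      if (length(row) == 0) next
      n_pieces <- chim$split_report$n_pieces[k]
      piece_ids <- sprintf("%s_%d", sid, seq_len(n_pieces))
      rep_rows <- ordering2[rep(row, n_pieces), ]
      rep_rows$scaffold_id <- piece_ids
      rep_rows$order_index <- ordering2$order_index[row] +
        (seq_len(n_pieces) - 1) / n_pieces
      ordering2 <- bind_rows(ordering2[-row, ], rep_rows)
    }
    ordering2 <- ordering2 |>
      group_by(.data$cluster_id) |>
      arrange(.data$order_index, .by_group = TRUE) |>
      mutate(order_index = ifelse(is.na(.data$order_index), NA_real_,
                                  cumsum(!is.na(.data$order_index)))) |>
      ungroup()
  }

  scaffold_lengths <- select(assembly2, "scaffold_id", "length")
  correspondence <- map_clusters_to_lgs(ordering2, anchoring2$assignment,
                                        scaffold_lengths)

  # scaffolds (typically split chimera pieces) whose marker LG contradicts
  # their cluster's LG are reassigned to the cluster matching that LG; the
  # proximity data cannot order them there, so they become
  # clustered-unordered
  lg_of_cluster0 <- setNames(correspondence$lg_id, correspondence$cluster_id)
  cluster_of_lg <- setNames(correspondence$cluster_id, correspondence$lg_id)
  ordering2 <- ordering2 |>
    left_join(anchoring2$assignment, by = "scaffold_id")
  mism <- !is.na(ordering2$lg_id) &
    !is.na(lg_of_cluster0[ordering2$cluster_id]) &
    ordering2$lg_id != lg_of_cluster0[ordering2$cluster_id] &
    ordering2$lg_id %in% names(cluster_of_lg)
  ordering2$cluster_id[mism] <- unname(cluster_of_lg[ordering2$lg_id[mism]])
  ordering2$order_index[mism] <- NA_real_
  ordering2$orientation[mism] <- "?"
  ordering2 <- select(ordering2, -"lg_id") |>
    group_by(.data$cluster_id) |>
    arrange(.data$order_index, .by_group = TRUE) |>
    mutate(order_index = ifelse(is.na(.data$order_index), NA_real_,
                                cumsum(!is.na(.data$order_index)))) |>
    ungroup()

  inv <- detect_inversions(ordering2, lmap2, correspondence)

  # apply inversion corrections
  ordering3 <- ordering2
  if (nrow(inv) > 0) {
    for (k in seq_len(nrow(inv))) {
      rows <- which(ordering3$cluster_id == inv$cluster_id[k] &
                      !is.na(ordering3$order_index) &
                      ordering3$order_index >= inv$first_order[k] &
                      ordering3$order_index <= inv$last_order[k])
      rows <- rows[order(ordering3$order_index[rows])]
      ordering3$order_index[rows] <- rev(ordering3$order_index[rows])
      ordering3$orientation[rows] <- flip_orientation(ordering3$orientation[rows])
    }
  }
  concordance <- compare_orderings(ordering3, lmap2, correspondence)

  # tiers
  lg_of_cluster <- setNames(correspondence$lg_id, correspondence$cluster_id)
  shared <- shared_order_table(ordering3, lmap2, correspondence)
  unresolved <- chim$split_report$scaffold_id[!chim$split_report$resolved]
  residual_disc <- shared |>
    group_by(.data$lg_id) |>
    summarise(bad = list({
      rk <- align_ranks(.data$order_index, .data$block_rank)
      i <- which(diff(rk) < 0)
      unique(c(.data$scaffold_id[i], .data$scaffold_id[i + 1]))
    }), .groups = "drop")
  bad_scaffolds <- unique(c(unlist(residual_disc$bad), unresolved))

  placed <- ordering3 |>
    mutate(lg_id = unname(lg_of_cluster[.data$cluster_id])) |>
    mutate(tier = dplyr::case_when(
      is.na(.data$order_index) ~ "clustered_unordered",
      .data$scaffold_id %in% shared$scaffold_id &
        !(.data$scaffold_id %in% bad_scaffolds) ~ "both_consistent",
      TRUE ~ "proximity_only"
    ))
  unclustered <- assembly2 |>
    filter(!(.data$scaffold_id %in% placed$scaffold_id)) |>
    mutate(lg_id = NA_character_, cluster_id = NA_character_,
           order_index = NA_real_, orientation = "?", tier = "unclustered") |>
    select("scaffold_id", "cluster_id", "order_index", "orientation",
           "lg_id", "tier")
  scaffolds <- bind_rows(
    placed |> select("scaffold_id", "cluster_id", "order_index",
                     "orientation", "lg_id", "tier"),
    unclustered
  ) |>
    arrange(.data$lg_id, .data$order_index, .data$scaffold_id) |>
    group_by(.data$lg_id) |>
    mutate(rank = ifelse(is.na(.data$order_index), NA_integer_,
                         as.integer(rank(.data$order_index)))) |>
    ungroup() |>
    left_join(scaffold_lengths, by = "scaffold_id")

  accounting <- tibble(
    statistic = c("Clustered scaffolds", "Total bp clustered",
                  "Clustered and ordered scaffolds",
                  "Total bp clustered and ordered",
                  "Clustered and unordered scaffolds",
                  "Total bp clustered and unordered",
                  "Conservative (both methods) scaffolds",
                  "Total bp conservative",
                  "Unclustered scaffolds", "Total bp unclustered",
                  "Total scaffolds in final assembly"),
    value = c(
      sum(scaffolds$tier != "unclustered"),
      sum(scaffolds$length[scaffolds$tier != "unclustered"]),
      sum(scaffolds$tier %in% c("both_consistent", "proximity_only")),
      sum(scaffolds$length[scaffolds$tier %in%
                             c("both_consistent", "proximity_only")]),
      sum(scaffolds$tier == "clustered_unordered"),
      sum(scaffolds$length[scaffolds$tier == "clustered_unordered"]),
      sum(scaffolds$tier == "both_consistent"),
      sum(scaffolds$length[scaffolds$tier == "both_consistent"]),
      sum(scaffolds$tier == "unclustered"),
      sum(scaffolds$length[scaffolds$tier == "unclustered"]),
      nrow(scaffolds)
    )
  )

  structure(
    list(scaffolds = scaffolds, accounting = accounting, inversions = inv,
         correspondence = correspondence, concordance = concordance,
         split_report = chim$split_report, assembly = assembly2,
         linkage_map = lmap2),
    class = "reconciled_assembly"
  )
}
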