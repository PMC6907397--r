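# Collinear syntenic-block chaining (DAGChainer-style sparse dynamic
# programming on gene-order anchors), syntenic depth (SynFind-style windowed
# counting) and syntenic coverage.

#' Filter a homology hit table into anchor pairs
#'
#' Keeps hits at or below the e-value cutoff (default 1e-4, the conventional
#' discontinuous-MegaBLAST threshold for synteny screens), drops self-hits,
#' and for self-genome comparisons keeps one of each symmetric duplicate.
#' Gene coordinates and order indices are attached from the gene tables.
#'
#' @param hits Tibble `gene_a`, `gene_b`, `score`, `evalue`.
#' @param genes_a Gene table for side a (`gene_id`, `chrom`, `order_index`,
#'   `start`, `end`).
#' @param genes_b Gene table for side b; defaults to `genes_a`
#'   (self-comparison).
#' @param max_evalue E-value cutoff.
#' @return Anchor tibble with per-side `chrom_*`, `order_*`, `start_*`,
#'   `end_*` columns plus `score`.
#' @export
filter_anchors <- function(hits, genes_a, genes_b = NULL,
                           max_evalue = 1e-4) {
  self <- is.null(genes_b)
  if (self) genes_b <- genes_a
  unknown <- setdiff(c(hits$gene_a, hits$gene_b),
                     c(genes_a$gene_id, genes_b$gene_id))
  assert_that(length(unknown) == 0,
              paste0("filter_anchors(): unknown gene id(s): ",
                     paste(utils::head(unknown, 3), collapse = ", ")))
  h <- hits |>
    filter(.data$evalue <= max_evalue, .data$gene_a != .data$gene_b)
  if (self) {
    key <- paste(pmin(h$gene_a, h$gene_b), pmax(h$gene_a, h$gene_b))
    h <- h[!duplicated(key), , drop = FALSE]
    swap <- h$gene_a > h$gene_b
    tmp <- h$gene_a[swap]; h$gene_a[swap] <- h$gene_b[swap]; h$gene_b[swap] <- tmp
  }
  ga <- genes_a |>
    select(gene_a = "gene_id", chrom_a = "chrom", order_a = "order_index",
           start_a = "start", end_a = "end")
  gb <- genes_b |>
    select(gene_b = "gene_id", chrom_b = "chrom", order_b = "order_index",
           start_b = "start", end_b = "end")
  h |>
    inner_join(ga, by = "gene_a") |>
    inner_join(gb, by = "gene_b")
}

#' Anchors from simulation truth
#'
#' Builds a perfect (optionally noised) anchor table from the truth
#' `duplicate_pairs` of a simulated genome, so chaining can be exercised
#' without any sequence-search dependency. False-positive anchors connect
#' random gene pairs at the given rate.
#'
#' @param truth A `wgd_truth`.
#' @param genome A `wgd_genome` (or a gene table).
#' @param fp_rate False anchors as a fraction of true anchors.
#' @param seed Integer seed (used only when `fp_rate > 0`).
#' @return Hit tibble `gene_a`, `gene_b`, `score`, `evalue`.
#' @export
truth_anchors <- function(truth, genome, fp_rate = 0, seed = 1) {
  genes <- if (inherits(genome, "wgd_genome")) genome$genes else genome
  hits <- truth$duplicate_pairs |>
    filter(.data$gene_a %in% genes$gene_id, .data$gene_b %in% genes$gene_id) |>
    mutate(score = 100, evalue = 1e-50) |>
    select("gene_a", "gene_b", "score", "evalue")
  if (fp_rate > 0 && nrow(hits) > 0) {
    with_seed(derive_seed(seed, 6L), {
      n_fp <- rpois(1, fp_rate * nrow(hits))
      if (n_fp > 0) {
        fp <- tibble(
          gene_a = sample(genes$gene_id, n_fp, replace = TRUE),
          gene_b = sample(genes$gene_id, n_fp, replace = TRUE),
          score = 50, evalue = 1e-6
        ) |> filter(.data$gene_a != .data$gene_b)
        hits <- bind_rows(hits, fp)
      }
    })
  }
  hits
}

# best chains for one chromosome pair and one orientation sign by sparse DP;
# returns list of integer vectors (anchor row indices) with chain scores
chain_one_side <- function(ord_a, ord_b, score, max_gap, anchor_score,
                           gap_penalty) {
  n <- length(ord_a)
  o <- order(ord_a, ord_b)
  oa <- ord_a[o]; ob <- ord_b[o]; sc <- score[o]
  best <- sc
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i == 1) next
    ja <- oa[i] - oa[1:(i - 1)]
    jb <- ob[i] - ob[1:(i - 1)]
    ok <- which(ja > 0 & jb > 0 & ja <= max_gap & jb <= max_gap)
    if (length(ok) == 0) next
    cand <- best[ok] + sc[i] -
      gap_penalty * ((ja[ok] - 1) + (jb[ok] - 1))
    k <- which.max(cand)
    if (cand[k] > best[i]) {
      best[i] <- cand[k]
      prev[i] <- ok[k]
    }
  }
  list(order = o, best = best, prev = prev)
}

trace_chain <- function(dp, end) {
  path <- integer(0)
  i <- end
  while (i != 0L) {
    path <- c(i, path)
    i <- dp$prev[i]
  }
  dp$order[path]
}

#' Chain anchors into collinear syntenic blocks
#'
#' DAGChainer-style chaining: per chromosome pair and orientation sign,
#' highest-scoring chains of anchors monotone in gene order on both sides are
#' found by dynamic programming (score = sum of anchor scores minus
#' `gap_penalty` per skipped gene per side, adjacent gaps at most
#' `max_gap_genes` on each side). Chains are extracted greedily by descending
#' score with used anchors removed; chains with fewer than `min_anchors`
#' anchors are discarded. For self-comparisons, tandem anchors (both genes on
#' one chromosome within `tandem_gap` positions) are collapsed away first.
#'
#' @param anchors Anchor tibble from [filter_anchors()].
#' @param max_gap_genes Maximum gene-order gap between adjacent anchors
#'   (default 40).
#' @param min_anchors Minimum anchors per reported block (default 5).
#' @param anchor_score,gap_penalty Chain scoring constants.
#' @param tandem_gap Self-hit order distance collapsed as tandem (default 5).
#' @return Tibble of blocks: `block_id`, `chrom_a`, `chrom_b`, `orientation`
#'   (`parallel`/`antiparallel`), `n_anchors`, `score`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `order_span_a`, `order_span_b` (list columns of the
#'   order-index ranges), `anchors` (list of anchor-row tibbles).
#' @export
chain_collinear_blocks <- function(anchors, max_gap_genes = 40,
                                   min_anchors = 5, anchor_score = 10,
                                   gap_penalty = 1, tandem_gap = 5) {
  if (nrow(anchors) == 0) return(empty_blocks())
  a <- anchors |>
    filter(!(.data$chrom_a == .data$chrom_b &
               abs(.data$order_a - .data$order_b) <= tandem_gap))
  if (nrow(a) == 0) return(empty_blocks())
  # canonical chromosome pair sides
  swap <- a$chrom_a > a$chrom_b |
    (a$chrom_a == a$chrom_b & a$order_a > a$order_b)
  a[swap, c("gene_a", "gene_b", "chrom_a", "chrom_b", "order_a", "order_b",
            "start_a", "end_a", "start_b", "end_b")] <-
    a[swap, c("gene_b", "gene_a", "chrom_b", "chrom_a", "order_b", "order_a",
              "start_b", "end_b", "start_a", "end_a")]
  blocks <- list()
  for (pair in split(a, paste(a$chrom_a, a$chrom_b))) {
    sub <- pair
    avail <- rep(TRUE, nrow(sub))
    # greedy partition: repeatedly take the best remaining chain over both
    # orientation signs, then retire its anchors
    repeat {
      idx <- which(avail)
      if (length(idx) < min_anchors) break
      cand <- purrr::map(c(1, -1), function(sign_b) {
        dp <- chain_one_side(sub$order_a[idx], sign_b * sub$order_b[idx],
                             rep(anchor_score, length(idx)),
                             max_gap_genes, anchor_score, gap_penalty)
        end <- which.max(dp$best)
        list(sign = sign_b, score = dp$best[end],
             chain = idx[trace_chain(dp, end)])
      })
      bi <- which.max(map_dbl(cand, "score"))
      chain <- cand[[bi]]$chain
      if (length(chain) < min_anchors) break
      avail[chain] <- FALSE
      ch <- sub[chain, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- tibble(
        chrom_a = ch$chrom_a[1], chrom_b = ch$chrom_b[1],
        orientation = if (cand[[bi]]$sign == 1) "parallel" else "antiparallel",
        n_anchors = nrow(ch),
        score = cand[[bi]]$score,
        start_a = min(ch$start_a), end_a = max(ch$end_a),
        start_b = min(ch$start_b), end_b = max(ch$end_b),
        order_span_a = list(range(ch$order_a)),
        order_span_b = list(range(ch$order_b)),
        anchors = list(ch)
      )
    }
  }
  if (length(blocks) == 0) return(empty_blocks())
  out <- bind_rows(blocks) |>
    arrange(dplyr::desc(.data$score))
  out$block_id <- sprintf("block_%03d", seq_len(nrow(out)))
  select(out, "block_id", dplyr::everything())
}

empty_blocks <- function() {
  tibble(block_id = character(0), chrom_a = character(0),
         chrom_b = character(0), orientation = character(0),
         n_anchors = integer(0), score = numeric(0),
         start_a = integer(0), end_a = integer(0),
         start_b = integer(0), end_b = integer(0),
         order_span_a = list(), order_span_b = list(), anchors = list())
}

#' Windowed syntenic depth
#'
#' For every window of `window` consecutive genes along each chromosome, the
#' depth is the number of blocks whose span overlaps the window (for
#' self-synteny both block sides count). Reports the window table, the
#' per-chromosome maximum, and the fraction of covered windows at each depth
#' (the 1:k histogram).
#'
#' @param blocks Block tibble from [chain_collinear_blocks()].
#' @param genes Gene table of the query genome.
#' @param window Window size in genes (default 20).
#' @return List of class `syntenic_depth`: `windows`, `by_chromosome`,
#'   `histogram`.
#' @export
syntenic_depth <- function(blocks, genes, window = 20) {
  chroms <- genes |>
    group_by(.data$chrom) |>
    summarise(n_genes = max(.data$order_index), .groups = "drop")
  spans <- list()
  if (nrow(blocks) > 0) {
    spans <- c(
      purrr::map(seq_len(nrow(blocks)), function(i) {
        tibble(chrom = blocks$chrom_a[i],
               lo = blocks$order_span_a[[i]][1],
               hi = blocks$order_span_a[[i]][2])
      }),
      purrr::map(seq_len(nrow(blocks)), function(i) {
        tibble(chrom = blocks$chrom_b[i],
               lo = blocks$order_span_b[[i]][1],
               hi = blocks$order_span_b[[i]][2])
      })
    )
  }
  spans <- if (length(spans)) bind_rows(spans) else
    tibble(chrom = character(0), lo = integer(0), hi = integer(0))
  windows <- purrr::map_dfr(seq_len(nrow(chroms)), function(i) {
    n <- chroms$n_genes[i]
    if (n < window) return(tibble())
    starts <- seq_len(n - window + 1L)
    sp <- filter(spans, .data$chrom == chroms$chrom[i])
    depth <- vapply(starts, function(s) {
      sum(sp$lo <= s + window - 1L & sp$hi >= s)
    }, numeric(1))
    tibble(chrom = chroms$chrom[i], window_start = starts,
           window_end = starts + window - 1L, depth = depth)
  })
  by_chrom <- windows |>
    group_by(.data$chrom) |>
    summarise(max_depth = max(.data$depth), .groups = "drop")
  covered <- filter(windows, .data$depth >= 1)
  histogram <- if (nrow(covered) > 0) {
    covered |> count(.data$depth) |>
      mutate(fraction = .data$n / sum(.data$n))
  } else {
    tibble(depth = numeric(0), n = integer(0), fraction = numeric(0))
  }
  structure(list(windows = windows, by_chromosome = by_chrom,
                 histogram = histogram, window = window),
            class = "syntenic_depth")
}

#' Syntenic coverage
#'
#' Total length of genes participating in at least one syntenic block divided
#' by the total length of all genes in the table.
#'
#' @param blocks Block tibble.
#' @param genes Gene table (`gene_id`, `start`, `end`).
#' @return Fraction in `[0, 1]`.
#' @export
syntenic_coverage <- function(blocks, genes) {
  len <- genes$end - genes$start + 1
  total <- sum(as.numeric(len))
  assert_that(total > 0, "syntenic_coverage(): zero total gene length")
  if (nrow(blocks) == 0) return(0)
  syntenic_genes <- unique(unlist(purrr::map(blocks$anchors, function(a) {
    c(a$gene_a, a$gene_b)
  })))
  sum(as.numeric(len[genes$gene_id %in% syntenic_genes])) / total
}
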