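# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small WGD-free genome + corrupted assembly + ordering + cross
small_reconcile_world <- function(seed = 2, chimera_count = 8,
                                  inversion_count = 2) {
  cfg <- sim_config(n_chromosomes = 6, genes_per_chromosome = 60,
                    wgd_events = list(), seed = seed)
  sim <- simulate_wgd_genome(cfg)
  fr <- fragment_and_corrupt(sim$genome, sim$truth,
                             target_scaffold_n50 = 4000,
                             chimera_count = chimera_count, seed = seed)
  po <- simulate_proximity_ordering(fr$assembly, fr$truth,
                                    inversion_count = inversion_count,
                                    seed = seed)
  gt <- simulate_cross(sim$genome, n_progeny = 110,
                       markers_per_chromosome = 40, truth = po$truth,
                       seed = seed)
  list(sim = sim, assembly = fr$assembly, ordering = po$ordering,
       truth = po$truth, gt = gt)
}

# a deterministic genotype matrix from explicit string patterns
calls_from_strings <- function(patterns) {
  m <- do.call(rbind, strsplit(patterns, ""))
  rownames(m) <- sprintf("m%02d", seq_along(patterns))
  m
}

gt_from_calls <- function(calls, scaffold_id = NULL) {
  n <- nrow(calls)
  structure(list(
    markers = tibble::tibble(
      marker_id = rownames(calls),
      chrom = "chr01",
      position_bp = seq_len(n),
      scaffold_id = scaffold_id %||% rep("scf1", n),
      scaffold_position = seq_len(n)
    ),
    calls = calls, n_progeny = ncol(calls)
  ), class = "genotype_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent NG86 oracle pieces (kept deliberately separate from the
# package implementation): per-codon synonymous-site count by enumeration
oracle_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (gc[[alt]] != "*" && gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# brute-force best collinear chain score over all anchor subsets (<= 12)
oracle_best_chain <- function(oa, ob, anchor_score = 10, gap_penalty = 1,
                              max_gap = 40) {
  n <- length(oa)
  best <- -Inf
  best_len <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    idx <- idx[order(oa[idx])]
    if (length(idx) < 1) next
    da <- diff(oa[idx]); db <- diff(ob[idx])
    ok_par <- all(da > 0) && all(db > 0) && all(da <= max_gap) &&
      all(db <= max_gap)
    ok_anti <- all(da > 0) && all(-db > 0) && all(da <= max_gap) &&
      all(-db <= max_gap)
    if (length(idx) > 1 && !ok_par && !ok_anti) next
    sc <- anchor_score * length(idx) -
      if (length(idx) > 1) gap_penalty * sum((da - 1) + (abs(db) - 1)) else 0
    if (sc > best) {
      best <- sc
      best_len <- length(idx)
    }
  }
  list(score = best, len = best_len)
}

# O(n!) exhaustive block-order oracle: minimum sum of adjacent r
oracle_best_order <- function(D) {
  n <- nrow(D)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(D[cbind(p[-n], p[-1])])
    if (cost < best) best <- cost
  }
  best
}

# O(n^2) Kendall tau-b oracle by direct pair enumeration
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}
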