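# Paranome construction and Ks age distributions: gene families as connected
# components of the hit graph, per-family Ks deduplication by average-linkage
# node averaging, and ortholog Ks samples from reciprocal best hits.

#' Build gene families from a filtered hit list
#'
#' Families are the connected components of the gene-gene hit graph (an
#' e-value-filtered similarity graph); singleton genes are excluded.
#'
#' @param hits Tibble `gene_a`, `gene_b` (already filtered).
#' @return Tibble `family_id`, `gene_id`.
#' @export
build_gene_families <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble(family_id = character(0), gene_id = character(0)))
  }
  g <- igraph::graph_from_data_frame(
    hits[, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)
  tibble(gene_id = names(comp$membership),
         comp = comp$membership) |>
    group_by(.data$comp) |>
    mutate(family_id = paste0("fam_", min(.data$gene_id))) |>
    ungroup() |>
    select("family_id", "gene_id") |>
    arrange(.data$family_id, .data$gene_id)
}

#' Pairwise Ks matrix for one family
#'
#' @param members Gene ids.
#' @param cds Named character vector of CDS.
#' @return Symmetric matrix of Ks values (`NA` where saturated).
#' @export
family_ks_matrix <- function(members, cds) {
  k <- length(members)
  m <- matrix(NA_real_, k, k, dimnames = list(members, members))
  if (k < 2) return(m)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      est <- ng86_ks(cds[[members[i]]], cds[[members[j]]])
      m[i, j] <- m[j, i] <- est$ks
    }
  }
  m
}

#' Deduplicate Ks values within a gene family
#'
#' Average-linkage hierarchical clustering on the pairwise Ks matrix; each
#' internal node contributes one Ks value, the mean of the pairwise values
#' first joined at that node, giving exactly `n - 1` values per family of `n`
#' genes. This removes the redundancy whereby a family of 2^k genes from k
#' nested duplications contributes many more old pairwise values than events.
#' Saturated (NA) entries are imputed as the family maximum before clustering.
#'
#' @param ks_matrix Symmetric pairwise Ks matrix.
#' @return Numeric vector of node Ks values (length `n - 1`; empty for
#'   families of one).
#' @export
family_ks_dedup <- function(ks_matrix) {
  n <- nrow(ks_matrix)
  if (n < 2) return(numeric(0))
  m <- ks_matrix
  if (all(is.na(m[upper.tri(m)]))) return(numeric(0))
  mx <- max(m, na.rm = TRUE)
  m[is.na(m)] <- mx
  if (n == 2) return(m[1, 2])
  hc <- hclust(as.dist(m), method = "average")
  # node value: mean of the original pairwise values first joined at the node
  members <- lapply(seq_len(n), function(i) i)
  vals <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    merge_row <- hc$merge[s, ]
    left <- if (merge_row[1] < 0) -merge_row[1] else members[[n + merge_row[1]]]
    right <- if (merge_row[2] < 0) -merge_row[2] else members[[n + merge_row[2]]]
    vals[s] <- mean(m[left, right, drop = FALSE])
    members[[n + s]] <- c(left, right)
  }
  vals
}

#' Paranome Ks sample for one genome
#'
#' Builds families from the hit table, computes pairwise NG86 Ks within each
#' family, and concatenates the deduplicated node values over all families.
#' Saturated pairs are excluded (their count is reported as an attribute), and
#' node values above `ks_cap` are dropped for distribution analysis.
#'
#' @param genome A `wgd_genome` (or gene table with a `cds` column).
#' @param hits Hit tibble `gene_a`, `gene_b` (e.g. [truth_anchors()] output or
#'   a parsed search result).
#' @param ks_cap Ceiling for retained node Ks values (default 3).
#' @return Numeric vector of node Ks values with attributes `n_saturated`,
#'   `n_capped`, `n_families`.
#' @export
paranome_ks <- function(genome, hits, ks_cap = 3) {
  genes <- if (inherits(genome, "wgd_genome")) genome$genes else genome
  cds <- setNames(genes$cds, genes$gene_id)
  fams <- build_gene_families(hits)
  n_sat <- 0L
  vals <- numeric(0)
  for (fid in unique(fams$family_id)) {
    members <- fams$gene_id[fams$family_id == fid]
    m <- family_ks_matrix(members, cds)
    n_sat <- n_sat + sum(is.na(m[upper.tri(m)]))
    vals <- c(vals, family_ks_dedup(m))
  }
  n_cap <- sum(vals > ks_cap)
  out <- vals[vals <= ks_cap & is.finite(vals)]
  attr(out, "n_saturated") <- n_sat
  attr(out, "n_capped") <- n_cap
  attr(out, "n_families") <- length(unique(fams$family_id))
  out
}

#' Ortholog Ks sample between two genomes
#'
#' Reciprocal best hits by score (score ties dropped on both sides), with Ks
#' per RBH pair estimated by [ng86_ks()].
#'
#' @param genome_a,genome_b `wgd_genome` objects (or gene tables with `cds`).
#' @param cross_hits Tibble `gene_a` (genome a), `gene_b` (genome b), `score`.
#' @param ks_cap Ceiling for retained values (default 3).
#' @return Numeric vector of Ks values (attribute `n_pairs` = RBH count);
#'   empty with a warning when no RBH pair exists.
#' @export
ortholog_ks <- function(genome_a, genome_b, cross_hits, ks_cap = 3) {
  ga <- if (inherits(genome_a, "wgd_genome")) genome_a$genes else genome_a
  gb <- if (inherits(genome_b, "wgd_genome")) genome_b$genes else genome_b
  best_of <- function(h, key) {
    h |>
      group_by(.data[[key]]) |>
      filter(.data$score == max(.data$score)) |>
      filter(dplyr::n() == 1) |>
      ungroup()
  }
  rbh <- if (nrow(cross_hits) == 0) {
    cross_hits[, c("gene_a", "gene_b")]
  } else {
    inner_join(select(best_of(cross_hits, "gene_a"), "gene_a", "gene_b"),
               select(best_of(cross_hits, "gene_b"), "gene_a", "gene_b"),
               by = c("gene_a", "gene_b"))
  }
  if (nrow(rbh) == 0) {
    warn("ortholog_ks(): no reciprocal best hit pairs")
    out <- numeric(0)
    attr(out, "n_pairs") <- 0L
    return(out)
  }
  cds_a <- setNames(ga$cds, ga$gene_id)
  cds_b <- setNames(gb$cds, gb$gene_id)
  vals <- map_dbl(seq_len(nrow(rbh)), function(i) {
    ng86_ks(cds_a[[rbh$gene_a[i]]], cds_b[[rbh$gene_b[i]]])$ks
  })
  out <- vals[!is.na(vals) & vals <= ks_cap]
  attr(out, "n_pairs") <- nrow(rbh)
  out
}
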