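# Nei-Gojobori (1986) synonymous/nonsynonymous machinery.
#
# Site counting: at each codon position the fraction of the three single-base
# changes that are synonymous (stop-codon changes count as nonsynonymous).
# Difference counting: codon pairs differing at 1-3 positions are scored by
# averaging synonymous/nonsynonymous steps over all minimal mutational
# pathways; pathways passing through a stop codon are excluded (if every
# pathway hits a stop, all are kept as a fallback so the pair still scores).
# Everything is precomputed into 64 x 64 lookup tables once per session.

ng86_env <- new.env(parent = emptyenv())

codon_universe <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

ng86_tables <- function() {
  if (!is.null(ng86_env$tabs)) return(ng86_env$tabs)
  codons <- sort(codon_universe())
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  names(aa) <- codons
  bases <- c("A", "C", "G", "T")

  one_step <- function(codon, pos) {
    cur <- substr(codon, pos, pos)
    vapply(setdiff(bases, cur), function(b) {
      x <- codon
      substr(x, pos, pos) <- b
      x
    }, character(1))
  }

  # synonymous site fraction per codon (summed over the 3 positions)
  syn_sites <- vapply(codons, function(cd) {
    if (aa[cd] == "*") return(NA_real_)
    s <- 0
    for (pos in 1:3) {
      alt <- one_step(cd, pos)
      s <- s + sum(aa[alt] == aa[cd] & aa[alt] != "*") / 3
    }
    s
  }, numeric(1))

  # pathway-averaged synonymous / total differences per codon pair
  n_codon <- length(codons)
  sd_tab <- matrix(0, n_codon, n_codon, dimnames = list(codons, codons))
  nd_tab <- sd_tab
  step_type <- function(from, to) {
    # 1 if synonymous step, 0 if nonsynonymous, NA if lands on a stop
    if (aa[to] == "*") return(NA_real_)
    as.numeric(aa[from] == aa[to])
  }
  perms <- list(
    list(), list(1L), list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (i in seq_len(n_codon)) {
    for (j in seq_len(n_codon)) {
      if (j <= i) next
      a <- codons[i]; b2 <- codons[j]
      if (aa[a] == "*" || aa[b2] == "*") next
      diff_pos <- which(vapply(1:3, function(p) {
        substr(a, p, p) != substr(b2, p, p)
      }, logical(1)))
      nd <- length(diff_pos)
      if (nd == 0) next
      paths <- perms[[nd + 1L]]
      syn_counts <- numeric(0)
      syn_all <- numeric(0)
      for (ord in paths) {
        cur <- a
        syn <- 0
        ok <- TRUE
        for (p in diff_pos[ord]) {
          nxt <- cur
          substr(nxt, p, p) <- substr(b2, p, p)
          st <- step_type(cur, nxt)
          if (is.na(st)) {
            ok <- FALSE
            st <- as.numeric(aa[cur] == aa[nxt]) # fallback scoring via stop
          }
          syn <- syn + st
          cur <- nxt
        }
        syn_all <- c(syn_all, syn)
        if (ok) syn_counts <- c(syn_counts, syn)
      }
      if (length(syn_counts) == 0) syn_counts <- syn_all
      sdij <- mean(syn_counts)
      sd_tab[i, j] <- sd_tab[j, i] <- sdij
      nd_tab[i, j] <- nd_tab[j, i] <- nd - sdij
    }
  }

  # synonymous one-step neighbours (used by the sequence simulator)
  syn_neighbors <- lapply(codons, function(cd) {
    if (aa[cd] == "*") return(character(0))
    out <- character(0)
    for (pos in 1:3) {
      alt <- one_step(cd, pos)
      out <- c(out, alt[aa[alt] == aa[cd] & aa[alt] != "*"])
    }
    out
  })
  names(syn_neighbors) <- codons

  ng86_env$tabs <- list(
    codons = codons, aa = aa, syn_sites = syn_sites,
    sd = sd_tab, nd = nd_tab, syn_neighbors = syn_neighbors
  )
  ng86_env$tabs
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

#' Pairwise Ks and Ka by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites and differences for a codon-aligned
#' pair of coding sequences and applies the Jukes-Cantor multiple-hit
#' correction: `Ks = -3/4 * log(1 - 4/3 * pS)`. Pairs with `pS >= 3/4` lie
#' beyond the correction's domain and are flagged saturated (`ks = NA`).
#'
#' @param cds_a,cds_b Coding sequences of identical length (multiple of 3,
#'   no internal stop codons). Codons containing non-ACGT characters are
#'   skipped on both sequences.
#' @return One-row tibble with columns `ks`, `ka`, `ps`, `pn`, `sites_s`,
#'   `sites_n`, `sd_count`, `nd_count`, `saturated`.
#' @examples
#' ng86_ks("ATGGCT", "ATGGCC")
#' @export
ng86_ks <- function(cds_a, cds_b) {
  assert_that(nchar(cds_a) == nchar(cds_b),
              "ng86_ks(): sequences must have identical length")
  assert_that(nchar(cds_a) %% 3 == 0,
              "ng86_ks(): sequence length must be a multiple of 3")
  tabs <- ng86_tables()
  ca <- split_codons(toupper(cds_a))
  cb <- split_codons(toupper(cds_b))
  ok <- ca %in% tabs$codons & cb %in% tabs$codons &
    tabs$aa[ca] != "*" & tabs$aa[cb] != "*"
  ok[is.na(ok)] <- FALSE
  ca <- ca[ok]; cb <- cb[ok]
  assert_that(length(ca) > 0, "ng86_ks(): no scorable codons")
  S <- (sum(tabs$syn_sites[ca]) + sum(tabs$syn_sites[cb])) / 2
  N <- 3 * length(ca) - S
  idx <- cbind(match(ca, tabs$codons), match(cb, tabs$codons))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * p)
  ks <- jc(ps)
  tibble(
    ks = ks, ka = jc(pn), ps = ps, pn = pn,
    sites_s = S, sites_n = N, sd_count = Sd, nd_count = Nd,
    saturated = is.na(ks)
  )
}
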