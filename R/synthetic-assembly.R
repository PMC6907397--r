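# Planted assembly errors and simulated genotyping: scaffold fragmentation
# with chimeric joins (marked by a lone N), proximity orderings with planted
# inversions, pseudo-testcross genotype tables, and direct Ks mixture samples.

#' Fragment a genome into scaffolds and plant chimeric joins
#'
#' Chromosomes are cut into scaffolds whose lengths scatter around
#' `target_scaffold_n50`, then exactly `chimera_count` scaffold pairs drawn
#' from *different* chromosomes are concatenated with a single `N` at the
#' junction - the signature the splitting rule in [split_chimeric_scaffold()]
#' targets. Every junction and every scaffold's true origin are recorded.
#'
#' @param genome A `wgd_genome`.
#' @param truth Matching `wgd_truth` (junctions and origins are appended).
#' @param target_scaffold_n50 Rough scaffold N50 in bp.
#' @param chimera_count Number of chimeric joins to plant.
#' @param seed Integer seed.
#' @return List `assembly` (scaffold tibble: `scaffold_id`, `sequence`,
#'   `length`), `truth` (with `chimeric_joins` and `scaffold_origin` filled).
#' @export
fragment_and_corrupt <- function(genome, truth, target_scaffold_n50 = 5000,
                                 chimera_count = 0, seed = 1) {
  assert_that(nrow(genome$chromosomes) > 0, "fragment_and_corrupt(): empty genome")
  assert_that(target_scaffold_n50 <= max(genome$chromosomes$length),
              "target_scaffold_n50 exceeds the longest chromosome")
  with_seed(derive_seed(seed, 2L), {
    origin <- list()
    pieces <- list()
    for (i in seq_len(nrow(genome$chromosomes))) {
      ch <- genome$chromosomes$chrom[i]
      L <- genome$chromosomes$length[i]
      cuts <- integer(0)
      pos <- 0
      while (TRUE) {
        step <- max(round(target_scaffold_n50 * runif(1, 0.5, 1.5)), 200)
        pos <- pos + step
        if (pos >= L) break
        cuts <- c(cuts, pos)
      }
      bounds <- cbind(c(1L, cuts + 1L), c(cuts, L))
      for (k in seq_len(nrow(bounds))) {
        id <- sprintf("scf_%s_%03d", ch, k)
        origin[[id]] <- tibble(scaffold_id = id, chrom = ch,
                               start = bounds[k, 1], end = bounds[k, 2],
                               strand = "+")
        pieces[[id]] <- substr(genome$chromosomes$sequence[i],
                               bounds[k, 1], bounds[k, 2])
      }
    }
    scf <- tibble(scaffold_id = names(pieces),
                  sequence = unname(unlist(pieces)))
    scf$length <- nchar(scf$sequence)
    origin <- bind_rows(origin)
    origin$piece <- 1L

    assert_that(chimera_count <= nrow(scf) - 1,
                "chimera_count exceeds available scaffolds")
    joins <- list()
    if (chimera_count > 0) {
      chrom_of <- setNames(origin$chrom, origin$scaffold_id)
      # prefer longer scaffolds so both sides of a join tend to carry markers
      avail <- scf$scaffold_id[order(-scf$length)]
      used <- character(0)
      for (j in seq_len(chimera_count)) {
        cand <- setdiff(avail, used)
        left <- cand[1]
        right_pool <- cand[chrom_of[cand] != chrom_of[left]]
        assert_that(length(right_pool) > 0,
                    "fragment_and_corrupt(): cannot place requested chimeras")
        right <- sample(right_pool, 1)
        used <- c(used, left, right)
        li <- match(left, scf$scaffold_id)
        ri <- match(right, scf$scaffold_id)
        new_id <- sprintf("chimera_%02d", j)
        junction <- scf$length[li] + 1L
        joined <- paste0(scf$sequence[li], "N", scf$sequence[ri])
        joins[[j]] <- tibble(scaffold_id = new_id,
                             junction_position = junction,
                             chrom_left = chrom_of[left],
                             chrom_right = chrom_of[right])
        origin$scaffold_id[origin$scaffold_id == left] <- new_id
        ri_origin <- which(origin$scaffold_id == right)
        origin$scaffold_id[ri_origin] <- new_id
        origin$piece[ri_origin] <- 2L
        scf$sequence[li] <- joined
        scf$length[li] <- nchar(joined)
        scf$scaffold_id[li] <- new_id
        scf <- scf[-ri, , drop = FALSE]
      }
    }
    truth$chimeric_joins <- bind_rows(truth$chimeric_joins, bind_rows(joins))
    truth$scaffold_origin <- origin
    list(assembly = scf, truth = truth)
  })
}

#' Simulate a proximity-guided (Hi-C style) scaffold ordering
#'
#' Scaffolds are clustered by their true chromosome and ordered by true
#' position - a best-case proximity assembly - after which `inversion_count`
#' contiguous runs of at least two scaffolds are reversed (order and
#' orientation flipped), emulating the large-scale inversion errors proximity
#' assemblers are known to make. Chimeric scaffolds are assigned to the
#' chromosome contributing most of their length.
#'
#' @param assembly Scaffold tibble from [fragment_and_corrupt()].
#' @param truth Matching `wgd_truth` (inversions are appended).
#' @param inversion_count Number of planted inversions.
#' @param min_run,max_run Inversion segment size range in scaffolds.
#' @param seed Integer seed.
#' @return List `ordering` (tibble `scaffold_id`, `cluster_id`, `order_index`,
#'   `orientation`), `truth`.
#' @export
simulate_proximity_ordering <- function(assembly, truth, inversion_count = 0,
                                        min_run = 2, max_run = 4, seed = 1) {
  assert_that(min_run >= 2, "planted inversions must span >= 2 scaffolds")
  with_seed(derive_seed(seed, 3L), {
    placement <- truth$scaffold_origin |>
      mutate(len = .data$end - .data$start + 1L) |>
      group_by(.data$scaffold_id) |>
      summarise(cluster_chrom = .data$chrom[which.max(.data$len)],
                pos = .data$start[which.max(.data$len)],
                .groups = "drop") |>
      filter(.data$scaffold_id %in% assembly$scaffold_id)
    ordering <- placement |>
      arrange(.data$cluster_chrom, .data$pos) |>
      group_by(.data$cluster_chrom) |>
      mutate(order_index = row_number()) |>
      ungroup() |>
      mutate(cluster_id = paste0("cluster_",
                                 as.integer(factor(.data$cluster_chrom))),
             orientation = "+") |>
      select("scaffold_id", "cluster_id", "order_index", "orientation")

    inversions <- list()
    if (inversion_count > 0) {
      clusters <- split(seq_len(nrow(ordering)), ordering$cluster_id)
      clusters <- clusters[vapply(clusters, length, 1L) >= min_run + 2]
      assert_that(length(clusters) >= 1,
                  "no cluster large enough for planted inversions")
      pick <- sample(names(clusters), inversion_count,
                     replace = inversion_count > length(clusters))
      for (cl in unique(pick)) {
        n_here <- sum(pick == cl)
        rows <- clusters[[cl]]
        rows <- rows[order(ordering$order_index[rows])]
        taken <- rep(FALSE, length(rows))
        for (k in seq_len(n_here)) {
          run_len <- sample(min_run:min(max_run, length(rows) - 1), 1)
          starts <- which(!vapply(seq_len(length(rows) - run_len + 1),
                                  function(s) any(taken[s:(s + run_len - 1)]),
                                  logical(1)))
          if (length(starts) == 0) {
            abort("inversion_count exceeds available non-overlapping runs")
          }
          s <- sample(starts, 1)
          seg <- rows[s:(s + run_len - 1)]
          taken[s:(s + run_len - 1)] <- TRUE
          ordering$order_index[seg] <- rev(ordering$order_index[seg])
          ordering$orientation[seg] <- ifelse(
            ordering$orientation[seg] == "+", "-", "+")
          inversions[[length(inversions) + 1L]] <- tibble(
            cluster_id = cl,
            first_index = min(ordering$order_index[seg]),
            last_index = max(ordering$order_index[seg]),
            scaffolds = list(ordering$scaffold_id[seg])
          )
        }
      }
    }
    truth$planted_inversions <- bind_rows(truth$planted_inversions,
                                          bind_rows(inversions))
    ordering <- arrange(ordering, .data$cluster_id, .data$order_index)
    list(ordering = ordering, truth = truth)
  })
}

#' Simulate an F1 pseudo-testcross genotype table
#'
#' One parent is heterozygous at every marker (1:1 segregation); progeny
#' gametes are generated by a no-interference crossover process, so the
#' recombination fraction between markers d cM apart is Haldane's
#' `(1 - exp(-2d/100)) / 2`. Missing calls are injected at `missing_rate`.
#'
#' @param genome A `wgd_genome`.
#' @param n_progeny Number of progeny (the validation conditions use 110).
#' @param markers_per_chromosome Markers evenly spaced per chromosome.
#' @param chromosome_length_cM Map length of each chromosome in centimorgans.
#' @param missing_rate Fraction of calls replaced by `-`.
#' @param truth Optional `wgd_truth` with `scaffold_origin`; when supplied,
#'   markers are also located on assembly scaffolds.
#' @param seed Integer seed.
#' @return List of class `genotype_table`: `markers` (tibble `marker_id`,
#'   `chrom`, `position_bp`, `position_cM`, `scaffold_id`,
#'   `scaffold_position`), `calls` (marker x progeny character matrix over
#'   `"a"`, `"b"`, `"-"`), `n_progeny`.
#' @export
simulate_cross <- function(genome, n_progeny = 110,
                           markers_per_chromosome = 50,
                           chromosome_length_cM = 100, missing_rate = 0.05,
                           truth = NULL, seed = 1) {
  assert_that(n_progeny >= 1 && markers_per_chromosome >= 1,
              "simulate_cross(): counts must be positive")
  with_seed(derive_seed(seed, 4L), {
    chroms <- genome$chromosomes
    markers <- purrr::map_dfr(seq_len(nrow(chroms)), function(i) {
      pos <- round(seq(1, chroms$length[i],
                       length.out = markers_per_chromosome))
      tibble(
        marker_id = sprintf("m_%s_%03d", chroms$chrom[i],
                            seq_len(markers_per_chromosome)),
        chrom = chroms$chrom[i],
        position_bp = as.integer(pos),
        position_cM = (pos - 1) / (chroms$length[i] - 1) * chromosome_length_cM
      )
    })

    calls <- matrix("", nrow = nrow(markers), ncol = n_progeny,
                    dimnames = list(markers$marker_id,
                                    sprintf("p%03d", seq_len(n_progeny))))
    for (ch in unique(markers$chrom)) {
      rows <- which(markers$chrom == ch)
      d <- diff(markers$position_cM[rows])
      r <- (1 - exp(-2 * d / 100)) / 2
      for (p in seq_len(n_progeny)) {
        first <- sample(0:1, 1)
        flips <- rbinom(length(r), 1, r)
        state <- (first + cumsum(c(0, flips))) %% 2
        calls[rows, p] <- c("a", "b")[state + 1]
      }
    }
    miss <- matrix(runif(length(calls)) < missing_rate, nrow = nrow(calls))
    calls[miss] <- "-"

    if (!is.null(truth) && nrow(truth$scaffold_origin) > 0) {
      loc <- purrr::map_dfr(seq_len(nrow(markers)), function(i) {
        hit <- truth$scaffold_origin |>
          filter(.data$chrom == markers$chrom[i],
                 .data$start <= markers$position_bp[i],
                 .data$end >= markers$position_bp[i])
        if (nrow(hit) == 0) {
          return(tibble(scaffold_id = NA_character_,
                        scaffold_position = NA_integer_))
        }
        # chimeric scaffolds: right-hand part is shifted past the left + N
        piece_offset <- 0L
        sid <- hit$scaffold_id[1]
        if (hit$piece[1] == 2L) {
          piece_offset <- truth$chimeric_joins$junction_position[
            match(sid, truth$chimeric_joins$scaffold_id)]
        }
        tibble(scaffold_id = sid,
               scaffold_position = as.integer(
                 markers$position_bp[i] - hit$start[1] + 1L + piece_offset))
      })
      markers <- bind_cols(markers, loc)
    } else {
      markers$scaffold_id <- markers$chrom
      markers$scaffold_position <- markers$position_bp
    }

    structure(list(markers = markers, calls = calls, n_progeny = n_progeny),
              class = "genotype_table")
  })
}

#' Draw a truncated normal-mixture Ks sample
#'
#' @param components Tibble or list of `(weight, mean, sd)`; weights must sum
#'   to 1 (within 1e-9) and sds be positive.
#' @param n Sample size (0 gives an empty sample).
#' @param seed Integer seed.
#' @return Numeric vector of `n` positive Ks values.
#' @export
sample_ks_mixture <- function(components, n, seed = 1) {
  comp <- if (is.data.frame(components)) components else
    purrr::map_dfr(components, function(x) {
      tibble(weight = x[[1]], mean = x[[2]], sd = x[[3]])
    })
  assert_that(all(comp$weight >= 0) && abs(sum(comp$weight) - 1) <= 1e-9,
              "sample_ks_mixture(): weights must be >= 0 and sum to 1")
  assert_that(all(comp$sd > 0), "sample_ks_mixture(): sds must be > 0")
  if (n == 0) return(numeric(0))
  with_seed(derive_seed(seed, 5L), {
    idx <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
    out <- rnorm(n, comp$mean[idx], comp$sd[idx])
    bad <- which(out <= 0)
    while (length(bad) > 0) {
      idx2 <- sample.int(nrow(comp), length(bad), replace = TRUE,
                         prob = comp$weight)
      out[bad] <- rnorm(length(bad), comp$mean[idx2], comp$sd[idx2])
      bad <- which(out <= 0)
    }
    out
  })
}
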