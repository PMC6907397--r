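# Significant peaks in Ks age distributions: Gaussian KDE on a fixed grid,
# a SiZer map (significant zero crossings of the density derivative across a
# bandwidth ladder, with effective-independent-blocks simultaneous inference
# and an effective-sample-size sparsity rule), mode counting with bandwidth
# persistence, EM fitting of normal mixtures with BIC selection, and placement
# of duplication peaks relative to speciation peaks from ortholog Ks.

#' Gaussian kernel density estimate on a fixed grid
#'
#' @param sample Numeric Ks values.
#' @param bandwidth Kernel bandwidth (> 0); default Silverman rule-of-thumb.
#' @param bins Number of grid points (default 401).
#' @param range Grid range; default `c(0, max(sample))`.
#' @return Tibble `x`, `density`.
#' @export
ks_kde <- function(sample, bandwidth = NULL, bins = 401, range = NULL) {
  assert_that(length(sample) > 0, "ks_kde(): empty sample")
  bandwidth <- bandwidth %||% bw.nrd0(sample)
  assert_that(bandwidth > 0, "ks_kde(): bandwidth must be > 0")
  range <- range %||% c(0, max(sample))
  x <- seq(range[1], range[2], length.out = bins)
  dens <- vapply(x, function(xx) {
    mean(dnorm((xx - sample) / bandwidth)) / bandwidth
  }, numeric(1))
  tibble(x = x, density = dens)
}

silverman_bw <- function(sample) bw.nrd0(sample)

#' SiZer significance map for a Ks sample
#'
#' For each grid position and bandwidth the kernel estimate of the density
#' derivative and its standard error are computed; a simultaneous confidence
#' interval (alpha adjusted for the effective number of independent blocks,
#' grid width / 2h, per bandwidth row) classifies each cell as significantly
#' increasing, significantly decreasing, or not significant. Cells whose
#' effective sample size (kernel-weighted local count) falls below
#' `ess_min` are coded sparse.
#'
#' @param sample Numeric Ks values (>= 20 for a non-degenerate map).
#' @param bandwidths Bandwidth ladder; default 15 log-spaced values spanning
#'   0.5-4 times the Silverman bandwidth.
#' @param alpha Significance level (default 0.05).
#' @param bins Grid size (default 401).
#' @param range Grid range; default `c(0, max(sample))`.
#' @param ess_min Sparsity threshold on effective sample size (default 5).
#' @return List of class `sizer_map`: `grid` tibble (`x`, `bandwidth`,
#'   `deriv`, `se`, `ess`, `code`), `bandwidths`, `alpha`, `n`.
#' @export
sizer_map <- function(sample, bandwidths = NULL, alpha = 0.05, bins = 401,
                      range = NULL, ess_min = 5) {
  n <- length(sample)
  range <- range %||% c(0, max(sample))
  x <- seq(range[1], range[2], length.out = bins)
  h0 <- silverman_bw(sample)
  bandwidths <- bandwidths %||% exp(seq(log(0.5 * h0), log(4 * h0),
                                        length.out = 15))
  if (n < 20) {
    warn("sizer_map(): sample too small, map is all-sparse")
    grid <- tidyr::expand_grid(bandwidth = bandwidths, x = x) |>
      mutate(deriv = NA_real_, se = NA_real_, ess = 0, code = "sparse")
    return(structure(list(grid = grid, bandwidths = bandwidths, alpha = alpha,
                          n = n, range = range),
                     class = "sizer_map"))
  }
  rows <- purrr::map_dfr(bandwidths, function(h) {
    # effective number of independent blocks for simultaneous inference
    m <- max((range[2] - range[1]) / (2 * h), 1)
    q <- qnorm((1 + (1 - alpha)^(1 / m)) / 2)
    out <- purrr::map_dfr(x, function(xx) {
      z <- (xx - sample) / h
      phi <- dnorm(z)
      y <- (-z * phi) / h^2        # d/dx of the scaled kernel
      est <- mean(y)
      se <- sqrt(var(y) / n)
      ess <- sum(phi) / dnorm(0)
      tibble(x = xx, deriv = est, se = se, ess = ess)
    })
    out$bandwidth <- h
    out$code <- dplyr::case_when(
      out$ess < ess_min ~ "sparse",
      out$deriv - q * out$se > 0 ~ "sig_increase",
      out$deriv + q * out$se < 0 ~ "sig_decrease",
      TRUE ~ "not_sig"
    )
    out
  })
  structure(list(grid = select(rows, "x", "bandwidth", "deriv", "se",
                               "ess", "code"),
                 bandwidths = bandwidths, alpha = alpha, n = n, range = range),
            class = "sizer_map")
}

# features (inc-run followed by dec-run) for one bandwidth row
row_features <- function(codes, x) {
  r <- rle(codes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sig <- which(r$values %in% c("sig_increase", "sig_decrease"))
  feats <- list()
  k <- 1
  while (k <= length(sig)) {
    if (r$values[sig[k]] == "sig_increase") {
      # next significant run of the opposite sign closes the feature
      nxt <- sig[sig > sig[k]]
      nxt <- nxt[r$values[nxt] == "sig_decrease"]
      # but only if no further sig_increase intervenes before it
      if (length(nxt) > 0) {
        j <- nxt[1]
        between <- sig[sig > sig[k] & sig < j]
        if (!any(r$values[between] == "sig_increase")) {
          feats[[length(feats) + 1L]] <- c(x[starts[sig[k]]], x[ends[j]])
        }
        k <- which(sig == j) + 1
        next
      }
    }
    k <- k + 1
  }
  feats
}

#' Count significant peaks in a SiZer map
#'
#' A peak at one bandwidth is a maximal position interval containing a run of
#' significant increase followed by a run of significant decrease. Only
#' features that persist across at least `persist` adjacent bandwidths are
#' counted; the reported count is the maximum over bandwidths of persistent
#' features, and the reported intervals come from the smoothest bandwidth
#' achieving that count.
#'
#' @param map A `sizer_map`.
#' @param persist Minimum number of adjacent bandwidths a feature must span
#'   (default 2).
#' @return List: `count`, `intervals` tibble (`lo`, `hi`), per-bandwidth
#'   feature table `by_bandwidth`.
#' @export
count_significant_peaks <- function(map, persist = 2) {
  grid <- arrange(map$grid, .data$bandwidth, .data$x)
  bws <- sort(unique(grid$bandwidth))
  feats <- purrr::map(bws, function(h) {
    sub <- filter(grid, .data$bandwidth == h)
    row_features(sub$code, sub$x)
  })
  overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  persistent <- purrr::map(seq_along(bws), function(i) {
    keep(feats[[i]], function(f) {
      nb <- c(i - 1, i + 1)
      nb <- nb[nb >= 1 & nb <= length(bws)]
      any(map_dbl(nb, function(j) {
        any(vapply(feats[[j]], overlaps, logical(1), b = f))
      }) > 0)
    })
  })
  counts <- map_int(persistent, length)
  count <- if (length(counts)) max(counts) else 0L
  intervals <- tibble(lo = numeric(0), hi = numeric(0))
  if (count > 0) {
    best <- max(which(counts == count))
    intervals <- purrr::map_dfr(persistent[[best]], function(f) {
      tibble(lo = f[1], hi = f[2])
    })
  }
  by_bw <- tibble(bandwidth = bws, n_features = map_int(feats, length),
                  n_persistent = counts)
  list(count = count, intervals = intervals, by_bandwidth = by_bw)
}

em_fit_once <- function(x, mu, sigma, w, max_iter = 2000, tol = 1e-8) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      log(w[j]) + dnorm(x, mu[j], sigma[j], log = TRUE)
    }, numeric(n))
    if (k == 1) logd <- matrix(logd, ncol = 1)
    mx <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    if (any(sigma < 1e-4) || any(w < 1e-3)) return(NULL)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], sds = sigma[ord],
       loglik = ll, ll_trace = ll_trace, k = k)
}

#' Fit normal mixtures to a Ks sample with BIC selection
#'
#' Maximum-likelihood EM over `k_range` component counts, each started from
#' `n_random` random initialisations plus `n_kmeans` k-means-based
#' initialisations; the best log-likelihood per k is kept and the component
#' count is selected by minimum BIC (`-2 loglik + (3k - 1) log n`). Starts
#' that collapse a component (sd < 1e-4 or weight < 1e-3) are rejected.
#'
#' @param sample Numeric Ks values.
#' @param k_range Component counts to try (default 1:5).
#' @param n_random,n_kmeans Starts per k.
#' @param seed Integer seed.
#' @return List of class `ks_mixture`: `fits` (per-k list), `selected`
#'   (best-BIC fit), `bic` tibble, `n`.
#' @export
fit_gaussian_mixture <- function(sample, k_range = 1:5, n_random = 20,
                                 n_kmeans = 5, seed = 1) {
  x <- sample
  n <- length(x)
  assert_that(n >= 10 * max(k_range),
              "fit_gaussian_mixture(): need n >= 10 * max(k_range)")
  with_seed(derive_seed(seed, 7L), {
    fits <- list()
    for (k in k_range) {
      best <- NULL
      starts <- list()
      for (s in seq_len(n_random)) {
        mu <- base::sample(x, k)
        starts[[length(starts) + 1L]] <- list(
          mu = mu, sigma = rep(sd(x) / sqrt(k), k), w = rep(1 / k, k))
      }
      for (s in seq_len(n_kmeans)) {
        km <- tryCatch(kmeans(x, centers = k, nstart = 1),
                       error = function(e) NULL)
        if (is.null(km)) next
        sds <- vapply(seq_len(k), function(j) {
          v <- x[km$cluster == j]
          if (length(v) > 1) sd(v) else sd(x) / k
        }, numeric(1))
        starts[[length(starts) + 1L]] <- list(
          mu = as.numeric(km$centers), sigma = pmax(sds, 1e-3),
          w = as.numeric(table(factor(km$cluster, levels = 1:k))) / n)
      }
      for (st in starts) {
        fit <- em_fit_once(x, st$mu, st$sigma, st$w)
        if (is.null(fit)) next
        # EM ascent property must hold on every accepted fit
        assert_that(all(diff(fit$ll_trace) > -1e-6),
                    "fit_gaussian_mixture(): EM log-likelihood decreased")
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      if (is.null(best)) {
        warn(sprintf("fit_gaussian_mixture(): all starts degenerate for k = %d", k))
        next
      }
      best$bic <- -2 * best$loglik + (3 * k - 1) * log(n)
      fits[[as.character(k)]] <- best
    }
    assert_that(length(fits) > 0, "fit_gaussian_mixture(): no usable fit")
    bic_tab <- tibble(
      k = map_int(fits, "k"),
      loglik = map_dbl(fits, "loglik"),
      bic = map_dbl(fits, "bic")
    )
    selected <- fits[[which.min(bic_tab$bic)]]
    structure(list(fits = fits, selected = selected, bic = bic_tab, n = n),
              class = "ks_mixture")
  })
}

#' Report mixture components that match SiZer peaks
#'
#' Components of the selected fit whose mean lies inside a significant SiZer
#' peak interval are reported as the headline components; the rest are
#' retained but suppressed (BIC routinely selects more components than there
#' are significant modes).
#'
#' @param fit A `ks_mixture`.
#' @param map A `sizer_map` (computed on the same sample).
#' @param recent_threshold Components below this mean are flagged
#'   `non_wgd_recent` (background duplication/loss signal, default 0.25).
#' @return Tibble `component`, `weight`, `mean`, `sd`, `in_sizer_peak`,
#'   `flag`.
#' @export
match_components_to_sizer <- function(fit, map, recent_threshold = 0.25) {
  pk <- count_significant_peaks(map)
  sel <- fit$selected
  comp <- tibble(component = seq_along(sel$means), weight = sel$weights,
                 mean = sel$means, sd = sel$sds)
  comp$in_sizer_peak <- vapply(comp$mean, function(m) {
    any(pk$intervals$lo <= m & m <= pk$intervals$hi)
  }, logical(1))
  if (pk$count == 0) warn("match_components_to_sizer(): no significant SiZer peak")
  comp$flag <- dplyr::case_when(
    !comp$in_sizer_peak ~ "suppressed",
    comp$mean < recent_threshold ~ "non_wgd_recent",
    TRUE ~ "wgd_candidate"
  )
  comp
}

#' Group duplication peaks across genomes into shared WGD calls
#'
#' Single-linkage grouping of reported component means across genomes at the
#' given Ks tolerance; each group becomes one call with its supporting
#' genomes and pooled mean.
#'
#' @param calls Tibble `genome`, `mean` (one row per reported component), as
#'   built from [match_components_to_sizer()] output per genome.
#' @param tolerance Maximum Ks gap merged by single linkage (default 0.25).
#' @return Tibble `call_id`, `ks_mean`, `n_genomes`, `genomes` (list),
#'   `shared`.
#' @export
match_peaks_across_genomes <- function(calls, tolerance = 0.25) {
  assert_that(nrow(calls) >= 1, "match_peaks_across_genomes(): no calls")
  if (nrow(calls) == 1) {
    grp <- 1L
  } else {
    hc <- hclust(stats::dist(calls$mean), method = "single")
    grp <- cutree(hc, h = tolerance)
  }
  calls$grp <- grp
  calls |>
    group_by(.data$grp) |>
    summarise(ks_mean = mean(.data$mean),
              n_genomes = dplyr::n_distinct(.data$genome),
              genomes = list(sort(unique(.data$genome))),
              .groups = "drop") |>
    arrange(.data$ks_mean) |>
    mutate(call_id = sprintf("wgd_%d", row_number()),
           shared = .data$n_genomes > 1) |>
    select("call_id", "ks_mean", "n_genomes", "genomes", "shared")
}

# half width at half maximum of the main KDE peak
kde_peak_halfwidth <- function(sample, bandwidth = NULL) {
  kd <- ks_kde(sample, bandwidth = bandwidth)
  i <- which.max(kd$density)
  half <- kd$density[i] / 2
  lo <- kd$x[i]; hi <- kd$x[i]
  j <- i
  while (j > 1 && kd$density[j] > half) j <- j - 1
  lo <- kd$x[j]
  j <- i
  while (j < nrow(kd) && kd$density[j] > half) j <- j + 1
  hi <- kd$x[j]
  list(mode = kd$x[i], halfwidth = (hi - lo) / 2)
}

#' Place a WGD peak relative to a speciation event
#'
#' The speciation Ks is the mode of the ortholog Ks sample (KDE argmax at a
#' plug-in bandwidth). The WGD is `before_speciation` when its Ks mean exceeds
#' the mode by more than delta, `after_speciation` when it falls below by more
#' than delta, else `indistinguishable`; delta is half the larger of the two
#' KDE peak half-widths (ortholog sample, and the WGD sample when given).
#'
#' @param wgd_ks_mean Ks mean of the duplication peak.
#' @param ortholog_sample Ortholog Ks values (non-empty).
#' @param wgd_sample Optional paralog Ks values behind the peak.
#' @param label Speciation label carried into the result.
#' @return One-row tibble `label`, `wgd_ks`, `speciation_ks`, `delta`,
#'   `placement`.
#' @export
place_wgd_relative_to_speciation <- function(wgd_ks_mean, ortholog_sample,
                                             wgd_sample = NULL,
                                             label = "speciation") {
  assert_that(length(ortholog_sample) > 0,
              "place_wgd_relative_to_speciation(): empty ortholog sample")
  bw <- tryCatch(bw.SJ(ortholog_sample), error = function(e)
    bw.nrd0(ortholog_sample))
  pk <- kde_peak_halfwidth(ortholog_sample, bandwidth = bw)
  hw <- pk$halfwidth
  if (!is.null(wgd_sample) && length(wgd_sample) > 1) {
    hw <- max(hw, kde_peak_halfwidth(wgd_sample)$halfwidth)
  }
  delta <- hw / 2
  placement <- if (wgd_ks_mean > pk$mode + delta) {
    "before_speciation"
  } else if (wgd_ks_mean < pk$mode - delta) {
    "after_speciation"
  } else {
    "indistinguishable"
  }
  tibble(label = label, wgd_ks = wgd_ks_mean, speciation_ks = pk$mode,
         delta = delta, placement = placement)
}
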