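# broom-style accessors and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted Ks mixture
#'
#' @param x A `ks_mixture`.
#' @param ... Unused.
#' @return Tibble with one row per component of the BIC-selected fit.
#' @export
tidy.ks_mixture <- function(x, ...) {
  sel <- x$selected
  tibble(component = seq_along(sel$means), weight = sel$weights,
         mean = sel$means, sd = sel$sds)
}

#' One-row summary of a fitted Ks mixture
#'
#' @param x A `ks_mixture`.
#' @param ... Unused.
#' @return Tibble `k`, `loglik`, `bic`, `n`.
#' @export
glance.ks_mixture <- function(x, ...) {
  tibble(k = x$selected$k, loglik = x$selected$loglik,
         bic = x$selected$bic, n = x$n)
}

#' Tidy a SiZer map
#'
#' @param x A `sizer_map`.
#' @param ... Unused.
#' @return The long grid tibble (`x`, `bandwidth`, `deriv`, `se`, `ess`,
#'   `code`).
#' @export
tidy.sizer_map <- function(x, ...) x$grid

#' Tidy a reconciled assembly
#'
#' @param x A `reconciled_assembly`.
#' @param ... Unused.
#' @return The per-scaffold placement tibble.
#' @export
tidy.reconciled_assembly <- function(x, ...) x$scaffolds

#' Accounting summary of a reconciled assembly
#'
#' @param x A `reconciled_assembly`.
#' @param ... Unused.
#' @return Wide one-row tibble of the tier accounting.
#' @export
glance.reconciled_assembly <- function(x, ...) {
  tidyr::pivot_wider(x$accounting, names_from = "statistic",
                     values_from = "value")
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat(sprintf("Normal mixture fit: k = %d selected by BIC (n = %d)\n",
              x$selected$k, x$n))
  print(tidy(x))
  invisible(x)
}

#' @export
print.sizer_map <- function(x, ...) {
  cat(sprintf("SiZer map: %d positions x %d bandwidths, alpha = %g, n = %d\n",
              length(unique(x$grid$x)), length(x$bandwidths), x$alpha, x$n))
  invisible(x)
}

#' @export
print.reconciled_assembly <- function(x, ...) {
  cat("Reconciled assembly\n")
  print(x$accounting)
  invisible(x)
}

#' Heatmap of a SiZer map
#'
#' The conventional SiZer display: position on the x axis, log bandwidth on
#' the y axis, cells coloured by significance code.
#'
#' @param object A `sizer_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sizer_map <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$x, y = log10(.data$bandwidth),
                               fill = .data$code)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      sig_increase = "#2166ac", sig_decrease = "#b2182b",
      not_sig = "#9970ab", sparse = "grey80")) +
    ggplot2::labs(x = "Ks", y = "log10 bandwidth", fill = NULL)
}

#' Histogram of a Ks sample with fitted mixture components
#'
#' @param object A `ks_mixture`.
#' @param sample The Ks sample the fit was computed on.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ks_mixture <- function(object, sample, bins = 60, ...) {
  comp <- tidy(object)
  xs <- seq(0, max(sample), length.out = 400)
  curves <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    tibble(component = factor(i), x = xs,
           y = comp$weight[i] * dnorm(xs, comp$mean[i], comp$sd[i]))
  })
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble(ks = sample),
      mapping = ggplot2::aes(x = .data$ks, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$component)) +
    ggplot2::labs(x = "Ks", y = "density")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
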