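#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols n row_number rename count distinct
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap keep
#' @importFrom stats dnorm qnorm rnorm runif rbinom rpois kmeans hclust cutree
#'   as.dist sd var density bw.nrd0 bw.SJ setNames rexp
NULL

# Deterministic child seeds: derive a stream of sub-seeds from one user seed so
# that independent stages never share random state. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(stream) * 7919L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors, as used when a scaffold is placed in "-" orientation.
#'
#' @param x Character vector of DNA sequences (IUPAC alphabet).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
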