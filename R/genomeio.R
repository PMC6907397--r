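# Assembly-level I/O and bookkeeping: FASTA round trips, N-run location,
# pseudochromosome stitching with 100-N spacers, and Table-1-style statistics.
# Coordinates are 1-based inclusive throughout (GFF3 convention).

#' Read a FASTA file into a scaffold tibble
#'
#' Three-way degenerate IUB codes (and every non-ACGTN character) are
#' normalised to `N` on read, mirroring common preprocessing of draft plant
#' assemblies before repeat modelling.
#'
#' @param path FASTA file.
#' @return Tibble with columns `scaffold_id`, `sequence`, `length`.
#' @export
read_scaffolds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  tibble(scaffold_id = names(x), sequence = unname(seqs),
         length = nchar(unname(seqs)))
}

#' Write a scaffold tibble to FASTA (80-column wrapped)
#'
#' @param scaffolds Tibble with `scaffold_id` and `sequence` columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scaffolds <- function(scaffolds, path) {
  x <- Biostrings::DNAStringSet(setNames(scaffolds$sequence,
                                         scaffolds$scaffold_id))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Scaffold-length summary statistics (N10/N50/N90)
#'
#' `Nxx` is the length of the scaffold at which the cumulative length, taken in
#' descending length order, first reaches xx% of the assembly total. Ties are
#' resolved by descending length then lexicographic id.
#'
#' @param scaffolds Tibble with `scaffold_id` and either `length` or `sequence`.
#' @return One-row tibble: `n_scaffolds`, `n10`, `n50`, `n90`, `total_bp`.
#' @export
assembly_stats <- function(scaffolds) {
  assert_that(nrow(scaffolds) > 0, "assembly_stats(): empty scaffold set")
  if (!"length" %in% names(scaffolds)) {
    scaffolds$length <- nchar(scaffolds$sequence)
  }
  ord <- order(-scaffolds$length, scaffolds$scaffold_id)
  len <- scaffolds$length[ord]
  total <- sum(as.numeric(len))
  cum <- cumsum(as.numeric(len))
  nxx <- function(frac) len[which(cum >= frac * total)[1]]
  tibble(
    n_scaffolds = nrow(scaffolds),
    n10 = nxx(0.10), n50 = nxx(0.50), n90 = nxx(0.90),
    total_bp = total
  )
}

#' Locate maximal runs of N in a sequence
#'
#' @param sequence DNA string.
#' @param min_len Minimum run length to report (default 20, the threshold used
#'   when excluding assembly gaps from chromosome-size estimates).
#' @return Tibble with 1-based inclusive `start`, `end`, `length`; zero rows if
#'   no qualifying run exists.
#' @export
find_n_runs <- function(sequence, min_len = 20) {
  assert_that(min_len >= 1, "find_n_runs(): min_len must be >= 1")
  if (nchar(sequence) == 0) {
    return(tibble(start = integer(0), end = integer(0), length = integer(0)))
  }
  r <- rle(strsplit(toupper(sequence), "")[[1]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Stitch ordered, oriented scaffolds into a pseudochromosome
#'
#' Scaffolds are concatenated in the given order with a spacer of exactly
#' `spacer` N's between consecutive scaffolds; "-" scaffolds contribute their
#' reverse complement. Offsets of every scaffold interval are recorded so gene
#' coordinates can be lifted.
#'
#' @param ordered Tibble with `scaffold_id`, `sequence`, `orientation`
#'   (each `"+"` or `"-"`; `"?"` is treated as `"+"`).
#' @param lg_id Label for the pseudochromosome.
#' @param spacer Number of N's between consecutive scaffolds (default 100).
#' @return List of class `pseudochromosome`: `lg_id`, `sequence`, and an
#'   `offsets` tibble (`scaffold_id`, `start`, `end`, `orientation`, 1-based
#'   inclusive).
#' @export
build_pseudochromosome <- function(ordered, lg_id = "LG", spacer = 100) {
  assert_that(nrow(ordered) > 0, "build_pseudochromosome(): empty input")
  orient <- ifelse(ordered$orientation == "-", "-", "+")
  seqs <- ifelse(orient == "-", revcomp(ordered$sequence), ordered$sequence)
  lens <- nchar(seqs)
  starts <- cumsum(c(1, lens[-length(lens)] + spacer))
  ends <- starts + lens - 1L
  pieces <- character(2 * length(seqs) - 1)
  pieces[seq(1, length(pieces), 2)] <- seqs
  if (length(seqs) > 1) {
    pieces[seq(2, length(pieces), 2)] <- strrep("N", spacer)
  }
  structure(
    list(
      lg_id = lg_id,
      sequence = paste(pieces, collapse = ""),
      offsets = tibble(scaffold_id = ordered$scaffold_id,
                       start = as.integer(starts), end = as.integer(ends),
                       orientation = orient),
      spacer = spacer
    ),
    class = "pseudochromosome"
  )
}

#' Split a pseudochromosome back into its scaffolds
#'
#' Inverse of [build_pseudochromosome()]; used for round-trip checks and for
#' emitting corrected scaffold sequences.
#'
#' @param pseudo A `pseudochromosome`.
#' @return Scaffold tibble in original orientation.
#' @export
split_pseudochromosome <- function(pseudo) {
  off <- pseudo$offsets
  seqs <- substring(pseudo$sequence, off$start, off$end)
  seqs <- ifelse(off$orientation == "-", revcomp(seqs), seqs)
  tibble(scaffold_id = off$scaffold_id, sequence = seqs, length = nchar(seqs))
}

#' Estimated chromosome size for one linkage group
#'
#' Sum of scaffold lengths assigned to the LG, optionally excluding assembly
#' gaps (runs of >= `n_run_min` N's), the two conventions used when reporting
#' per-chromosome sizes with and without gap inflation.
#'
#' @param lg_scaffolds Scaffold tibble (may be empty).
#' @param include_n_runs If `FALSE`, subtract all N-runs of length >=
#'   `n_run_min`.
#' @param n_run_min Minimum N-run length counted as a gap (default 20).
#' @return Size in bp.
#' @export
chromosome_size <- function(lg_scaffolds, include_n_runs = TRUE,
                            n_run_min = 20) {
  if (nrow(lg_scaffolds) == 0) return(0)
  if (!"length" %in% names(lg_scaffolds)) {
    lg_scaffolds$length <- nchar(lg_scaffolds$sequence)
  }
  total <- sum(as.numeric(lg_scaffolds$length))
  if (include_n_runs) return(total)
  gaps <- sum(map_dbl(lg_scaffolds$sequence, function(s) {
    sum(find_n_runs(s, min_len = n_run_min)$length)
  }))
  total - gaps
}

#' Lift gene models onto pseudochromosome coordinates
#'
#' Genes with scaffold coordinates are lifted through the stitch offsets.
#' On "-" scaffolds the interval is mirrored (`start' = L - end + 1`) and the
#' strand flipped before offsetting. Genes are then assigned consecutive order
#' indices along the pseudochromosome by start coordinate.
#'
#' @param pseudo A `pseudochromosome`.
#' @param genes Tibble with `gene_id`, `scaffold_id`, `start`, `end`, `strand`.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`, `order_index`.
#' @export
extract_pseudochromosome_cds <- function(pseudo, genes) {
  off <- pseudo$offsets
  g <- inner_join(genes, off, by = "scaffold_id",
                  suffix = c("", "_scf"))
  missing <- setdiff(genes$gene_id, g$gene_id)
  if (length(missing) > 0) {
    abort(paste0("extract_pseudochromosome_cds(): gene(s) outside offsets: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  scf_len <- g$end_scf - g$start_scf + 1L
  bad <- g$start < 1 | g$end > scf_len
  if (any(bad)) {
    abort(paste0("extract_pseudochromosome_cds(): gene(s) span outside their ",
                 "scaffold: ", paste(utils::head(g$gene_id[bad], 5),
                                     collapse = ", ")))
  }
  minus <- g$orientation == "-"
  s_local <- ifelse(minus, scf_len - g$end + 1L, g$start)
  e_local <- ifelse(minus, scf_len - g$start + 1L, g$end)
  strand <- ifelse(minus, ifelse(g$strand == "+", "-", "+"), g$strand)
  out <- tibble(
    gene_id = g$gene_id,
    chrom = pseudo$lg_id,
    start = as.integer(g$start_scf + s_local - 1L),
    end = as.integer(g$start_scf + e_local - 1L),
    strand = strand
  )
  out <- arrange(out, .data$start, .data$end, .data$gene_id)
  out$order_index <- seq_len(nrow(out))
  out
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, and `CDS` features (1-based inclusive) for a gene
#' table; one mRNA and one single-CDS exon per gene, matching the simplified
#' gene models this package works with.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  feat <- function(type, id, parent = NULL) {
    attr <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
    paste(genes$chrom, "wgdmap", type, genes$start, genes$end, ".",
          genes$strand, if (type == "CDS") "0" else ".", attr, sep = "\t")
  }
  lines <- c(
    "##gff-version 3",
    as.vector(rbind(
      feat("gene", genes$gene_id),
      feat("mRNA", paste0(genes$gene_id, ".1"), genes$gene_id),
      feat("CDS", paste0(genes$gene_id, ".1.cds"), paste0(genes$gene_id, ".1"))
    ))
  )
  writeLines(lines, path)
  invisible(path)
}
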