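#' Create a genome partition into fixed-width bins
#'
#' A partition tiles every chromosome left to right with non-overlapping
#' bins of `bin_width` bp (0-based, half-open); the last bin of a
#' chromosome may be shorter. The partition defines the observation
#' coordinate system for all signal tracks and the HMM.
#'
#' @param chrom_sizes Named integer vector (chromosome -> length in bp), or
#'   a two-column data frame (name, length), or the path to a two-column
#'   chromosome-sizes text file.
#' @param bin_width Bin width in bp (default 100).
#' @return An object of class `genome_partition`.
#' @examples
#' genome_partition(c(chr1 = 1000, chr2 = 550), bin_width = 100)
#' @export
genome_partition <- function(chrom_sizes, bin_width = 100L) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  }
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0), bin_width > 0)
  bin_width <- as.integer(bin_width)
  n_bins <- as.integer(ceiling(chrom_sizes / bin_width))
  structure(
    list(chrom_sizes = chrom_sizes, bin_width = bin_width,
         n_bins = setNames(n_bins, names(chrom_sizes))),
    class = "genome_partition"
  )
}

#' @export
print.genome_partition <- function(x, ...) {
  cat("<genome_partition> ", length(x$chrom_sizes), " chromosome(s), ",
      x$bin_width, " bp bins, ", sum(x$n_bins), " bins total\n", sep = "")
  invisible(x)
}

#' Read a two-column chromosome sizes file
#'
#' @param path Path to a tab- or space-separated file with chromosome name
#'   and length columns.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Bin coordinates of a partition as a tibble
#'
#' @param partition A [genome_partition()].
#' @return Tibble with columns `chrom`, `start`, `end`, `bin` (1-based index
#'   within the whole partition, chromosomes in declaration order).
#' @export
partition_bins <- function(partition) {
  stopifnot(inherits(partition, "genome_partition"))
  bw <- partition$bin_width
  chroms <- names(partition$chrom_sizes)
  pieces <- lapply(chroms, function(ch) {
    nb <- partition$n_bins[[ch]]
    start <- (seq_len(nb) - 1L) * bw
    tibble::tibble(
      chrom = ch, start = start,
      end = pmin(start + bw, partition$chrom_sizes[[ch]])
    )
  })
  out <- dplyr::bind_rows(pieces)
  out$bin <- seq_len(nrow(out))
  out
}

# map (chrom, pos) to global bin index; positions are 0-based bp
bin_index <- function(partition, chrom, pos) {
  bw <- partition$bin_width
  offs <- cumsum(c(0L, unname(partition$n_bins)))
  names(offs) <- c(names(partition$n_bins), ".end")
  idx <- match(chrom, names(partition$n_bins))
  local <- pmin(pmax(floor(pos / bw), 0), partition$n_bins[idx] - 1L)
  as.integer(offs[idx] + local + 1L)
}
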