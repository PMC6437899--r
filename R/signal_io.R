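#' Assemble a multi-feature signal matrix
#'
#' A signal matrix holds per-bin, per-feature non-negative integer read
#' counts over a genome partition, in the canonical feature order
#' (accessibility first, then H3K27ac, H3K4me1, H3K4me3). It is the
#' observation sequence the HMM consumes.
#'
#' @param partition A [genome_partition()].
#' @param counts Named list of integer vectors (one per feature, each of
#'   length `sum(partition$n_bins)`), or a matrix with feature columns.
#' @param pseudocount Pseudo-count added before any log transform
#'   (default 1); keeps logarithms finite at zero counts.
#' @param shift_bp Named integer vector of per-feature 5' read shifts used
#'   when the counts were binned (metadata only at this point).
#' @return A tibble of class `signal_matrix` with columns `chrom`, `start`,
#'   `end`, `bin` and one column per feature; partition, pseudocount and
#'   shifts are carried as attributes.
#' @export
signal_matrix <- function(partition, counts, pseudocount = 1L,
                          shift_bp = DEFAULT_SHIFTS) {
  stopifnot(inherits(partition, "genome_partition"), pseudocount >= 1)
  if (is.matrix(counts)) {
    counts <- as.list(as.data.frame(counts))
  }
  feats <- names(counts)
  stopifnot(!is.null(feats), !anyDuplicated(feats))
  nb <- sum(partition$n_bins)
  for (f in feats) {
    if (length(counts[[f]]) != nb) {
      stop("feature '", f, "' has ", length(counts[[f]]), " bins, expected ", nb)
    }
    if (any(counts[[f]] < 0)) stop("negative counts in feature '", f, "'")
  }
  # canonical order first, extras after
  ord <- c(intersect(CANONICAL_FEATURES, feats), setdiff(feats, CANONICAL_FEATURES))
  out <- partition_bins(partition)
  for (f in ord) out[[f]] <- as.integer(round(counts[[f]]))
  structure(out,
            class = c("signal_matrix", class(out)),
            partition = partition,
            features = ord,
            pseudocount = as.integer(pseudocount),
            shift_bp = shift_bp)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", nrow(x), " bins x ", length(signal_features(x)),
      " features (", paste(signal_features(x), collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' Feature names of a signal matrix
#' @param x A `signal_matrix`.
#' @return Character vector of feature column names in canonical order.
#' @export
signal_features <- function(x) attr(x, "features")

#' Genome partition of a signal matrix
#' @param x A `signal_matrix`.
#' @return The [genome_partition()] the matrix is binned on.
#' @export
signal_partition <- function(x) attr(x, "partition")

# counts as a plain numeric matrix (bins x features)
signal_counts <- function(x, features = signal_features(x)) {
  as.matrix(as.data.frame(x)[, features, drop = FALSE])
}

#' Count shifted read 5' ends per bin
#'
#' Each read contributes one count to the bin containing its shifted 5'
#' position: the shift is applied in read orientation (+`shift_bp` on the
#' forward strand, -`shift_bp` on the reverse strand), estimating the
#' fragment center for ChIP reads (default 75 bp for an expected 150 bp
#' fragment). Positions shifted off the chromosome are clipped to the
#' terminal bin. Reads on chromosomes absent from the partition are skipped
#' with a warning.
#'
#' @param reads Path to an indexed BAM file, or a tibble/data.frame with
#'   columns `chrom`, `pos` (1-based leftmost mapped position), `strand`
#'   ("+"/"-") and `width` (read length; used to locate the reverse-strand
#'   5' end).
#' @param partition A [genome_partition()].
#' @param shift_bp Non-negative integer shift in bp.
#' @return Integer vector of counts, one per partition bin.
#' @export
bin_reads <- function(reads, partition, shift_bp = 75L) {
  stopifnot(inherits(partition, "genome_partition"), shift_bp >= 0)
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_bam_reads(reads)
  }
  nb <- sum(partition$n_bins)
  if (nrow(reads) == 0L) return(integer(nb))
  known <- reads$chrom %in% names(partition$chrom_sizes)
  if (!all(known)) {
    warning(sum(!known), " read(s) on chromosomes absent from the partition were skipped")
    reads <- reads[known, , drop = FALSE]
    if (nrow(reads) == 0L) return(integer(nb))
  }
  fwd <- reads$strand != "-"
  # 0-based 5' end per orientation
  p5 <- ifelse(fwd, reads$pos - 1L, reads$pos - 1L + reads$width - 1L)
  shifted <- ifelse(fwd, p5 + shift_bp, p5 - shift_bp)
  idx <- bin_index(partition, reads$chrom, shifted)
  tabulate(idx, nbins = nb)
}

# minimal BAM reader: mapped reads only, fields needed for 5'-end binning
read_bam_reads <- function(path) {
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  tibble::tibble(
    chrom = as.character(b$rname),
    pos = b$pos,
    strand = as.character(b$strand),
    width = b$qwidth
  )
}

#' Load pre-binned coverage from a bedGraph or tabular bins file
#'
#' Record values are distributed over the partition bins they overlap,
#' proportionally to overlap length, then summed per bin and rounded to the
#' nearest integer. Records aligned to the partition grid therefore load
#' exactly. Records on unknown chromosomes are skipped with a warning.
#'
#' @param path Path to a 4-column bedGraph / tabular bins file
#'   (chrom, start, end, value; 0-based half-open). `track` and comment
#'   lines are ignored.
#' @param partition A [genome_partition()].
#' @return Integer vector of counts, one per partition bin.
#' @export
load_binned <- function(path, partition) {
  stopifnot(inherits(partition, "genome_partition"))
  nb <- sum(partition$n_bins)
  df <- suppressWarnings(
    readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                    col_types = "ciid", comment = "#", progress = FALSE))
  df <- df[!grepl("^track", df$chrom) & !is.na(df$start), , drop = FALSE]
  if (nrow(df) == 0L) return(integer(nb))
  known <- df$chrom %in% names(partition$chrom_sizes)
  if (!all(known)) {
    warning(sum(!known), " record(s) on chromosomes absent from the partition were skipped")
    df <- df[known, , drop = FALSE]
    if (nrow(df) == 0L) return(integer(nb))
  }
  bw <- partition$bin_width
  acc <- numeric(nb)
  first_bin <- floor(df$start / bw)
  last_bin <- floor((df$end - 1) / bw)
  simple <- first_bin == last_bin
  if (any(simple)) {
    i <- bin_index(partition, df$chrom[simple], df$start[simple])
    # full value lands in the one bin it overlaps
    acc <- acc + unname(tapply_sum(i, df$value[simple], nb))
  }
  if (any(!simple)) {
    sp <- df[!simple, , drop = FALSE]
    for (r in seq_len(nrow(sp))) {
      b0 <- floor(sp$start[r] / bw); b1 <- floor((sp$end[r] - 1) / bw)
      bins <- b0:b1
      lo <- pmax(bins * bw, sp$start[r])
      hi <- pmin((bins + 1) * bw, sp$end[r])
      frac <- (hi - lo) / (sp$end[r] - sp$start[r])
      idx <- bin_index(partition, rep(sp$chrom[r], length(bins)), lo)
      acc[idx] <- acc[idx] + sp$value[r] * frac
    }
  }
  as.integer(round(acc))
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, group = idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Pseudo-counted natural-log transform
#'
#' Returns `log(count + pseudocount)` so every output is finite; with the
#' default pseudo-count of 1, a zero count maps to exactly 0.
#'
#' @param x A `signal_matrix`, or a numeric vector/matrix of counts.
#' @param pseudocount Pseudo-count (default: the matrix's own, else 1).
#' @return Numeric matrix (bins x features) of log counts for a
#'   `signal_matrix`; otherwise an object shaped like `x`.
#' @export
apply_pseudocount_log <- function(x, pseudocount = NULL) {
  if (inherits(x, "signal_matrix")) {
    pc <- if (is.null(pseudocount)) attr(x, "pseudocount") else pseudocount
    return(log(signal_counts(x) + pc))
  }
  pc <- if (is.null(pseudocount)) 1L else pseudocount
  stopifnot(all(x >= 0), pc >= 1)
  log(x + pc)
}

#' Quantile-normalize a query track onto a reference distribution
#'
#' Replaces query values rank-wise by the reference quantiles: an
#' order-preserving rescaling that gives the query the reference's count
#' distribution, used to apply a model trained on one sample to another.
#' When the lengths differ, reference quantiles are linearly interpolated
#' at the query's plotting positions. Tied query values receive the mean of
#' the reference quantiles their rank span covers.
#'
#' @param query Numeric vector of query counts.
#' @param reference Numeric vector of reference counts (from the training
#'   sample), or a pre-sorted reference quantile vector.
#' @return Numeric vector, same length/order as `query`.
#' @examples
#' quantile_normalize(c(1, 2, 3), c(10, 20, 30)) # 10 20 30
#' quantile_normalize(c(5, 5, 5), c(1, 2, 3))    # 2 2 2
#' @export
quantile_normalize <- function(query, reference) {
  n <- length(query)
  if (length(reference) == 0L) stop("empty reference")
  if (n == 0L) return(numeric(0))
  ref_sorted <- sort(as.numeric(reference))
  m <- length(ref_sorted)
  rq <- if (m == n) ref_sorted else if (m == 1L) rep(ref_sorted, n) else {
    # interpolate reference quantiles at the query's plotting positions
    approx(x = seq(0, 1, length.out = m), y = ref_sorted,
           xout = seq(0, 1, length.out = n))$y
  }
  r_min <- rank(query, ties.method = "min")
  r_max <- rank(query, ties.method = "max")
  cs <- c(0, cumsum(rq))
  # mean of the reference quantiles spanned by each (possibly tied) rank
  (cs[r_max + 1] - cs[r_min]) / (r_max - r_min + 1)
}

#' Quantile-normalize every feature of a signal matrix to model references
#'
#' Applies [quantile_normalize()] per feature against the reference
#' quantiles stored in a trained model (or supplied directly), rounding the
#' results to non-negative integers so downstream code sees ordinary count
#' data.
#'
#' @param signal A `signal_matrix`.
#' @param reference A trained `crehmm_model` carrying reference quantiles,
#'   or a named list of reference count vectors per feature.
#' @return A `signal_matrix` with normalized counts.
#' @export
normalize_signal <- function(signal, reference) {
  stopifnot(inherits(signal, "signal_matrix"))
  ref <- if (inherits(reference, "crehmm_model")) reference$ref_quantiles else reference
  if (is.null(ref)) stop("reference carries no quantiles")
  feats <- signal_features(signal)
  missing <- setdiff(feats, names(ref))
  if (length(missing)) stop("no reference quantiles for feature(s): ",
                            paste(missing, collapse = ", "))
  counts <- lapply(feats, function(f) {
    as.integer(pmax(0, round(quantile_normalize(as.numeric(signal[[f]]), ref[[f]]))))
  })
  names(counts) <- feats
  signal_matrix(signal_partition(signal), counts,
                pseudocount = attr(signal, "pseudocount"),
                shift_bp = attr(signal, "shift_bp"))
}

#' Compress a count track to reference quantiles for model storage
#'
#' @param counts Integer vector of training-sample counts for one feature.
#' @param n_quantiles Number of stored quantile knots (default 1000);
#'   normalization interpolates between them.
#' @return Sorted numeric vector of reference quantiles.
#' @export
reference_quantiles <- function(counts, n_quantiles = 1000L) {
  stopifnot(length(counts) > 0)
  if (length(counts) <= n_quantiles) return(sort(as.numeric(counts)))
  unname(quantile(as.numeric(counts), probs = seq(0, 1, length.out = n_quantiles),
                  type = 7))
}

#' Write a per-bin track as bedGraph
#'
#' @param values Numeric vector, one value per partition bin.
#' @param partition A [genome_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, partition, path) {
  bins <- partition_bins(partition)
  readr::write_tsv(
    tibble::tibble(chrom = bins$chrom, start = bins$start, end = bins$end,
                   value = values),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
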