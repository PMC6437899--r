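#' Region tibbles
#'
#' Genomic region sets are plain tibbles with columns `chrom`, `start`,
#' `end` (0-based, half-open), and optionally `score` (CAGE tag counts or
#' peak scores) and `label` (one of `enhancer`, `promoter`, `background`,
#' `test_pos`, `test_neg`).
#'
#' @param chrom,start,end,score,label Column vectors (recycled as usual).
#' @return A region tibble.
#' @export
region_tibble <- function(chrom, start, end, score = NA_real_, label = NA_character_) {
  out <- tibble::tibble(chrom = as.character(chrom), start = as.numeric(start),
                        end = as.numeric(end), score = as.numeric(score),
                        label = as.character(label))
  stopifnot(all(out$start < out$end), all(out$start >= 0))
  out
}

empty_regions <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 score = numeric(), label = character())
}

as_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end))
}

granges_to_tibble <- function(gr, score = NA_real_, label = NA_character_) {
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = as.numeric(GenomicRanges::end(gr)),
                 score = score, label = label)
}

#' Read / write BED files as region tibbles
#'
#' 3-6 column BED; column 4 is kept as `label`, column 5 as `score` (used
#' for CAGE tag counts and peak scores).
#'
#' @param path File path.
#' @param regions A region tibble.
#' @return `read_bed`: a region tibble. `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  df <- suppressWarnings(
    readr::read_tsv(path, col_names = FALSE, comment = "#",
                    progress = FALSE, show_col_types = FALSE))
  if (nrow(df) == 0) return(empty_regions())
  df <- df[!grepl("^track|^browser", df[[1]]), , drop = FALSE]
  tibble::tibble(
    chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
    end = as.numeric(df[[3]]),
    score = if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NA_real_,
    label = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_)
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  out <- tibble::tibble(
    chrom = regions$chrom,
    start = format(regions$start, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    name = if (!is.null(regions$label)) dplyr::coalesce(regions$label, ".") else ".",
    score = if (!is.null(regions$score)) dplyr::coalesce(regions$score, 0) else 0)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Extract per-region observation matrices from a signal matrix
#'
#' @param signal A `signal_matrix`.
#' @param regions A region tibble.
#' @return List of log-count matrices (bins x features), one per region, in
#'   input order.
#' @export
region_observations <- function(signal, regions) {
  part <- signal_partition(signal)
  stopifnot(all(regions$chrom %in% names(part$chrom_sizes)))
  logx <- apply_pseudocount_log(signal)
  lapply(seq_len(nrow(regions)), function(i) {
    i0 <- bin_index(part, regions$chrom[i], regions$start[i])
    i1 <- bin_index(part, regions$chrom[i], regions$end[i] - 1)
    logx[i0:i1, , drop = FALSE]
  })
}

# per-region mean log-count per feature
region_feature_means <- function(signal, regions) {
  obs <- region_observations(signal, regions)
  do.call(rbind, lapply(obs, colMeans))
}

#' Filter CAGE regions by minimum tag count
#'
#' Bidirectionally transcribed CAGE regions mark candidate active
#' enhancers; regions with fewer than `min_tags` supporting tags (stored in
#' `score`) are removed.
#'
#' @param cage_regions Region tibble with tag counts in `score`.
#' @param min_tags Minimum tag count (kept if `score >= min_tags`).
#' @return Filtered region tibble.
#' @export
filter_cage <- function(cage_regions, min_tags) {
  dplyr::filter(cage_regions, .data$score >= min_tags)
}

#' Select the candidate cluster with the strongest active-enhancer signature
#'
#' Summarizes each region by its mean binned log-count per feature, runs
#' k-means (default k = 5) on the summaries, and returns the cluster
#' maximizing the activity score: the sum of across-region standard scores
#' of accessibility, H3K27ac and H3K4me1, minus the H3K4me3 standard score
#' (discarded clusters typically look like promoters, poised enhancers, or
#' signal-depleted regions).
#'
#' @param regions Candidate region tibble.
#' @param signal A `signal_matrix` covering the regions.
#' @param k Number of clusters (default 5).
#' @param seed k-means seed (default 0).
#' @return The member regions of the selected cluster.
#' @export
select_active_cluster <- function(regions, signal, k = 5L, seed = 0) {
  if (nrow(regions) < k) stop("fewer regions (", nrow(regions), ") than clusters (", k, ")")
  m <- region_feature_means(signal, regions)
  feats <- colnames(m)
  stopifnot(all(CANONICAL_FEATURES %in% feats))
  z <- scale(m)
  z[!is.finite(z)] <- 0 # constant feature across regions carries no signal
  if (nrow(unique(m)) < k) {
    warning("regions are not separable into ", k, " clusters; returning all")
    return(regions)
  }
  cl <- withr::with_seed(seed, kmeans(z, centers = k, nstart = 10, iter.max = 50))$cluster
  act <- z[, "atac"] + z[, "h3k27ac"] + z[, "h3k4me1"] - z[, "h3k4me3"]
  best <- which.max(vapply(seq_len(k), function(j) mean(act[cl == j]), numeric(1)))
  regions[cl == best, , drop = FALSE]
}

#' Match H3K27ac - accessibility - H3K27ac peak triplets
#'
#' The model topology requires training regions to start and end at
#' nucleosome positions. For each candidate region, this searches for an
#' accessibility (ATAC) peak overlapping the candidate, flanked by one
#' H3K27ac peak on each side (peak centers on opposite sides of the ATAC
#' peak center, all three distinct). The triplet span (leftmost start to
#' rightmost end) must be narrower than `max_width`; the span becomes the
#' output interval. Candidates without a qualifying triplet are dropped;
#' when several qualify, the narrowest span wins.
#'
#' @param candidates Candidate region tibble.
#' @param h3k27ac_peaks,atac_peaks Peak region tibbles.
#' @param max_width Maximum triplet span in bp (default 2000).
#' @return Region tibble of triplet spans (deduplicated), carrying the
#'   candidate's score/label.
#' @export
match_peak_triplets <- function(candidates, h3k27ac_peaks, atac_peaks,
                                max_width = 2000) {
  if (nrow(candidates) == 0) return(empty_regions())
  hits <- GenomicRanges::findOverlaps(as_granges(candidates), as_granges(atac_peaks))
  out <- vector("list", nrow(candidates))
  ac_center <- (atac_peaks$start + atac_peaks$end) / 2
  kc_center <- (h3k27ac_peaks$start + h3k27ac_peaks$end) / 2
  for (ci in unique(S4Vectors::queryHits(hits))) {
    ai <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == ci]
    best <- NULL
    for (a in ai) {
      same <- which(h3k27ac_peaks$chrom == atac_peaks$chrom[a])
      left <- same[kc_center[same] < ac_center[a]]
      right <- same[kc_center[same] > ac_center[a]]
      if (!length(left) || !length(right)) next
      l <- left[which.max(kc_center[left])]
      r <- right[which.min(kc_center[right])]
      span_start <- min(h3k27ac_peaks$start[l], atac_peaks$start[a])
      span_end <- max(h3k27ac_peaks$end[r], atac_peaks$end[a])
      if (span_end - span_start >= max_width) next
      if (is.null(best) || span_end - span_start < best$end - best$start) {
        best <- list(start = span_start, end = span_end)
      }
    }
    if (!is.null(best)) {
      out[[ci]] <- tibble::tibble(chrom = candidates$chrom[ci],
                                  start = best$start, end = best$end,
                                  score = candidates$score[ci],
                                  label = candidates$label[ci])
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_regions())
  dplyr::distinct(res, .data$chrom, .data$start, .data$end, .keep_all = TRUE)
}

#' Remove pairs of neighboring regions
#'
#' Any two regions whose edge-to-edge gap is below `min_distance` are both
#' removed, keeping only isolated elements (the model assumes flanking
#' background around every training region).
#'
#' @param regions Region tibble.
#' @param min_distance Minimum allowed gap in bp (default 2000).
#' @return Region tibble of isolated regions, coordinate-sorted.
#' @export
remove_neighbors <- function(regions, min_distance = 2000) {
  if (nrow(regions) <= 1) return(regions)
  regions <- dplyr::arrange(regions, .data$chrom, .data$start, .data$end)
  bad <- rep(FALSE, nrow(regions))
  same_next <- regions$chrom[-nrow(regions)] == regions$chrom[-1]
  gap <- regions$start[-1] - regions$end[-nrow(regions)]
  close_pair <- which(same_next & gap < min_distance)
  bad[close_pair] <- TRUE
  bad[close_pair + 1L] <- TRUE
  regions[!bad, , drop = FALSE]
}

#' Genomic proportions for the unbalanced background training set
#'
#' @param enhancer,active_promoter,inactive_promoter,genic,intergenic
#'   Category proportions; must sum to 1. Defaults approximate the reported
#'   functional-element composition of mammalian genomes.
#' @return Named numeric vector of proportions.
#' @export
background_proportions <- function(enhancer = 0.10, active_promoter = 0.05,
                                   inactive_promoter = 0.05, genic = 0.10,
                                   intergenic = 0.70) {
  p <- c(enhancer = enhancer, active_promoter = active_promoter,
         inactive_promoter = inactive_promoter, genic = genic,
         intergenic = intergenic)
  stopifnot(abs(sum(p) - 1) < 1e-9, all(p >= 0))
  p
}

#' Sample an unbalanced background training set
#'
#' Draws `n` fixed-width regions according to genomic category proportions
#' with respect to a gene annotation: genic, intergenic and
#' inactive-promoter draws come from the corresponding annotation-derived
#' territory; regions overlapping the supplied enhancer or active-promoter
#' sets are rejected and resampled; the enhancer and active-promoter quota
#' slots are filled with additional genic/intergenic draws (in proportion
#' 10:70), since those elements are excluded by construction.
#'
#' @param annotation Gene annotation tibble (`chrom`, `start`, `end`,
#'   optional `strand`); the TSS is the strand-aware 5' end.
#' @param enhancers,active_promoters Region tibbles to exclude.
#' @param partition A [genome_partition()] providing chromosome sizes.
#' @param proportions A [background_proportions()] vector.
#' @param n Number of regions to sample.
#' @param region_bp Region width in bp (default 2000).
#' @param promoter_bp Promoter window width around each TSS (default 2000).
#' @param seed Sampling seed (default 0).
#' @return Region tibble of `n` background regions (label `background`).
#' @export
sample_background <- function(annotation, enhancers, active_promoters,
                              partition, proportions = background_proportions(),
                              n = 1000L, region_bp = 2000, promoter_bp = 2000,
                              seed = 0) {
  sizes <- partition$chrom_sizes
  genome <- GenomicRanges::GRanges(names(sizes), IRanges::IRanges(1, unname(sizes)))
  genes <- GenomicRanges::reduce(as_granges(annotation))
  strand <- if (!is.null(annotation$strand)) annotation$strand else "+"
  tss <- ifelse(strand == "-", annotation$end - 1, annotation$start)
  prom <- GenomicRanges::reduce(GenomicRanges::trim(GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(1, tss + 1 - promoter_bp / 2), tss + promoter_bp / 2),
    seqlengths = sizes)))
  active_gr <- if (nrow(active_promoters)) as_granges(active_promoters)
               else GenomicRanges::GRanges()
  inactive_prom <- if (length(active_gr)) {
    prom[!IRanges::overlapsAny(prom, active_gr)]
  } else prom
  genic <- GenomicRanges::setdiff(genes, prom)
  intergenic <- GenomicRanges::setdiff(GenomicRanges::setdiff(genome, genes), prom)

  # quota: enhancer/active-promoter slots re-allocated to genic/intergenic
  realloc <- proportions[["enhancer"]] + proportions[["active_promoter"]]
  gshare <- proportions[["genic"]] /
    (proportions[["genic"]] + proportions[["intergenic"]])
  quota <- c(
    inactive_promoter = round(n * proportions[["inactive_promoter"]]),
    genic = round(n * (proportions[["genic"]] + realloc * gshare)))
  quota <- c(quota, intergenic = n - sum(quota))
  territories <- list(inactive_promoter = inactive_prom, genic = genic,
                      intergenic = intergenic)

  # the two exclusion sets may live on disjoint chromosomes; that is fine
  exclude <- GenomicRanges::reduce(suppressWarnings(c(
    if (nrow(enhancers)) as_granges(enhancers) else GenomicRanges::GRanges(),
    active_gr)))

  withr::with_seed(seed, {
    draws <- lapply(names(quota), function(cat) {
      m <- quota[[cat]]
      if (m == 0) return(empty_regions())
      terr <- territories[[cat]]
      if (length(terr) == 0) stop("no available territory for category '", cat, "'")
      got <- empty_regions()
      attempts <- 0L
      while (nrow(got) < m) {
        attempts <- attempts + 1L
        if (attempts > 200L) stop("could not place ", m, " '", cat,
                                  "' regions outside the exclusion sets")
        need <- m - nrow(got)
        w <- GenomicRanges::width(terr)
        iv <- sample.int(length(terr), need, replace = TRUE, prob = w)
        center0 <- GenomicRanges::start(terr)[iv] - 1 +
          floor(runif(need) * w[iv]) # region centers uniform in territory
        chrom <- as.character(GenomicRanges::seqnames(terr))[iv]
        start <- pmax(0, center0 - region_bp / 2)
        start <- pmin(start, sizes[chrom] - region_bp)
        cand <- region_tibble(chrom, start, start + region_bp,
                              label = "background")
        if (length(exclude)) {
          cand <- cand[!IRanges::overlapsAny(as_granges(cand), exclude), ,
                       drop = FALSE]
        }
        got <- dplyr::bind_rows(got, cand)
      }
      got[seq_len(m), , drop = FALSE]
    })
    dplyr::bind_rows(draws)
  })
}

#' Sample fixed-width windows avoiding an exclusion set
#'
#' Draws `n` windows of `region_bp` bp uniformly over the given
#' chromosomes, rejecting any window overlapping the exclusion regions.
#' Used to build test negatives and background pools that are guaranteed
#' element-free.
#'
#' @param partition A [genome_partition()] (chromosome sizes).
#' @param exclude Region tibble of intervals windows must not touch (may
#'   be empty).
#' @param n Number of windows.
#' @param region_bp Window width (default 2000).
#' @param chroms Restrict to these chromosomes (default all).
#' @param label Label column value (default `"test_neg"`).
#' @param seed Sampling seed.
#' @return Region tibble of `n` windows.
#' @export
sample_clear_windows <- function(partition, exclude, n, region_bp = 2000,
                                 chroms = NULL, label = "test_neg", seed = 0) {
  sizes <- partition$chrom_sizes
  if (!is.null(chroms)) sizes <- sizes[names(sizes) %in% chroms]
  stopifnot(length(sizes) > 0, all(sizes > region_bp))
  ex <- if (nrow(exclude)) as_granges(exclude) else GenomicRanges::GRanges()
  withr::with_seed(seed, {
    got <- empty_regions()
    attempts <- 0L
    while (nrow(got) < n) {
      attempts <- attempts + 1L
      if (attempts > 200L) stop("could not place ", n, " windows outside the exclusion set")
      need <- n - nrow(got)
      chrom <- sample(names(sizes), need, replace = TRUE, prob = as.numeric(sizes))
      start <- floor(runif(need) * (sizes[chrom] - region_bp))
      cand <- region_tibble(chrom, start, start + region_bp, label = label)
      if (length(ex)) {
        cand <- cand[!IRanges::overlapsAny(as_granges(cand), ex), , drop = FALSE]
      }
      got <- dplyr::bind_rows(got, cand)
    }
    got[seq_len(n), , drop = FALSE]
  })
}

#' Process raw test regions into a centered, promoter-free test set
#'
#' Merges regions closer than `merge_within` bp, drops merged regions
#' within `tss_exclude` bp of any annotated TSS, and re-centers each
#' survivor on the summit (midpoint) of its highest-scoring overlapping
#' accessibility peak, keeping the merged width. Survivors without an
#' overlapping peak are dropped.
#'
#' @param raw Raw test region tibble.
#' @param tss TSS tibble (1-bp positions, or intervals whose `start` is the
#'   TSS).
#' @param atac_peaks Accessibility peak tibble with `score`.
#' @param merge_within Maximum gap merged (default 500 bp).
#' @param tss_exclude Exclusion distance around TSS (default 2000 bp).
#' @return Processed region tibble.
#' @export
process_test_regions <- function(raw, tss, atac_peaks, merge_within = 500,
                                 tss_exclude = 2000) {
  if (nrow(raw) == 0) return(empty_regions())
  merged <- GenomicRanges::reduce(as_granges(raw), min.gapwidth = merge_within + 1)
  tss_gr <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(tss$start + 1, tss$start + 1))
  if (length(tss_gr)) {
    d <- GenomicRanges::distanceToNearest(merged, tss_gr)
    near <- rep(FALSE, length(merged))
    near[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance < tss_exclude
    merged <- merged[!near]
  }
  if (length(merged) == 0) return(empty_regions())
  peaks_gr <- as_granges(atac_peaks)
  hits <- GenomicRanges::findOverlaps(merged, peaks_gr)
  keep <- integer(0); new_start <- numeric(0); new_end <- numeric(0)
  for (q in unique(S4Vectors::queryHits(hits))) {
    pk <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == q]
    sc <- atac_peaks$score[pk]
    sc[is.na(sc)] <- 0
    top <- pk[which.max(sc)]
    summit <- floor((atac_peaks$start[top] + atac_peaks$end[top]) / 2)
    w <- GenomicRanges::width(merged[q])
    keep <- c(keep, q)
    new_start <- c(new_start, summit - floor(w / 2))
    new_end <- c(new_end, summit - floor(w / 2) + w)
  }
  if (!length(keep)) return(empty_regions())
  region_tibble(as.character(GenomicRanges::seqnames(merged))[keep],
                pmax(0, new_start), new_end, label = "test_pos")
}

#' Build cross-validation folds over enhancer training regions
#'
#' Partitions the enhancers into `k_folds` disjoint, near-equal folds. Each
#' test set combines one enhancer fold (label `test_pos`) with negatives
#' sampled from `background_pool` at genomic proportions (enhancers are
#' ~10% of elements, so 9 negatives per positive by default); each training
#' set is the remaining enhancers.
#'
#' @param enhancers Enhancer region tibble.
#' @param background_pool Region tibble of candidate negatives.
#' @param k_folds Number of folds (default 5).
#' @param neg_per_pos Negatives sampled per test positive (default 9).
#' @param seed Shuffling seed (default 0).
#' @return List of `k_folds` elements, each with `train` and `test` region
#'   tibbles.
#' @export
make_cv_folds <- function(enhancers, background_pool, k_folds = 5L,
                          neg_per_pos = 9L, seed = 0) {
  n <- nrow(enhancers)
  stopifnot(n >= k_folds)
  withr::with_seed(seed, {
    fold <- sample(rep(seq_len(k_folds), length.out = n))
    lapply(seq_len(k_folds), function(f) {
      test_pos <- enhancers[fold == f, , drop = FALSE]
      test_pos$label <- "test_pos"
      n_neg <- min(nrow(background_pool), neg_per_pos * nrow(test_pos))
      neg <- background_pool[sample.int(nrow(background_pool), n_neg), , drop = FALSE]
      neg$label <- "test_neg"
      train <- enhancers[fold != f, , drop = FALSE]
      train$label <- "enhancer"
      list(train = train, test = dplyr::bind_rows(test_pos, neg))
    })
  })
}
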