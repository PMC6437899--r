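#' Ground-truth constricted model for simulation
#'
#' Builds a full 22-state model encoding the expected epigenetic
#' environment of regulatory elements: enhancer modules with high
#' H3K4me1/H3K27ac nucleosome states and a highly accessible core,
#' promoter modules distinguished by high H3K4me3, and ten background
#' states with assorted low-level signal. Background-to-foreground entry
#' uses the default genome-composition rates. `"easy"` uses well-separated
#' emission means (>= 2 log-units on the discriminating features); `"hard"`
#' shrinks the foreground-background contrast to <= 0.5 log-units.
#'
#' @param separation `"easy"` or `"hard"`.
#' @param config A [composition_config()] for the entry rates.
#' @return A `crehmm_model` with known parameters.
#' @export
default_truth_model <- function(separation = c("easy", "hard"),
                                config = composition_config()) {
  separation <- match.arg(separation)
  feats <- CANONICAL_FEATURES
  # background: varied low-level signal (baseline, single-mark flavors)
  bg_mu <- matrix(0.3, 10, 4, dimnames = list(NULL, feats))
  bg_mu[2, "atac"] <- 0.9
  bg_mu[3, "h3k27ac"] <- 0.9
  bg_mu[4, "h3k4me1"] <- 1.1
  bg_mu[5, "h3k4me3"] <- 1.1
  bg_mu[6, ] <- 0.7
  bg_mu[7, ] <- 0.25 # depleted; means below ~0.25 are distorted by integer rounding
  bg_mu[8, c("h3k27ac", "h3k4me1")] <- 0.8
  bg_mu[9, "atac"] <- 0.6
  bg_mu[10, ] <- 0.5
  # foreground means, easy separation; the two states of each group are
  # genuinely distinct sub-flavors (real elements are heterogeneous), so a
  # 5-state fit on training regions is identifiable
  e_mu <- rbind(
    n1a = c(1.0, 3.6, 3.2, 0.8), n1b = c(1.4, 2.8, 4.0, 0.8),
    aa  = c(4.4, 3.4, 2.4, 0.8), ab  = c(3.8, 2.6, 2.0, 0.8))
  p_mu <- rbind(
    n1a = c(1.0, 3.2, 1.2, 3.4), n1b = c(1.4, 2.6, 0.8, 4.2),
    aa  = c(4.4, 3.0, 1.0, 3.2), ab  = c(3.8, 2.4, 1.4, 3.8))
  colnames(e_mu) <- colnames(p_mu) <- feats
  if (separation == "hard") {
    # pull foreground means toward the background baseline
    squeeze <- function(v) 0.5 + (v - 0.5) * 0.15
    e_mu <- squeeze(e_mu); p_mu <- squeeze(p_mu)
  }
  sigma <- 0.4

  bg_trans <- matrix(0.1 / 9, 10, 10)
  diag(bg_trans) <- 0.9
  bg <- constricted_hmm(
    roles = rep("BG", 10), initial = rep(0.1, 10), transitions = bg_trans,
    emissions = emission_model(paste0("BG", 1:10), feats, bg_mu,
                               matrix(sigma, 10, 4)),
    bin_width = config$bin_width)

  module <- function(fg_mu, prefix) {
    # order N1a, N1b, Aa, Ab, N2a, N2b; N2 emissions duplicate N1's
    mu <- fg_mu[c("n1a", "n1b", "aa", "ab", "n1a", "n1b"), , drop = FALSE]
    mask <- matrix(FALSE, 6, 6)
    mask[1:2, 1:4] <- TRUE; mask[3:4, 3:6] <- TRUE; mask[5:6, 5:6] <- TRUE
    trans <- matrix(0, 6, 6)
    trans[1, ] <- c(0.60, 0.05, 0.175, 0.175, 0, 0)
    trans[2, ] <- c(0.05, 0.60, 0.175, 0.175, 0, 0)
    trans[3, ] <- c(0, 0, 0.60, 0.05, 0.175, 0.175)
    trans[4, ] <- c(0, 0, 0.05, 0.60, 0.175, 0.175)
    trans[5, ] <- c(0, 0, 0, 0, 0.95, 0.05)
    trans[6, ] <- c(0, 0, 0, 0, 0.05, 0.95)
    constricted_hmm(
      roles = paste0(prefix, c("N1", "N1", "A", "A", "N2", "N2")),
      initial = c(0.5, 0.5, 0, 0, 0, 0), transitions = trans, mask = mask,
      emissions = emission_model(
        paste0(prefix, c("N1a", "N1b", "Aa", "Ab", "N2a", "N2b")), feats,
        mu, matrix(sigma, 6, 4)),
      bin_width = config$bin_width)
  }
  compose(bg, module(e_mu, "E_"), module(p_mu, "P_"), config)
}

#' Simulate a genome from a known constricted model
#'
#' Samples a state path from the model's initial distribution and
#' transition matrix, then draws per-bin, per-feature counts from the
#' state's log-normal emission: the pseudo-counted value is
#' `round(exp(Normal(mu, sigma)))` clamped to >= 1, so `log(count + 1)`
#' follows the emission model up to integer rounding. Truth elements are
#' extracted from the sampled roles exactly as [extract_elements()] would.
#'
#' @param model A `crehmm_model` with known parameters.
#' @param n_bins Bins per chromosome (a vector simulates several
#'   chromosomes, named `chr1`, `chr2`, ...).
#' @param seed RNG seed (default 0); everything is deterministic given it.
#' @return A `crehmm_truth` list: `model`, `partition`, `path` (integer
#'   states), `tracks` (a `signal_matrix`), `elements` (truth region
#'   tibble with `label` = element kind).
#' @export
simulate_truth <- function(model, n_bins, seed = 0) {
  stopifnot(all(n_bins >= 1))
  bw <- model$bin_width
  chroms <- paste0("chr", seq_along(n_bins))
  partition <- genome_partition(setNames(n_bins * bw, chroms), bin_width = bw)
  feats <- model$emissions$features
  withr::with_seed(seed, {
    path <- unlist(lapply(n_bins, function(nb) {
      cpp_sample_path(model$transitions, model$initial, runif(nb))
    }), use.names = FALSE)
    n <- length(path)
    counts <- lapply(feats, function(f) {
      fi <- match(f, feats)
      v <- exp(rnorm(n, model$emissions$mu[path, fi],
                     model$emissions$sigma[path, fi]))
      as.integer(pmax(1, round(v)) - 1L) # counts; +1 pseudo-count recovers v
    })
  })
  names(counts) <- feats
  tracks <- signal_matrix(partition, counts)
  track <- partition_bins(partition)
  track$role <- model$roles[path]
  track$score_enhancer <- 0
  track$score_promoter <- 0
  elements <- extract_elements(track)
  elements <- tibble::tibble(chrom = elements$chrom, start = elements$start,
                             end = elements$end, score = NA_real_,
                             label = elements$kind)
  structure(list(model = model, partition = partition, path = path,
                 tracks = tracks, elements = elements),
            class = "crehmm_truth")
}

#' @export
print.crehmm_truth <- function(x, ...) {
  cat("<crehmm_truth> ", length(x$path), " bins, ",
      sum(x$elements$label == "enhancer"), " enhancers, ",
      sum(x$elements$label == "promoter"), " promoters\n", sep = "")
  invisible(x)
}

#' Training region sets from a simulated truth
#'
#' Samples isolated truth enhancers and promoters (pairwise gap >= 2 kb,
#' mirroring the training-set geometry used on real data) and random
#' fixed-width background windows.
#'
#' @param truth A `crehmm_truth`.
#' @param n_enhancers,n_promoters Training regions per kind (default 300).
#' @param n_background Background windows (default 1000).
#' @param background_bp Background window width (default 2000 bp).
#' @param min_distance Isolation distance for foreground regions (bp).
#' @param min_bins Minimum region length in bins (default 5, the size of
#'   the foreground sub-model).
#' @param chroms Restrict training regions to these chromosomes (default:
#'   all), e.g. to hold chromosomes out for testing.
#' @param seed Sampling seed.
#' @return List of region tibbles: `enhancers`, `promoters`, `background`.
#' @export
truth_training_regions <- function(truth, n_enhancers = 300L,
                                   n_promoters = 300L, n_background = 1000L,
                                   background_bp = 2000, min_distance = 2000,
                                   min_bins = 5L, chroms = NULL, seed = 0) {
  elements <- truth$elements
  if (!is.null(chroms)) elements <- elements[elements$chrom %in% chroms, , drop = FALSE]
  bw <- truth$partition$bin_width
  elements <- elements[elements$end - elements$start >= min_bins * bw, , drop = FALSE]
  iso <- remove_neighbors(elements, min_distance = min_distance)
  pick <- function(kind, m) {
    pool <- iso[iso$label == kind, , drop = FALSE]
    if (nrow(pool) < m) {
      warning("only ", nrow(pool), " isolated ", kind, "s available (asked ", m, ")")
      m <- nrow(pool)
    }
    withr::with_seed(seed, pool[sample.int(nrow(pool), m), , drop = FALSE])
  }
  # background windows leave out enhancers and promoters, like the
  # annotation-based protocol does
  bg <- sample_clear_windows(truth$partition, truth$elements, n_background,
                             region_bp = background_bp, chroms = chroms,
                             label = "background", seed = seed + 1)
  list(enhancers = pick("enhancer", n_enhancers),
       promoters = pick("promoter", n_promoters),
       background = bg)
}

#' Export a simulated truth as plain-text fixture files
#'
#' Writes one bedGraph per feature (bin-aligned, so [load_binned()]
#' round-trips the counts exactly), the truth elements as BED, a
#' chromosome-sizes file, and training-region BEDs usable end-to-end.
#'
#' @param truth A `crehmm_truth`.
#' @param dir Output directory (created if needed).
#' @param seed Seed for training-region sampling.
#' @param ... Passed to [truth_training_regions()] (training-set sizes).
#' @return Named list of written paths, invisibly.
#' @export
export_fixture <- function(truth, dir, seed = 0, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  part <- truth$partition
  paths <- list()
  for (f in signal_features(truth$tracks)) {
    p <- file.path(dir, paste0(f, ".bedGraph"))
    write_bedgraph(truth$tracks[[f]], part, p)
    paths[[f]] <- p
  }
  paths$truth <- file.path(dir, "truth_elements.bed")
  write_bed(truth$elements, paths$truth)
  paths$chrom_sizes <- file.path(dir, "chrom.sizes")
  readr::write_tsv(tibble::tibble(chrom = names(part$chrom_sizes),
                                  size = unname(part$chrom_sizes)),
                   paths$chrom_sizes, col_names = FALSE, progress = FALSE)
  tr <- truth_training_regions(truth, seed = seed, ...)
  for (nm in names(tr)) {
    paths[[paste0("train_", nm)]] <- file.path(dir, paste0("train_", nm, ".bed"))
    write_bed(tr[[nm]], paths[[paste0("train_", nm)]])
  }
  invisible(paths)
}
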