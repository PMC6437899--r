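test_that("CAGE tag filtering uses an inclusive threshold", {
  r <- region_tibble("chr1", c(0, 1000, 2000), c(500, 1500, 2500),
                     score = c(11, 10, 12))
  expect_equal(nrow(filter_cage(r, 11)), 2)
  expect_equal(nrow(filter_cage(r, 0)), 3)
  expect_equal(nrow(filter_cage(r[0, ], 5)), 0)
})

test_that("neighbor removal drops both members of close pairs", {
  r <- region_tibble("chr1", c(0, 1500), c(100, 1600)) # gap 1400 < 2000
  expect_equal(nrow(remove_neighbors(r, 2000)), 0)
  r2 <- region_tibble("chr1", c(0, 3000), c(100, 3100)) # gap 2900
  expect_equal(nrow(remove_neighbors(r2, 2000)), 2)
  expect_equal(nrow(remove_neighbors(r[1, ], 2000)), 1)
  # chromosome boundaries do not count as neighbors
  r3 <- region_tibble(c("chr1", "chr2"), c(0, 500), c(100, 600))
  expect_equal(nrow(remove_neighbors(r3, 2000)), 2)
  # output minimum pairwise gap >= min_distance (property)
  set.seed(9)
  r4 <- region_tibble("chr1", s <- sort(sample.int(1e6, 200)) * 10, s * 10 + 50)
  out <- remove_neighbors(r4, 2000)
  if (nrow(out) > 1) {
    gaps <- out$start[-1] - out$end[-nrow(out)]
    expect_true(all(gaps >= 2000))
  }
})

test_that("peak triplets: flanked accessibility peaks within the width cap", {
  cand <- region_tibble("chr1", 400, 800, score = 5)
  k27 <- region_tibble("chr1", c(0, 900), c(300, 1200))
  atac <- region_tibble("chr1", 450, 750)
  out <- match_peak_triplets(cand, k27, atac, max_width = 2000)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 0)
  expect_equal(out$end, 1200)
  expect_equal(out$score, 5)
  # span >= 2 kb is rejected
  k27_far <- region_tibble("chr1", c(0, 2100), c(300, 2400))
  expect_equal(nrow(match_peak_triplets(cand, k27_far, atac, 2000)), 0)
  # missing flank on one side is rejected
  k27_left <- region_tibble("chr1", 0, 300)
  expect_equal(nrow(match_peak_triplets(cand, k27_left, atac, 2000)), 0)
})

test_that("test-region processing merges, excludes near-TSS, re-centers on peaks", {
  raw <- region_tibble("chr1", c(10000, 10600, 50000, 80000),
                       c(10200, 10800, 50200, 80200))
  tss <- tibble::tibble(chrom = "chr1", start = 52100) # 1900 bp from [50000,50200)
  atac <- region_tibble("chr1", c(10300, 80000), c(10500, 80100),
                        score = c(7, 2))
  out <- process_test_regions(raw, tss, atac, merge_within = 500,
                              tss_exclude = 2000)
  # the two 400 bp-gap regions merged into one, re-centered on the peak summit
  expect_equal(nrow(out), 2)
  merged <- out[out$end - out$start == 800, ]
  expect_equal(nrow(merged), 1)
  expect_equal((merged$start + merged$end) / 2, 10400) # summit of [10300,10500)
  # region 1900 bp from a TSS is dropped; at 2100 bp it survives
  raw2 <- region_tibble("chr1", c(50000, 49800), c(50200, 49900))
  tss2a <- tibble::tibble(chrom = "chr1", start = 52100)
  tss2b <- tibble::tibble(chrom = "chr1", start = 52300)
  atac2 <- region_tibble("chr1", 50000, 50200, score = 1)
  expect_equal(nrow(process_test_regions(raw2[1, ], tss2a, atac2)), 0)
  expect_equal(nrow(process_test_regions(raw2[1, ], tss2b, atac2)), 1)
  # survivor without an overlapping peak is dropped
  expect_equal(nrow(process_test_regions(raw2[1, ], tss2b, atac2[0, ])), 0)
})

test_that("active-cluster selection finds the planted enhancer cluster", {
  set.seed(17)
  p <- genome_partition(c(chr1 = 5e5), 100)
  n_reg <- 100
  starts <- seq(0, by = 5000, length.out = n_reg)
  cluster <- rep(1:5, each = 20)
  # per-cluster signal signatures: cluster 1 is the active-enhancer one
  sig <- list(
    `1` = c(30, 30, 30, 1),  # high atac/k27/me1, low me3 -> active enhancer
    `2` = c(30, 20, 1, 30),  # promoter-like
    `3` = c(1, 5, 20, 1),    # poised
    `4` = c(1, 1, 1, 1),     # depleted
    `5` = c(5, 1, 1, 5))
  feats <- c("atac", "h3k27ac", "h3k4me1", "h3k4me3")
  counts <- lapply(seq_along(feats), function(f) rep(1L, 5000))
  names(counts) <- feats
  for (i in seq_len(n_reg)) {
    bins <- (starts[i] / 100 + 1):(starts[i] / 100 + 10)
    for (f in seq_along(feats)) {
      counts[[f]][bins] <- rpois(10, sig[[cluster[i]]][f]) + 1L
    }
  }
  sm <- signal_matrix(p, counts)
  regions <- region_tibble("chr1", starts, starts + 1000)
  out <- select_active_cluster(regions, sm, k = 5, seed = 0)
  expect_setequal(which(regions$start %in% out$start), which(cluster == 1))
  expect_error(select_active_cluster(regions[1:3, ], sm, k = 5), "fewer regions")
  # degenerate identical regions: warn, return input
  same <- regions[rep(1, 10), ]
  expect_warning(all_back <- select_active_cluster(same, sm, k = 5, seed = 0))
  expect_equal(nrow(all_back), 10)
})

test_that("background sampling matches quotas and avoids exclusions", {
  part <- genome_partition(c(chr1 = 2e6, chr2 = 2e6), 100)
  genes <- region_tibble(rep(c("chr1", "chr2"), each = 10),
                         rep(seq(1e5, 1e6, length.out = 10), 2),
                         rep(seq(1e5, 1e6, length.out = 10) + 3e4, 2))
  genes$strand <- "+"
  enh <- region_tibble("chr1", seq(1.2e6, 1.6e6, by = 5e4),
                       seq(1.2e6, 1.6e6, by = 5e4) + 1000, label = "enhancer")
  act <- region_tibble("chr2", 1.5e6, 1.502e6, label = "promoter")
  bg <- sample_background(genes, enh, act, part, n = 100, seed = 0)
  expect_equal(nrow(bg), 100)
  expect_true(all(bg$end - bg$start == 2000))
  # no overlap with the exclusion sets
  ex <- dplyr::bind_rows(enh, act)
  expect_false(any(IRanges::overlapsAny(crehmm:::as_granges(bg),
                                        crehmm:::as_granges(ex))))
  # deterministic under the seed
  bg2 <- sample_background(genes, enh, act, part, n = 100, seed = 0)
  expect_identical(bg, bg2)
  expect_false(identical(bg, sample_background(genes, enh, act, part,
                                               n = 100, seed = 1)))
})

test_that("cross-validation folds are disjoint, exhaustive and reproducible", {
  enh <- region_tibble("chr1", (0:299) * 10000, (0:299) * 10000 + 1000)
  pool <- region_tibble("chr2", (0:4999) * 3000, (0:4999) * 3000 + 2000)
  folds <- make_cv_folds(enh, pool, k_folds = 5, seed = 0)
  expect_length(folds, 5)
  test_sizes <- vapply(folds, function(f) sum(f$test$label == "test_pos"), integer(1))
  expect_equal(test_sizes, rep(60L, 5))
  # disjoint positives whose union is the input
  pos <- lapply(folds, function(f) f$test[f$test$label == "test_pos", 1:3])
  all_pos <- dplyr::bind_rows(pos)
  expect_equal(nrow(dplyr::distinct(all_pos)), 300)
  expect_equal(dplyr::arrange(all_pos, start), dplyr::select(enh, 1:3))
  # train sets exclude the test fold
  for (f in folds) {
    expect_equal(nrow(f$train), 240)
    expect_equal(nrow(dplyr::intersect(f$train[, 1:3],
                                       f$test[f$test$label == "test_pos", 1:3])), 0)
    expect_equal(sum(f$test$label == "test_neg"), 540)
  }
  expect_identical(folds, make_cv_folds(enh, pool, k_folds = 5, seed = 0))
})

test_that("regions round-trip through BED", {
  r <- region_tibble("chr1", c(0, 5000), c(1000, 5800),
                     score = c(11, 4), label = c("enhancer", "background"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, f)
  r2 <- read_bed(f)
  expect_equal(r2$chrom, r$chrom)
  expect_equal(r2$start, r$start)
  expect_equal(r2$end, r$end)
  expect_equal(r2$score, r$score)
  expect_equal(r2$label, r$label)
})
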