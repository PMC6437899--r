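#' Score test regions by maximum posterior
#'
#' Each region's score is the maximum per-bin enhancer (or promoter)
#' accessibility posterior over the bins it covers.
#'
#' @param track A `prediction_track`.
#' @param test Region tibble (must lie on the track's partition).
#' @param what `"enhancer"` or `"promoter"` posterior.
#' @return The `test` tibble with a `score` column of posteriors in
#'   `[0, 1]`.
#' @export
score_test_regions <- function(track, test, what = c("enhancer", "promoter")) {
  what <- match.arg(what)
  part <- attr(track, "partition")
  if (!all(test$chrom %in% names(part$chrom_sizes)))
    stop("test region(s) off the track's partition")
  if (any(test$end > part$chrom_sizes[test$chrom]))
    stop("test region(s) extend past the chromosome end")
  col <- paste0("score_", what)
  score <- vapply(seq_len(nrow(test)), function(i) {
    i0 <- bin_index(part, test$chrom[i], test$start[i])
    i1 <- bin_index(part, test$chrom[i], test$end[i] - 1)
    max(track[[col]][i0:i1])
  }, numeric(1))
  out <- test
  out$score <- score
  out
}

#' Precision-recall curve and AUPRC
#'
#' Computes precision and recall at every distinct score threshold
#' (predicting positive when `score >= threshold`) and the area under the
#' curve by the average-precision (step-interpolation) estimator:
#' `sum over thresholds of (recall_i - recall_{i-1}) * precision_i`,
#' walking thresholds from high to low. This estimator is stated explicitly
#' because estimator choice shifts AUPRC by up to ~0.01.
#'
#' @param scores Numeric scores (higher = more enhancer-like).
#' @param labels Logical or 0/1 vector; both classes must be present.
#' @return A tibble of class `pr_curve` with columns `threshold`,
#'   `precision`, `recall`; the AUPRC is in `attr(x, "auprc")` and in
#'   [glance()].
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (all(labels) || !any(labels))
    stop("both classes must be present to compute a precision-recall curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  # operating points at the last index of each distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / sum(y)
  auprc <- sum(diff(c(0, recall)) * precision)
  out <- tibble::tibble(threshold = s[last], precision = precision,
                        recall = recall)
  structure(out, class = c("pr_curve", class(out)), auprc = auprc)
}

#' @rdname pr_curve
#' @param x A `pr_curve`.
#' @param ... Unused.
#' @export
glance.pr_curve <- function(x, ...) {
  tibble::tibble(auprc = attr(x, "auprc"), n_thresholds = nrow(x))
}

#' @rdname pr_curve
#' @param object A `pr_curve`.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  subtitle = sprintf("AUPRC = %.3f", attr(object, "auprc"))) +
    ggplot2::theme_minimal()
}

#' Viterbi operating point: precision and recall of hard predictions
#'
#' A test positive is recalled if overlapped (>= 1 bp) by at least one
#' predicted element of the given kind; precision is the fraction of
#' predicted elements overlapping a test positive among those overlapping
#' any test region. With no predictions, precision is reported as 0 with
#' the `defined` flag set to `FALSE`.
#'
#' @param elements A `predicted_elements` tibble.
#' @param test Region tibble with a `label` column (`test_pos` /
#'   `test_neg`).
#' @param kind Element kind to evaluate (default `"enhancer"`).
#' @return List with `precision`, `recall`, `defined`.
#' @export
viterbi_point <- function(elements, test, kind = "enhancer") {
  el <- elements[elements$kind == kind, , drop = FALSE]
  pos <- test[test$label == "test_pos", , drop = FALSE]
  if (nrow(pos) == 0) stop("no test positives")
  if (nrow(el) == 0) {
    warning("no predicted elements; precision undefined, reported as 0")
    return(list(precision = 0, recall = 0, defined = FALSE))
  }
  el_gr <- as_granges(el)
  pos_gr <- as_granges(pos)
  all_gr <- as_granges(test)
  recall <- mean(IRanges::overlapsAny(pos_gr, el_gr))
  touches_any <- IRanges::overlapsAny(el_gr, all_gr)
  if (!any(touches_any)) {
    warning("no predicted element overlaps the test set; precision undefined, reported as 0")
    return(list(precision = 0, recall = recall, defined = FALSE))
  }
  precision <- sum(IRanges::overlapsAny(el_gr, pos_gr)) / sum(touches_any)
  list(precision = precision, recall = recall, defined = TRUE)
}

#' Center-to-center distance to the nearest feature
#'
#' For each element, the absolute distance (bp) between the element center
#' and the nearest feature center on the same chromosome.
#'
#' @param elements Region tibble of predicted elements.
#' @param features Region tibble of features (peaks, TSS, ...); non-empty.
#' @return Numeric vector of distances (NA for elements on chromosomes
#'   without features), with `median` and `iqr` attributes.
#' @export
distance_to_features <- function(elements, features) {
  stopifnot(nrow(features) > 0)
  ec <- (elements$start + elements$end) / 2
  fc <- (features$start + features$end) / 2
  d <- vapply(seq_len(nrow(elements)), function(i) {
    j <- features$chrom == elements$chrom[i]
    if (!any(j)) return(NA_real_)
    min(abs(ec[i] - fc[j]))
  }, numeric(1))
  structure(d, median = median(d, na.rm = TRUE),
            iqr = unname(diff(quantile(d, c(0.25, 0.75), na.rm = TRUE))))
}

#' Fraction of predicted elements overlapping an annotated TSS
#'
#' TSS are treated as 1-bp positions; an element overlaps a TSS when its
#' interval contains the TSS coordinate. An inflated fraction flags false
#' enhancer calls at promoters.
#'
#' @param elements Region tibble of predicted elements.
#' @param tss TSS tibble (`start` is the TSS coordinate).
#' @return Fraction in `[0, 1]`; 0 with a warning for an empty element
#'   list.
#' @export
tss_overlap_fraction <- function(elements, tss) {
  if (nrow(elements) == 0) {
    warning("no elements; TSS overlap fraction reported as 0")
    return(0)
  }
  if (nrow(tss) == 0) return(0)
  tss_gr <- GenomicRanges::GRanges(tss$chrom,
                                   IRanges::IRanges(tss$start + 1, tss$start + 1))
  mean(IRanges::overlapsAny(as_granges(elements), tss_gr))
}
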