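#' Segment a genome with a trained constricted HMM
#'
#' Decodes each chromosome independently with the Viterbi algorithm (the
#' globally most likely path, which respects the model grammar and yields a
#' definite set of predicted elements without any score threshold) and
#' computes per-bin posterior probabilities by forward-backward. Summing
#' the posteriors of the accessibility states gives a per-bin prediction
#' certainty: `score_enhancer` sums over the enhancer-module A states,
#' `score_promoter` over the promoter-module A states.
#'
#' @param model A trained `crehmm_model`.
#' @param signal A `signal_matrix` with the model's features. If the model
#'   carries reference quantiles and `normalize = TRUE`, the signal is
#'   quantile-normalized to the training sample first.
#' @param normalize Quantile-normalize the signal to the model's embedded
#'   reference before decoding (default `FALSE`).
#' @return A tibble of class `prediction_track`: one row per bin with
#'   `chrom`, `start`, `end`, `bin`, `state`, `role`, `score_enhancer`,
#'   `score_promoter`.
#' @export
segment_genome <- function(model, signal, normalize = FALSE) {
  stopifnot(inherits(signal, "signal_matrix"))
  feats <- model$emissions$features
  missing <- setdiff(feats, signal_features(signal))
  if (length(missing)) stop("signal is missing model feature(s): ",
                            paste(missing, collapse = ", "))
  if (normalize) signal <- normalize_signal(signal, model)
  v <- viterbi(model, signal)
  fb <- forward_backward(model, signal)
  e_a <- model$roles == "E_A"
  p_a <- model$roles == "P_A"
  out <- partition_bins(signal_partition(signal))
  out$state <- v$path
  out$role <- model$roles[v$path]
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  out$score_enhancer <- clamp01(rowSums(fb$gamma[, e_a, drop = FALSE]))
  out$score_promoter <- clamp01(rowSums(fb$gamma[, p_a, drop = FALSE]))
  structure(out, class = c("prediction_track", class(out)),
            partition = signal_partition(signal), roles = model$roles,
            loglik = fb$loglik)
}

#' Extract predicted elements from a decoded track
#'
#' Maximal runs of enhancer-role (resp. promoter-role) bins become one
#' predicted element. The element score is the maximum per-bin
#' accessibility posterior inside the element; the N1/A/N2 substructure is
#' reported as sub-interval widths (the grammar guarantees the order
#' N1, A, N2 and at least one A bin per element).
#'
#' @param track A `prediction_track` from [segment_genome()].
#' @return Tibble of class `predicted_elements` with columns `chrom`,
#'   `start`, `end`, `kind` (`enhancer`/`promoter`), `score`, `n1_bp`,
#'   `a_bp`, `n2_bp`.
#' @export
extract_elements <- function(track) {
  group <- dplyr::case_when(
    startsWith(track$role, "E_") ~ "enhancer",
    startsWith(track$role, "P_") ~ "promoter",
    TRUE ~ "background")
  # run id changes at chromosome or group boundaries
  brk <- c(TRUE, group[-1] != group[-length(group)] |
                 track$chrom[-1] != track$chrom[-length(track$chrom)])
  run <- cumsum(brk)
  keep <- group != "background"
  if (!any(keep)) {
    return(structure(
      tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                     kind = character(), score = numeric(), n1_bp = numeric(),
                     a_bp = numeric(), n2_bp = numeric()),
      class = c("predicted_elements", class(tibble::tibble()))))
  }
  df <- tibble::tibble(
    run = run[keep], chrom = track$chrom[keep], start = track$start[keep],
    end = track$end[keep], kind = group[keep], role = track$role[keep],
    score = ifelse(group[keep] == "enhancer",
                   track$score_enhancer[keep], track$score_promoter[keep]),
    width = track$end[keep] - track$start[keep])
  out <- df |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom), start = min(.data$start),
      end = max(.data$end), kind = dplyr::first(.data$kind),
      score = max(.data$score),
      n1_bp = sum(.data$width[endsWith(.data$role, "_N1")]),
      a_bp = sum(.data$width[endsWith(.data$role, "_A")]),
      n2_bp = sum(.data$width[endsWith(.data$role, "_N2")]),
      .groups = "drop") |>
    dplyr::select(-"run")
  structure(out, class = c("predicted_elements", class(out)))
}

#' Write predicted elements to BED
#'
#' BED6-style output: name column = element kind, score column =
#' `round(1000 * score)`.
#'
#' @param elements A `predicted_elements` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(elements, path) {
  out <- tibble::tibble(
    chrom = elements$chrom,
    start = format(elements$start, scientific = FALSE, trim = TRUE),
    end = format(elements$end, scientific = FALSE, trim = TRUE),
    name = elements$kind,
    score = as.integer(round(1000 * elements$score)),
    strand = ".")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write per-bin posterior scores to bedGraph
#'
#' @param track A `prediction_track`.
#' @param path Output path.
#' @param what Which score to write: `"enhancer"` or `"promoter"`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(track, path, what = c("enhancer", "promoter")) {
  what <- match.arg(what)
  col <- paste0("score_", what)
  readr::write_tsv(
    tibble::tibble(chrom = track$chrom, start = track$start, end = track$end,
                   value = signif(track[[col]], 6)),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Plot the posterior accessibility scores of a decoded track
#'
#' @param object A `prediction_track`.
#' @param chrom Chromosome to show (default: the first).
#' @param ... Unused.
#' @return A ggplot object: per-bin enhancer/promoter accessibility
#'   posteriors along the chromosome.
#' @export
autoplot.prediction_track <- function(object, chrom = NULL, ...) {
  chrom <- chrom %||% object$chrom[1]
  df <- object |>
    dplyr::filter(.data$chrom == !!chrom) |>
    tidyr::pivot_longer(dplyr::all_of(c("score_enhancer", "score_promoter")),
                        names_to = "kind", values_to = "posterior",
                        names_prefix = "score_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$posterior,
                                   colour = .data$kind)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = paste0(chrom, " position (bp)"),
                  y = "posterior accessibility", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
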