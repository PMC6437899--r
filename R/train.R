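#' Train the full constricted model from signal and training regions
#'
#' Runs the complete supervised construction: for each of the enhancer and
#' promoter training sets, fit an unconstrained 5-state HMM
#' ([fit_foreground_5state()]), assign accessibility/nucleosome roles from
#' the emission means ([select_states()]), build the directed 6-state
#' module ([build_foreground_module()]) and refine its transitions by
#' constrained Viterbi training with frozen emissions
#' ([refine_foreground()]); fit the 10-state background model on the
#' background regions; and compose everything into the 22-state model with
#' genome-derived entry rates ([compose()]). Per-feature reference
#' quantiles of the training signal are embedded for later cross-sample
#' normalization.
#'
#' @param signal A `signal_matrix` for the training sample.
#' @param enhancers,promoters,background Region tibbles of training
#'   regions (e.g. from the region-construction functions or
#'   [truth_training_regions()]).
#' @param config A [composition_config()].
#' @param seed Seed for the k-means initializations.
#' @param max_iter Baum-Welch iteration cap.
#' @param verbose Print progress.
#' @return The trained 22-state `crehmm_model`.
#' @export
train_model <- function(signal, enhancers, promoters, background,
                        config = composition_config(), seed = 0,
                        max_iter = 100L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  fg <- list(enhancer = enhancers, promoter = promoters)
  modules <- lapply(names(fg), function(kind) {
    say("fitting 5-state ", kind, " model")
    obs <- region_observations(signal, fg[[kind]])
    m5 <- fit_foreground_5state(obs, seed = seed, max_iter = max_iter)
    sel <- select_states(m5, kind = kind)
    mod <- build_foreground_module(m5, sel, kind = kind)
    say("refining ", kind, " module by Viterbi training")
    refine_foreground(mod, obs)
  })
  say("fitting 10-state background model")
  bg_obs <- region_observations(signal, background)
  bg <- fit_background(bg_obs, seed = seed, max_iter = max_iter)
  rq <- lapply(setNames(signal_features(signal), signal_features(signal)),
               function(f) reference_quantiles(signal[[f]]))
  compose(bg, modules[[1]], modules[[2]], config, ref_quantiles = rq)
}

#' Heatmap of a model's emission means
#'
#' @param object A `crehmm_model`.
#' @param ... Unused.
#' @return A ggplot tile plot of `mu` per state and feature, annotated by
#'   role.
#' @export
autoplot.crehmm_model <- function(object, ...) {
  df <- tidy(object, what = "emissions")
  df$state <- factor(df$state, levels = unique(df$state))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$state,
                                   fill = .data$mu)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mu (log counts)") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$role), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
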