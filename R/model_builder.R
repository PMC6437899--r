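#' Fit an unconstrained HMM by Baum-Welch with k-means seeding
#'
#' Emission parameters are seeded by k-means on the log-counts (cluster
#' means and within-cluster standard deviations), transitions and initial
#' distribution start uniform, then Baum-Welch runs to convergence. The
#' seed makes the k-means initialization reproducible; inputs with fewer
#' distinct observation rows than states fall back to deterministic
#' quantile seeding.
#'
#' @param observations Log-count matrix, list of matrices, or
#'   `signal_matrix` (see [forward_backward()]).
#' @param n_states Number of states.
#' @param features Feature names (default: column names of the
#'   observations).
#' @param role Role label assigned to every state (default `"FG5"`).
#' @param seed Seed for the k-means initialization (default 0).
#' @param max_iter,tol Passed to [baum_welch()].
#' @param sigma_floor Lower bound on emission sigma during fitting (default
#'   0.2). Counts are integers, so the log-normal likelihood is unbounded
#'   when a state collapses onto a single count value; a variance floor of
#'   this size keeps EM away from those spikes while still letting states
#'   model near-constant coverage.
#' @return A fitted `crehmm_model` with an all-`TRUE` mask.
#' @export
fit_hmm_unsupervised <- function(observations, n_states, features = NULL,
                                 role = "FG5", seed = 0, max_iter = 100L,
                                 tol = 1e-4, sigma_floor = 0.2) {
  obs <- as_observation_list(observations)
  logx <- do.call(rbind, obs)
  if (is.null(features)) features <- colnames(logx) %||% paste0("f", seq_len(ncol(logx)))
  colnames(logx) <- features
  k <- as.integer(n_states)
  stopifnot(k >= 1, nrow(logx) >= k)
  nf <- length(features)
  mu <- matrix(0, k, nf); sigma <- matrix(1, k, nf)
  uniq <- unique(logx)
  if (nrow(uniq) >= k && k > 1) {
    km <- withr::with_seed(seed, kmeans(logx, centers = k, nstart = 5, iter.max = 50))
    mu <- unname(km$centers)
    for (j in seq_len(k)) {
      rows <- logx[km$cluster == j, , drop = FALSE]
      sigma[j, ] <- pmax(apply(rows, 2, sd), 0.1)
    }
    sigma[!is.finite(sigma)] <- 1
  } else {
    # deterministic fallback: spread states over per-feature quantiles
    for (f in seq_len(nf)) {
      mu[, f] <- quantile(logx[, f], probs = (seq_len(k) - 0.5) / k, type = 7)
    }
    s <- apply(logx, 2, sd)
    sigma <- matrix(pmax(rep(s, each = k), 0.1), k, nf)
    if (k > 1 && nrow(uniq) < k)
      warning("fewer distinct observations than states; quantile seeding used")
  }
  em <- emission_model(paste0("S", seq_len(k)), features, mu, sigma, sigma_floor)
  model <- constricted_hmm(roles = rep(role, k), initial = rep(1 / k, k),
                           transitions = matrix(1 / k, k, k), emissions = em)
  baum_welch(model, obs, max_iter = max_iter, tol = tol)
}

#' Fit the 5-state foreground HMM on training regions
#'
#' First step of the supervised two-step construction: a conventional
#' (unconstrained) 5-state HMM is learned on the training-region
#' observations; its states are subsequently assigned regulatory roles by
#' [select_states()].
#'
#' @param training_regions Observations for the training regions: a list of
#'   log-count matrices (one per region), e.g. from [region_observations()].
#' @inheritParams fit_hmm_unsupervised
#' @return A fitted 5-state `crehmm_model` (roles `FG5`).
#' @export
fit_foreground_5state <- function(training_regions, seed = 0, max_iter = 100L,
                                  tol = 1e-4) {
  obs <- as_observation_list(training_regions)
  stopifnot(length(obs) >= 1, all(vapply(obs, nrow, integer(1)) >= 5))
  fit_hmm_unsupervised(obs, n_states = 5L, role = "FG5", seed = seed,
                       max_iter = max_iter, tol = tol)
}

#' Fit the 10-state background HMM
#'
#' The background model is a conventional unconstrained HMM learned on an
#' unbalanced training set reflecting genomic proportions of functional
#' elements.
#'
#' @param background_regions Observations (as in [fit_foreground_5state()]).
#' @param n_states Number of background states (default 10).
#' @inheritParams fit_hmm_unsupervised
#' @return A fitted `crehmm_model` with all roles `BG`.
#' @export
fit_background <- function(background_regions, n_states = 10L, seed = 0,
                           max_iter = 100L, tol = 1e-4) {
  fit_hmm_unsupervised(background_regions, n_states = n_states, role = "BG",
                       seed = seed, max_iter = max_iter, tol = tol)
}

#' Assign accessibility and nucleosome roles to foreground states
#'
#' From the fitted 5-state model's emission parameters: the two states with
#' the highest accessibility/H3K27ac ratio become A-states; of the
#' remaining three, the two with the highest (enhancer) or lowest
#' (promoter) H3K4me1/H3K4me3 ratio become N-states; the fifth is
#' discarded. Ratios are computed on the log-normal distribution means
#' `exp(mu + sigma^2/2)`.
#'
#' @param model5 A 5-state `crehmm_model` over the four canonical features.
#' @param kind `"enhancer"` or `"promoter"`.
#' @return List with integer state indices `a_states`, `n_states` (ordered
#'   by selection rank) and `discarded`.
#' @export
select_states <- function(model5, kind = c("enhancer", "promoter")) {
  kind <- match.arg(kind)
  stopifnot(model5$n_states == 5,
            all(CANONICAL_FEATURES %in% model5$emissions$features))
  em <- model5$emissions
  means <- exp(em$mu + em$sigma^2 / 2)
  colnames(means) <- em$features
  ratio_a <- means[, "atac"] / means[, "h3k27ac"]
  ord_a <- order(-ratio_a, seq_along(ratio_a))
  if (isTRUE(all.equal(ratio_a[ord_a[2]], ratio_a[ord_a[3]])))
    warning("A-state selection tie broken toward the lowest state index")
  a_states <- ord_a[1:2]
  rest <- sort(ord_a[3:5])
  ratio_n <- means[rest, "h3k4me1"] / means[rest, "h3k4me3"]
  ord_n <- if (kind == "enhancer") order(-ratio_n, seq_along(ratio_n))
           else order(ratio_n, seq_along(ratio_n))
  if (isTRUE(all.equal(ratio_n[ord_n[2]], ratio_n[ord_n[3]])))
    warning("N-state selection tie broken toward the lowest state index")
  n_states <- rest[ord_n[1:2]]
  list(a_states = a_states, n_states = n_states,
       discarded = rest[ord_n[3]])
}

#' Build the directed 6-state foreground module
#'
#' Duplicates the selected N-states into N1 and N2 groups (N2 emissions are
#' exact copies of N1's) and arranges them with the A-states in the
#' directed order N1 -> A -> N2. Transitions conflicting with that
#' directionality (A back to N1, N2 back to A, N1 skipping A to N2) are
#' forbidden by the mask; allowed rows are initialized from the 5-state
#' fit's corresponding entries, renormalized; N2 intra-group rows are
#' copied from N1's.
#'
#' @param model5 The fitted 5-state model.
#' @param selection A [select_states()] result.
#' @param kind `"enhancer"` or `"promoter"` (sets the role prefix).
#' @return A 6-state `crehmm_model` with roles N1,N1,A,A,N2,N2 (prefixed
#'   `E_` or `P_`) and initial distribution uniform over the N1 states.
#' @export
build_foreground_module <- function(model5, selection,
                                    kind = c("enhancer", "promoter")) {
  kind <- match.arg(kind)
  pre <- if (kind == "enhancer") "E_" else "P_"
  ns <- selection$n_states; as_ <- selection$a_states
  stopifnot(length(ns) == 2, length(as_) == 2,
            !anyDuplicated(c(ns, as_, selection$discarded)))
  em5 <- model5$emissions
  sel <- c(ns, as_, ns) # N1 pair, A pair, N2 pair (copies of N1)
  em <- emission_model(
    states = paste0(pre, c("N1a", "N1b", "Aa", "Ab", "N2a", "N2b")),
    features = em5$features,
    mu = em5$mu[sel, , drop = FALSE], sigma = em5$sigma[sel, , drop = FALSE],
    sigma_floor = em5$sigma_floor)
  N1 <- 1:2; A <- 3:4; N2 <- 5:6
  mask <- matrix(FALSE, 6, 6)
  mask[N1, c(N1, A)] <- TRUE
  mask[A, c(A, N2)] <- TRUE
  mask[N2, N2] <- TRUE
  t5 <- model5$transitions
  trans <- matrix(0, 6, 6)
  for (i in 1:2) {
    trans[N1[i], N1] <- t5[ns[i], ns]
    trans[N1[i], A] <- t5[ns[i], as_]
    trans[A[i], A] <- t5[as_[i], as_]
    trans[A[i], N2] <- t5[as_[i], ns]
    trans[N2[i], N2] <- t5[ns[i], ns] # intra-group rows copied from N1
  }
  trans <- renormalize_rows(trans, mask)
  roles <- paste0(pre, c("N1", "N1", "A", "A", "N2", "N2"))
  constricted_hmm(roles = roles, initial = c(0.5, 0.5, 0, 0, 0, 0),
                  transitions = trans, mask = mask, emissions = em,
                  bin_width = model5$bin_width)
}

renormalize_rows <- function(trans, mask) {
  trans[!mask] <- 0
  rs <- rowSums(trans)
  for (i in seq_len(nrow(trans))) {
    if (rs[i] <= 1e-12) {
      if (!any(mask[i, ])) stop("transition row ", i, " has no allowed targets")
      warning("row ", i, " had no mass on allowed targets; set uniform")
      trans[i, mask[i, ]] <- 1 / sum(mask[i, ])
    } else {
      trans[i, ] <- trans[i, ] / rs[i]
    }
  }
  trans
}

#' Refine a foreground module by constrained Viterbi training
#'
#' Runs [viterbi_train()] on the training regions with the first bin
#' restricted to N1 roles and the last bin to N2 roles (training regions
#' start and end at nucleosome positions). Emissions are frozen; only the
#' transition parameters adapt.
#'
#' @param module A 6-state foreground module from
#'   [build_foreground_module()].
#' @param training_regions Observations (as in [fit_foreground_5state()]).
#' @param max_iter Maximum Viterbi-training iterations (default 50).
#' @return The refined `crehmm_model`.
#' @export
refine_foreground <- function(module, training_regions, max_iter = 50L) {
  n1 <- unique(grep("_N1$", module$roles, value = TRUE))
  n2 <- unique(grep("_N2$", module$roles, value = TRUE))
  stopifnot(length(n1) == 1, length(n2) == 1)
  viterbi_train(module, training_regions, start_roles = n1, end_roles = n2,
                max_iter = max_iter)
}

#' Genome composition statistics for background-to-foreground entry rates
#'
#' Defaults are the ENCODE-derived estimates for the human genome: 399,124
#' enhancers and 70,292 promoters in roughly 3e9 bp, binned at 100 bp;
#' these are taken as good estimates for other mammalian genomes too.
#'
#' @param n_enhancers_genome,n_promoters_genome Estimated element counts.
#' @param genome_bp Genome size in bp.
#' @param bin_width Bin width in bp.
#' @return A `composition_config` list.
#' @export
composition_config <- function(n_enhancers_genome = 399124,
                               n_promoters_genome = 70292,
                               genome_bp = 3e9, bin_width = 100L) {
  stopifnot(n_enhancers_genome >= 0, n_promoters_genome >= 0,
            genome_bp > 0, bin_width > 0)
  structure(list(n_enhancers_genome = n_enhancers_genome,
                 n_promoters_genome = n_promoters_genome,
                 genome_bp = genome_bp, bin_width = as.integer(bin_width)),
            class = "composition_config")
}

#' Background-to-foreground entry rates
#'
#' The per-bin rate of entering a foreground module from the background is
#' the expected number of elements per genome bin:
#' `rate = n_elements / (genome_bp / bin_width)`. With the default genome
#' statistics this gives 1.33% for enhancers and 0.23% for promoters.
#'
#' @param config A [composition_config()].
#' @return Named list with `enhancer` and `promoter` rates.
#' @examples
#' entry_rates(composition_config()) # 0.0133..., 0.0023...
#' @export
entry_rates <- function(config = composition_config()) {
  n_bins <- config$genome_bp / config$bin_width
  r <- list(enhancer = config$n_enhancers_genome / n_bins,
            promoter = config$n_promoters_genome / n_bins)
  if (r$enhancer + r$promoter >= 1) stop("entry rates exceed 1; check config")
  r
}

#' Compose background and foreground modules into the full 22-state model
#'
#' Stacks the 10 background states with the enhancer and promoter modules
#' (6 states each). Cross-module transitions are forbidden except
#' BG -> N1 (total mass per background row equals the configured entry
#' rate, split over the module's two N1 states) and N2 -> BG (each N2
#' state's exit mass is set to the corresponding N1 state's learned N1 -> A
#' mass, since N1 and N2 stretches are expected to be equally long, and is
#' distributed over background states by their stationary weights).
#' Background and N2 intra-module rows are rescaled to stay stochastic.
#' No emission parameter is altered.
#'
#' @param background A 10-state background `crehmm_model`.
#' @param enhancer_module,promoter_module Refined 6-state modules.
#' @param config A [composition_config()].
#' @param ref_quantiles Optional per-feature reference quantiles to embed
#'   for cross-sample normalization.
#' @return The combined 22-state `crehmm_model`; initial distribution is
#'   uniform over the background states.
#' @export
compose <- function(background, enhancer_module, promoter_module,
                    config = composition_config(), ref_quantiles = NULL) {
  feats <- background$emissions$features
  stopifnot(identical(feats, enhancer_module$emissions$features),
            identical(feats, promoter_module$emissions$features))
  rates <- entry_rates(config)
  kb <- background$n_states
  mods <- list(E = enhancer_module, P = promoter_module)
  k <- kb + 6L + 6L
  off <- c(E = kb, P = kb + 6L)
  trans <- matrix(0, k, k); mask <- matrix(FALSE, k, k)
  bg_idx <- seq_len(kb)
  bg_stat <- stationary_distribution(background$transitions)

  # background block, rescaled for the entry mass
  scale_bg <- 1 - rates$enhancer - rates$promoter
  trans[bg_idx, bg_idx] <- background$transitions * scale_bg
  mask[bg_idx, bg_idx] <- background$mask

  for (m in names(mods)) {
    mod <- mods[[m]]
    idx <- off[[m]] + 1:6
    trans[idx, idx] <- mod$transitions
    mask[idx, idx] <- mod$mask
    n1 <- idx[grepl("_N1$", mod$roles)]
    a <- idx[grepl("_A$", mod$roles)]
    n2 <- idx[grepl("_N2$", mod$roles)]
    rate <- if (m == "E") rates$enhancer else rates$promoter
    # entry mass split across the two N1 states by the module's stationary
    # occupancy; 50/50 when degenerate (the usual case: N2 absorbs within
    # the module)
    st <- stationary_distribution(mod$transitions)
    w <- st[grepl("_N1$", mod$roles)]
    w <- if (sum(w) > 1e-9) w / sum(w) else rep(0.5, 2)
    trans[bg_idx, n1] <- matrix(rate * w, kb, 2, byrow = TRUE)
    mask[bg_idx, n1] <- TRUE
    # N2 exit to background = the matching N1 state's N1->A mass
    n1_local <- which(grepl("_N1$", mod$roles))
    a_local <- which(grepl("_A$", mod$roles))
    for (i in 1:2) {
      exit <- sum(mod$transitions[n1_local[i], a_local])
      trans[n2[i], idx] <- mod$transitions[n1_local[i] + 4L, ] * (1 - exit)
      trans[n2[i], bg_idx] <- exit * bg_stat
      mask[n2[i], bg_idx] <- TRUE
    }
  }

  em_list <- c(list(background$emissions), lapply(mods, `[[`, "emissions"))
  em <- emission_model(
    states = unlist(lapply(em_list, `[[`, "states"), use.names = FALSE),
    features = feats,
    mu = do.call(rbind, lapply(em_list, `[[`, "mu")),
    sigma = do.call(rbind, lapply(em_list, `[[`, "sigma")),
    sigma_floor = background$emissions$sigma_floor)
  roles <- c(background$roles, enhancer_module$roles, promoter_module$roles)
  initial <- c(rep(1 / kb, kb), rep(0, 12))
  constricted_hmm(roles = roles, initial = initial, transitions = trans,
                  mask = mask, emissions = em,
                  bin_width = config$bin_width, ref_quantiles = ref_quantiles)
}

MODEL_FORMAT_VERSION <- "1.0"

#' Save / load a constricted HMM
#'
#' The model file is a self-describing JSON archive holding all parameters,
#' roles, the transition mask, feature names, bin width and any embedded
#' reference quantiles. Numbers are written with 17 significant digits, so
#' a save/load/save round trip is byte-identical.
#'
#' @param model A `crehmm_model`.
#' @param path File path.
#' @return `save_model`: `path` invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  validate_model(model)
  obj <- list(
    format = "crehmm-model", version = MODEL_FORMAT_VERSION,
    n_states = model$n_states, roles = model$roles,
    initial = model$initial,
    transitions = model$transitions, mask = model$mask * 1L,
    features = model$emissions$features,
    emission_states = model$emissions$states,
    mu = model$emissions$mu, sigma = model$emissions$sigma,
    sigma_floor = model$emissions$sigma_floor,
    bin_width = model$bin_width,
    ref_quantiles = model$ref_quantiles
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "crehmm-model"))
    stop("not a crehmm model file: ", path)
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stop("model format version mismatch: file has ", obj$version,
         ", this package reads ", MODEL_FORMAT_VERSION)
  if (is.null(obj$features) || !length(obj$features))
    stop("model file is missing feature names")
  em <- emission_model(obj$emission_states, obj$features,
                       matrix(obj$mu, obj$n_states),
                       matrix(obj$sigma, obj$n_states),
                       sigma_floor = obj$sigma_floor)
  rq <- obj$ref_quantiles
  if (!is.null(rq) && length(rq) == 0) rq <- NULL
  if (!is.null(rq)) rq <- lapply(rq, as.numeric)
  constricted_hmm(roles = obj$roles, initial = obj$initial,
                  transitions = matrix(obj$transitions, obj$n_states),
                  mask = matrix(obj$mask, obj$n_states) > 0,
                  emissions = em, bin_width = obj$bin_width,
                  ref_quantiles = rq)
}
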