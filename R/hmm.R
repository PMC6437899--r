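#' Construct a constricted hidden Markov model
#'
#' A constricted HMM is an HMM whose transition matrix carries a boolean
#' mask of allowed moves, enforcing the regulatory-element grammar
#' BG -> N1 -> A -> N2 -> BG: enhancer and promoter modules can only be
#' traversed in that order, so a decoded element always contains an
#' accessible core flanked by nucleosome states.
#'
#' @param roles Character vector of state role labels, one per state, from
#'   `BG`, `E_N1`, `E_A`, `E_N2`, `P_N1`, `P_A`, `P_N2`, `FG5`.
#' @param initial Initial state distribution (sums to 1; 0 for states
#'   disallowed as path starts).
#' @param transitions Row-stochastic transition matrix.
#' @param mask Logical matrix, `TRUE` where a transition is allowed;
#'   `transitions` must be 0 wherever `mask` is `FALSE`. Default: allow all.
#' @param emissions An [emission_model()] with one state per HMM state.
#' @param bin_width Bin width (bp) the model was trained at.
#' @param ref_quantiles Optional named list of per-feature reference
#'   quantiles for cross-sample normalization.
#' @return An object of class `crehmm_model`.
#' @export
constricted_hmm <- function(roles, initial, transitions, mask = NULL,
                            emissions, bin_width = 100L, ref_quantiles = NULL) {
  k <- length(roles)
  transitions <- as.matrix(transitions)
  if (is.null(mask)) mask <- matrix(TRUE, k, k)
  mask <- as.matrix(mask)
  model <- structure(
    list(n_states = k, roles = as.character(roles),
         initial = as.numeric(initial), transitions = unname(transitions),
         mask = unname(mask), emissions = emissions,
         bin_width = as.integer(bin_width), ref_quantiles = ref_quantiles),
    class = "crehmm_model")
  validate_model(model)
  model
}

#' Validate a constricted HMM's invariants
#'
#' Checks row-stochasticity, mask consistency (zero probability wherever a
#' transition is forbidden), initial-distribution normalization and
#' emission/state agreement.
#'
#' @param model A `crehmm_model`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  k <- model$n_states
  stopifnot(length(model$roles) == k, length(model$initial) == k,
            all(dim(model$transitions) == c(k, k)),
            all(dim(model$mask) == c(k, k)))
  if (any(abs(rowSums(model$transitions) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  if (any(model$transitions[!model$mask] != 0))
    stop("nonzero probability on a masked transition")
  if (any(model$transitions < 0)) stop("negative transition probability")
  if (abs(sum(model$initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
  if (any(model$initial < 0)) stop("negative initial probability")
  stopifnot(inherits(model$emissions, "emission_model"),
            length(model$emissions$states) == k)
  invisible(model)
}

#' @export
print.crehmm_model <- function(x, ...) {
  rt <- table(x$roles)
  cat("<crehmm_model> ", x$n_states, " states (",
      paste(names(rt), rt, sep = ":", collapse = ", "), "), features: ",
      paste(x$emissions$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a constricted HMM
#'
#' @param x A `crehmm_model`.
#' @param what `"transitions"` (one row per allowed state pair) or
#'   `"emissions"` (one row per state/feature).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crehmm_model <- function(x, what = c("transitions", "emissions"), ...) {
  what <- match.arg(what)
  if (what == "emissions") {
    out <- tidy(x$emissions)
    out$role <- x$roles[match(out$state, x$emissions$states)]
    return(out[, c("state", "role", "feature", "mu", "sigma", "mean")])
  }
  k <- x$n_states
  tibble::tibble(
    from = rep(seq_len(k), times = k), to = rep(seq_len(k), each = k),
    from_role = rep(x$roles, times = k), to_role = rep(x$roles, each = k),
    allowed = as.vector(x$mask), probability = as.vector(x$transitions)
  ) |> dplyr::filter(.data$allowed) |> dplyr::select(-"allowed")
}

#' One-row summary of a fitted model
#'
#' @param x A `crehmm_model`.
#' @param ... Unused.
#' @return Tibble with state counts, feature count, final log-likelihood
#'   and iteration count when the model was fitted iteratively.
#' @export
glance.crehmm_model <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states,
    n_features = length(x$emissions$features),
    n_allowed_transitions = sum(x$mask),
    log_likelihood = attr(x, "loglik") %||% NA_real_,
    n_iterations = attr(x, "iterations") %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize observations to a list of log-count matrices (bins x features)
as_observation_list <- function(observations, model = NULL) {
  if (inherits(observations, "signal_matrix")) {
    logx <- apply_pseudocount_log(observations)
    if (!is.null(model)) {
      feats <- model$emissions$features
      stopifnot(all(feats %in% colnames(logx)))
      logx <- logx[, feats, drop = FALSE]
    }
    return(split.data.frame(logx, factor(observations$chrom,
                                         levels = unique(observations$chrom))))
  }
  if (is.matrix(observations)) return(list(observations))
  stopifnot(is.list(observations), length(observations) > 0)
  observations
}

#' Posterior state probabilities by the forward-backward algorithm
#'
#' Computes `gamma[t, i] = P(state_t = i | observations)` for every bin by
#' scaled forward-backward, considering all admissible paths, plus the
#' total data log-likelihood. Numerically stable for sequences of 1e6+
#' bins.
#'
#' @param model A `crehmm_model`.
#' @param observations A log-count matrix (bins x features), a list of such
#'   matrices (one per sequence), or a `signal_matrix` (split per
#'   chromosome, pseudo-counted and logged automatically).
#' @return List with `gamma` (posterior matrix, sequences stacked in input
#'   order), `loglik` (total), `logliks` (per sequence) and `xi` (expected
#'   transition counts summed over sequences).
#' @export
forward_backward <- function(model, observations) {
  validate_model(model)
  if (any(rowSums(model$mask) == 0)) stop("model has an all-forbidden transition row")
  obs <- as_observation_list(observations, model)
  res <- lapply(obs, function(logx) {
    ll <- emission_loglik_matrix(model$emissions, logx)
    cpp_forward_backward(ll, model$transitions, model$initial)
  })
  gamma <- do.call(rbind, lapply(res, `[[`, "gamma"))
  xi <- Reduce(`+`, lapply(res, `[[`, "xi"))
  logliks <- vapply(res, `[[`, numeric(1), "loglik")
  list(gamma = gamma, loglik = sum(logliks), logliks = unname(logliks), xi = xi)
}

#' Viterbi decoding: the globally most likely state path
#'
#' Returns the jointly most probable state sequence. Unlike posterior
#' decoding, the Viterbi path respects the model's grammar by
#' construction — it can never contain a forbidden transition. Ties are
#' broken toward the lowest state index.
#'
#' @inheritParams forward_backward
#' @param start_roles,end_roles Optional character vectors of roles allowed
#'   at the first/last bin of each sequence (first/last-bin scores of other
#'   states are set to -Inf in the lattice; the model is not modified).
#' @return List with `path` (integer state indices, sequences concatenated
#'   in input order), `paths` (per-sequence list) and `logprob` (summed).
#' @export
viterbi <- function(model, observations, start_roles = NULL, end_roles = NULL) {
  validate_model(model)
  obs <- as_observation_list(observations, model)
  k <- model$n_states
  allow_start <- if (is.null(start_roles)) rep(TRUE, k) else model$roles %in% start_roles
  allow_end <- if (is.null(end_roles)) rep(TRUE, k) else model$roles %in% end_roles
  if (!any(allow_start) || !any(allow_end)) stop("constraints admit no state")
  logtrans <- suppressWarnings(log(model$transitions))
  loginit <- if (is.null(start_roles)) {
    suppressWarnings(log(model$initial))
  } else {
    # uniform over the allowed start roles (sub-model training convention)
    suppressWarnings(log(allow_start / sum(allow_start)))
  }
  paths <- vector("list", length(obs))
  logprob <- 0
  for (s in seq_along(obs)) {
    ll <- emission_loglik_matrix(model$emissions, obs[[s]])
    v <- cpp_viterbi(ll, logtrans, loginit, allow_start, allow_end)
    if (!isTRUE(v$ok)) {
      nm <- names(obs)[s] %||% as.character(s)
      stop("no admissible state path for sequence '", nm, "'")
    }
    paths[[s]] <- v$path
    logprob <- logprob + v$logprob
  }
  list(path = unlist(paths, use.names = FALSE), paths = paths, logprob = logprob)
}

# weighted normal fit of log-counts (reliability-weighted sd, floored)
weighted_norm_fit <- function(lx, w, sigma_floor) {
  sw <- sum(w)
  mu <- sum(w * lx) / sw
  denom <- sw - sum(w^2) / sw
  s2 <- if (denom > 0) sum(w * (lx - mu)^2) / denom else 0
  c(mu = mu, sigma = max(sqrt(max(s2, 0)), sigma_floor))
}

#' Baum-Welch (EM) parameter estimation
#'
#' Iterates forward-backward (E) and re-estimation (M): transitions from
#' expected counts restricted to the mask, emissions by gamma-weighted
#' log-normal fits, initial distribution from first-bin posteriors
#' restricted to its original support. The data log-likelihood is
#' non-decreasing across iterations.
#'
#' @inheritParams forward_backward
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default 1e-4).
#' @return The re-estimated `crehmm_model`, with attributes `loglik`,
#'   `loglik_trace` and `iterations`.
#' @export
baum_welch <- function(model, observations, max_iter = 100L, tol = 1e-4) {
  validate_model(model)
  obs <- as_observation_list(observations, model)
  k <- model$n_states
  nf <- length(model$emissions$features)
  logx_all <- do.call(rbind, obs)
  trace <- numeric(0)
  iter <- 0L
  if (max_iter >= 1L) repeat {
    fb <- forward_backward(model, obs)
    if (!is.finite(fb$loglik))
      stop("non-finite likelihood at iteration ", iter,
           " (trace: ", paste(signif(trace, 8), collapse = ", "), ")")
    trace <- c(trace, fb$loglik)
    iter <- iter + 1L
    # M step: transitions
    xi <- fb$xi * model$mask
    rs <- rowSums(xi)
    trans <- model$transitions
    nz <- rs > 0
    trans[nz, ] <- xi[nz, , drop = FALSE] / rs[nz]
    # initial: average first-bin posterior over sequences, on original support
    starts <- cumsum(c(1L, vapply(obs, nrow, integer(1))))[seq_along(obs)]
    g1 <- colMeans(fb$gamma[starts, , drop = FALSE])
    supp <- model$initial > 0
    init <- model$initial
    if (sum(g1[supp]) > 0) {
      init[supp] <- g1[supp] / sum(g1[supp])
      init[!supp] <- 0
    }
    # emissions: gamma-weighted log-normal moments
    mu <- model$emissions$mu; sigma <- model$emissions$sigma
    for (j in seq_len(k)) {
      w <- fb$gamma[, j]
      if (sum(w) <= 0) next
      for (f in seq_len(nf)) {
        fit <- weighted_norm_fit(logx_all[, f], w, model$emissions$sigma_floor)
        mu[j, f] <- fit[["mu"]]; sigma[j, f] <- fit[["sigma"]]
      }
    }
    model$transitions <- trans
    model$initial <- init
    model$emissions <- emission_model(model$emissions$states,
                                      model$emissions$features, mu, sigma,
                                      model$emissions$sigma_floor)
    if (iter >= max_iter) break
    if (length(trace) >= 2 && trace[iter] - trace[iter - 1] < tol) break
  }
  final <- if (length(trace)) forward_backward(model, obs)$loglik else NA_real_
  attr(model, "loglik") <- final
  attr(model, "loglik_trace") <- c(trace, final)
  attr(model, "iterations") <- iter
  model
}

#' Viterbi training with frozen emissions
#'
#' Hard-assignment EM: per iteration, each training sequence is decoded
#' with a constrained Viterbi pass (first bin restricted to `start_roles`,
#' last bin to `end_roles`), then transitions are re-estimated from the
#' pooled path transition counts (mask respected, add-epsilon smoothing on
#' allowed transitions, rows renormalized). Emission parameters are never
#' modified, preventing states selected for a particular regulatory role
#' from drifting. Stops when no path changes or `max_iter` is reached.
#'
#' @inheritParams forward_backward
#' @param start_roles,end_roles Roles allowed at sequence starts/ends
#'   (defaults `c("E_N1","P_N1","N1")` / `c("E_N2","P_N2","N2")` cover the
#'   module-training case where regions start and end at nucleosomes).
#' @param max_iter Maximum iterations (default 50).
#' @param eps Smoothing count added to every allowed transition before
#'   renormalization (default 1e-6), so finite training data never
#'   collapses an allowed transition to exactly zero.
#' @return The re-estimated `crehmm_model` (emissions bitwise identical to
#'   input), with attributes `iterations` and `converged`.
#' @export
viterbi_train <- function(model, observations,
                          start_roles = c("E_N1", "P_N1", "N1"),
                          end_roles = c("E_N2", "P_N2", "N2"),
                          max_iter = 50L, eps = 1e-6) {
  validate_model(model)
  obs <- as_observation_list(observations, model)
  k <- model$n_states
  prev_paths <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    v <- viterbi(model, obs, start_roles = start_roles, end_roles = end_roles)
    if (identical(v$paths, prev_paths)) { converged <- TRUE; iter <- iter - 1L; break }
    prev_paths <- v$paths
    counts <- matrix(0, k, k)
    for (p in v$paths) {
      if (length(p) < 2L) next
      idx <- (p[-length(p)] - 1L) * k + p[-1L]
      counts <- counts + matrix(tabulate(idx, nbins = k * k), k, k, byrow = TRUE)
    }
    counts <- counts + eps
    counts[!model$mask] <- 0
    rs <- rowSums(counts)
    trans <- model$transitions
    nz <- rs > 0
    trans[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
    model$transitions <- trans
  }
  attr(model, "iterations") <- iter
  attr(model, "converged") <- converged
  model
}

# stationary distribution of a row-stochastic matrix (power iteration)
stationary_distribution <- function(trans, iters = 2000L, tol = 1e-12) {
  k <- nrow(trans)
  p <- rep(1 / k, k)
  for (i in seq_len(iters)) {
    p2 <- as.vector(p %*% trans)
    p2 <- p2 / sum(p2)
    if (max(abs(p2 - p)) < tol) return(p2)
    p <- p2
  }
  p
}
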