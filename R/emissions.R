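#' Log-normal emission models
#'
#' Per-state, per-feature read counts are modelled with independent
#' log-normal distributions: for state `s` and feature `f`, the
#' pseudo-counted count `v >= 1` has density
#' `dnorm(log v; mu, sigma) / v`. Independence across features makes the
#' state log-likelihood the sum of per-feature log-densities, and fitting
#' reduces to (weighted) moments of `log v`.
#'
#' @param states Character vector of state identifiers.
#' @param features Character vector of feature names (canonical order).
#' @param mu,sigma Numeric matrices (states x features) of log-count means
#'   and standard deviations; `sigma` is floored at `sigma_floor`.
#' @param sigma_floor Lower bound on sigma (default 1e-3); keeps densities
#'   proper for states that capture a constant signal.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(states, features, mu, sigma, sigma_floor = 1e-3) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  stopifnot(nrow(mu) == length(states), ncol(mu) == length(features),
            all(dim(mu) == dim(sigma)), all(is.finite(mu)), all(is.finite(sigma)))
  sigma <- pmax(sigma, sigma_floor)
  dimnames(mu) <- dimnames(sigma) <- list(states, features)
  structure(list(states = as.character(states), features = as.character(features),
                 mu = mu, sigma = sigma, sigma_floor = sigma_floor),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat("<emission_model> ", length(x$states), " states x ",
      length(x$features), " features (log-normal)\n", sep = "")
  invisible(x)
}

#' Tidy an emission model into one row per state/feature
#'
#' @param x An `emission_model`.
#' @param ... Unused.
#' @return Tibble with columns `state`, `feature`, `mu`, `sigma`, `mean`
#'   (the distribution mean `exp(mu + sigma^2/2)` on the count scale).
#' @export
tidy.emission_model <- function(x, ...) {
  tibble::tibble(
    state = rep(x$states, times = length(x$features)),
    feature = rep(x$features, each = length(x$states)),
    mu = as.vector(x$mu),
    sigma = as.vector(x$sigma),
    mean = exp(as.vector(x$mu) + as.vector(x$sigma)^2 / 2)
  )
}

#' Fit a log-normal distribution by weighted moments
#'
#' `mu` is the weighted mean of `log(values)`; `sigma` the weighted
#' standard deviation using the reliability-weights (unbiased) form
#' `sum(w (x - mu)^2) / (sum(w) - sum(w^2)/sum(w))`, which reduces to the
#' usual n-1 sample variance for unit weights. `sigma` is floored so a
#' state capturing a single coverage value still has a proper density.
#'
#' @param values Pseudo-counted counts (all >= 1).
#' @param weights Non-negative weights, one per value (default: unit).
#' @param sigma_floor Lower bound on sigma (default 1e-3).
#' @return List with elements `mu` and `sigma`.
#' @export
fit_lognormal <- function(values, weights = NULL, sigma_floor = 1e-3) {
  stopifnot(length(values) > 0, all(values >= 1))
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(weights >= 0))
  sw <- sum(weights)
  if (sw <= 0) stop("all weights are zero")
  lx <- log(values)
  mu <- sum(weights * lx) / sw
  denom <- sw - sum(weights^2) / sw
  s2 <- if (denom > 0) sum(weights * (lx - mu)^2) / denom else 0
  list(mu = mu, sigma = max(sqrt(max(s2, 0)), sigma_floor))
}

#' Log-density of a pseudo-counted count under log-normal parameters
#'
#' @param params List with `mu`, `sigma` (as from [fit_lognormal()]).
#' @param value Pseudo-counted count(s), >= 1.
#' @return Log-density, vectorized over `value`.
#' @export
log_density <- function(params, value) {
  stopifnot(all(value >= 1))
  dnorm(log(value), params$mu, params$sigma, log = TRUE) - log(value)
}

#' Per-state log-likelihood of one observation vector
#'
#' Features are independent given the state, so the log-likelihood is the
#' sum over features of the per-feature log-normal log-density.
#'
#' @param model An `emission_model`.
#' @param state A state identifier or index.
#' @param observation Named numeric vector of pseudo-counted counts, one
#'   per model feature.
#' @return Scalar log-likelihood.
#' @export
state_log_likelihood <- function(model, state, observation) {
  stopifnot(inherits(model, "emission_model"))
  s <- if (is.character(state)) match(state, model$states) else as.integer(state)
  if (is.na(s)) stop("unknown state")
  if (is.null(names(observation))) {
    stopifnot(length(observation) == length(model$features))
    names(observation) <- model$features
  }
  missing <- setdiff(model$features, names(observation))
  if (length(missing)) stop("observation is missing feature(s): ",
                            paste(missing, collapse = ", "))
  v <- observation[model$features]
  sum(dnorm(log(v), model$mu[s, ], model$sigma[s, ], log = TRUE) - log(v))
}

# emission log-likelihood matrix: bins x states, from a log-count matrix
# (bins x features). The -sum(log v) Jacobian term is constant across
# states per bin; it is included so log-likelihoods are true log-densities.
emission_loglik_matrix <- function(emissions, logx) {
  stopifnot(inherits(emissions, "emission_model"),
            ncol(logx) == length(emissions$features))
  n <- nrow(logx); k <- length(emissions$states)
  jac <- -rowSums(logx)
  ll <- matrix(0, n, k)
  for (j in seq_len(k)) {
    acc <- jac
    for (f in seq_along(emissions$features)) {
      acc <- acc + dnorm(logx[, f], emissions$mu[j, f], emissions$sigma[j, f],
                         log = TRUE)
    }
    ll[, j] <- acc
  }
  ll
}

#' Kolmogorov-Smirnov distance between counts and a log-normal fit
#'
#' Sup-norm distance between the empirical CDF of `log(values)` and the
#' Normal(mu, sigma) CDF. A state modelling a single coverage value is
#' assigned distance 0 by convention.
#'
#' @param values Pseudo-counted counts (>= 1), non-empty.
#' @param params List with `mu`, `sigma`.
#' @return Distance in `[0, 1]`.
#' @export
ks_fit_distance <- function(values, params) {
  stopifnot(length(values) > 0)
  if (length(unique(values)) == 1L) return(0)
  x <- sort(log(values))
  n <- length(x)
  p <- pnorm(x, params$mu, params$sigma)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}
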