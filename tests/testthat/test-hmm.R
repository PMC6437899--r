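test_that("forward-backward and Viterbi agree with exhaustive enumeration", {
  for (seed in 1:30) {
    k <- sample(2:3, 1)
    n <- sample(3:8, 1)
    inst <- random_hmm_instance(k, n, seed = seed)
    oracle <- brute_force_hmm(inst$model$initial, inst$model$transitions,
                              inst$logemit)
    fb <- forward_backward(inst$model, inst$logx)
    expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-9)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-9)
    v <- viterbi(inst$model, inst$logx)
    expect_equal(v$logprob, oracle$best_logp, tolerance = 1e-9)
    expect_equal(v$path, oracle$best_path)
  }
})

test_that("single-state model: gamma is 1 and loglik is the emission sum", {
  em <- emission_model("s", c("f1", "f2"), matrix(1, 1, 2), matrix(0.5, 1, 2))
  m <- constricted_hmm("BG", 1, matrix(1, 1, 1), emissions = em)
  logx <- matrix(rnorm(20, 1, 0.3), 10, dimnames = list(NULL, c("f1", "f2")))
  fb <- forward_backward(m, logx)
  expect_true(all(fb$gamma == 1))
  expect_equal(fb$loglik, sum(crehmm:::emission_loglik_matrix(em, logx)))
  expect_equal(viterbi(m, logx)$path, rep(1L, 10))
})

test_that("gamma rows sum to 1 and masked transitions are impossible", {
  set.seed(5)
  inst <- random_hmm_instance(3, 50, seed = 99)
  m <- inst$model
  # forbid 1 -> 3
  m$mask[1, 3] <- FALSE
  m$transitions[1, ] <- c(0.5, 0.5, 0)
  fb <- forward_backward(m, inst$logx)
  expect_equal(rowSums(fb$gamma), rep(1, 50), tolerance = 1e-9)
  v <- viterbi(m, inst$logx)
  pairs <- cbind(v$path[-50], v$path[-1])
  expect_true(all(m$mask[pairs]))
})

test_that("adding a constant to all emission log-densities leaves the Viterbi path unchanged", {
  inst <- random_hmm_instance(3, 40, seed = 123)
  lt <- suppressWarnings(log(inst$model$transitions))
  li <- suppressWarnings(log(inst$model$initial))
  all_ok <- rep(TRUE, 3)
  v1 <- crehmm:::cpp_viterbi(inst$logemit, lt, li, all_ok, all_ok)
  v2 <- crehmm:::cpp_viterbi(inst$logemit + 7.5, lt, li, all_ok, all_ok)
  expect_equal(v1$path, v2$path)
})

test_that("Viterbi ties break toward the lowest state index", {
  em <- emission_model(c("a", "b"), "f", matrix(1, 2, 1), matrix(0.5, 2, 1))
  m <- constricted_hmm(c("BG", "BG"), c(0.5, 0.5), matrix(0.5, 2, 2),
                       emissions = em)
  logx <- matrix(rnorm(6, 1), 6, 1, dimnames = list(NULL, "f"))
  expect_equal(viterbi(m, logx)$path, rep(1L, 6))
})

test_that("Baum-Welch recovers a known 2-state model and is monotone", {
  set.seed(21)
  feats <- c("f1", "f2")
  em <- emission_model(c("lo", "hi"), feats,
                       mu = rbind(c(0.5, 0.6), c(2.5, 2.2)),
                       sigma = matrix(0.5, 2, 2))
  truth <- constricted_hmm(c("BG", "BG"), c(0.5, 0.5),
                           rbind(c(0.95, 0.05), c(0.10, 0.90)), emissions = em)
  n <- 2e4
  path <- crehmm:::cpp_sample_path(truth$transitions, truth$initial, runif(n))
  logx <- sapply(1:2, function(f) rnorm(n, em$mu[path, f], em$sigma[path, f]))
  colnames(logx) <- feats
  fit <- fit_hmm_unsupervised(logx, 2, seed = 0, max_iter = 60, tol = 1e-6,
                              sigma_floor = 1e-3)
  # monotone likelihood (EM guarantee, small numerical slack)
  expect_true(all(diff(attr(fit, "loglik_trace")) > -1e-6))
  # identify states by mu ordering
  ord <- order(fit$emissions$mu[, 1])
  expect_equal(fit$emissions$mu[ord, ], em$mu, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(fit$transitions[ord, ord], truth$transitions, tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("baum_welch with max_iter = 0 returns the model unchanged", {
  inst <- random_hmm_instance(2, 30, seed = 4)
  out <- baum_welch(inst$model, inst$logx, max_iter = 0)
  expect_equal(out$transitions, inst$model$transitions)
  expect_identical(out$emissions$mu, inst$model$emissions$mu)
})

test_that("masked transitions stay exactly zero through Baum-Welch", {
  inst <- random_hmm_instance(3, 200, seed = 31)
  m <- inst$model
  m$mask[2, 1] <- FALSE
  m$transitions[2, ] <- c(0, 0.6, 0.4)
  out <- baum_welch(m, inst$logx, max_iter = 5)
  expect_identical(out$transitions[2, 1], 0)
  expect_true(all(abs(rowSums(out$transitions) - 1) < 1e-9))
})

test_that("Viterbi training freezes emissions and honours end constraints", {
  # module with well-separated emissions; observations from deterministic paths
  feats <- c("atac", "h3k27ac")
  mu <- rbind(c(1, 3), c(1, 3), c(4, 3), c(4, 3), c(1, 3), c(1, 3))
  em <- emission_model(paste0("s", 1:6), feats, mu, matrix(0.3, 6, 2))
  mask <- matrix(FALSE, 6, 6)
  mask[1:2, 1:4] <- TRUE; mask[3:4, 3:6] <- TRUE; mask[5:6, 5:6] <- TRUE
  trans <- crehmm:::renormalize_rows(matrix(1, 6, 6), mask)
  roles <- c("N1", "N1", "A", "A", "N2", "N2")
  m <- constricted_hmm(roles, c(0.5, 0.5, 0, 0, 0, 0), trans, mask, em)
  # hand-built state paths: N1 x2, A x3, N2 x2 (states 1, 3, 5 only)
  path <- c(1, 1, 3, 3, 3, 5, 5)
  obs <- lapply(1:6, function(i) {
    logx <- mu[path, ] + 0.01 * (i %% 3) # tiny deterministic perturbation
    colnames(logx) <- feats
    logx
  })
  out <- viterbi_train(m, obs, start_roles = "N1", end_roles = "N2",
                       max_iter = 20, eps = 1e-9)
  expect_identical(out$emissions$mu, em$mu)       # bitwise frozen
  expect_identical(out$emissions$sigma, em$sigma)
  # re-estimated transitions equal empirical path frequencies:
  # from state 1: 1->1 once, 1->3 once per sequence
  expect_equal(out$transitions[1, 1], 0.5, tolerance = 1e-6)
  expect_equal(out$transitions[1, 3], 0.5, tolerance = 1e-6)
  # from state 3: 3->3 twice, 3->5 once
  expect_equal(out$transitions[3, 3], 2 / 3, tolerance = 1e-6)
  expect_equal(out$transitions[3, 5], 1 / 3, tolerance = 1e-6)
  expect_true(attr(out, "converged"))
  expect_lte(attr(out, "iterations"), 10)
  # every decoded training path ends in an N2-role state
  v <- viterbi(out, obs, start_roles = "N1", end_roles = "N2")
  lasts <- vapply(v$paths, function(p) p[length(p)], integer(1))
  expect_true(all(roles[lasts] == "N2"))
  firsts <- vapply(v$paths, function(p) p[1], integer(1))
  expect_true(all(roles[firsts] == "N1"))
})

test_that("an inadmissible constrained sequence raises an informative error", {
  em <- emission_model(c("s1", "s2"), "f", matrix(c(1, 2), 2, 1),
                       matrix(0.5, 2, 1))
  mask <- rbind(c(TRUE, FALSE), c(FALSE, TRUE)) # disconnected
  m <- constricted_hmm(c("N1", "N2"), c(1, 0), diag(2), mask, em)
  logx <- matrix(1.5, 4, 1, dimnames = list(NULL, "f"))
  expect_error(viterbi(m, logx, start_roles = "N2", end_roles = "N1"),
               "no admissible")
})
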