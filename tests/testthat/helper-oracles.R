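# Brute-force HMM oracle: exhaustive enumeration over all k^n state paths.
# Independent of the package's forward-backward/Viterbi implementation.
brute_force_hmm <- function(init, trans, logemit) {
  n <- nrow(logemit); k <- length(init)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  logp <- apply(paths, 1, function(p) {
    lp <- log(init[p[1]]) + logemit[1, p[1]]
    if (n > 1) for (t in 2:n) lp <- lp + log(trans[p[t - 1], p[t]]) + logemit[t, p[t]]
    lp
  })
  mx <- max(logp[is.finite(logp)])
  w <- exp(logp - mx)
  gamma <- matrix(0, n, k)
  for (t in seq_len(n)) for (j in seq_len(k)) gamma[t, j] <- sum(w[paths[, t] == j])
  gamma <- gamma / sum(w)
  best <- which.max(logp)
  list(gamma = gamma, loglik = mx + log(sum(w)),
       best_logp = max(logp), best_path = unname(paths[best, ]))
}

# random unconstrained model + observations for the oracle suite
random_hmm_instance <- function(k, n, n_features = 2, seed) {
  set.seed(seed)
  trans <- matrix(rexp(k * k), k)
  trans <- trans / rowSums(trans)
  init <- rexp(k); init <- init / sum(init)
  mu <- matrix(rnorm(k * n_features, 1, 1), k)
  sigma <- matrix(runif(k * n_features, 0.3, 1), k)
  em <- emission_model(paste0("S", 1:k), paste0("f", 1:n_features), mu, sigma)
  model <- constricted_hmm(roles = rep("FG5", k), initial = init,
                           transitions = trans, emissions = em)
  logx <- matrix(rnorm(n * n_features, 1, 0.8), n)
  colnames(logx) <- paste0("f", 1:n_features)
  list(model = model, logx = logx,
       logemit = crehmm:::emission_loglik_matrix(em, logx))
}

# small fast truth world shared by several tests
small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- default_truth_model("easy")
      cache <<- simulate_truth(m, n_bins = c(30000, 30000), seed = 7)
    }
    cache
  }
})

# tiny SAM -> BAM fixture for read binning
write_test_bam <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:100000",
           "@SQ\tSN:chr2\tLN:50000")
  writeLines(c(hdr, records), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}

sam_record <- function(qname, flag, rname, pos, width = 50) {
  paste(qname, flag, rname, pos, 60, paste0(width, "M"), "*", 0, 0,
        strrep("A", width), strrep("I", width), sep = "\t")
}
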