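feats <- c("atac", "h3k27ac", "h3k4me1", "h3k4me3")

# 5-state model with hand-set emission means: states 1,2 accessible
# (atac/h3k27ac ratio 10, 8), states 3,4,5 nucleosomal with me1/me3 ratios
# 5, 4, 0.1
hand_model5 <- function() {
  mu <- log(rbind(
    c(100, 10, 1, 1),   # ratio A = 10, ratio N = 1
    c(80, 10, 1, 1),    # ratio A = 8
    c(10, 10, 5, 1),    # ratio A = 1, ratio N = 5
    c(10, 10, 4, 1),    # ratio N = 4
    c(10, 10, 1, 10)))  # ratio N = 0.1
  em <- emission_model(paste0("S", 1:5), feats, mu, matrix(1e-3, 5, 4))
  constricted_hmm(rep("FG5", 5), rep(0.2, 5), matrix(0.2, 5, 5),
                  emissions = em)
}

test_that("state selection ranks by emission-mean ratios", {
  m5 <- hand_model5()
  sel_e <- select_states(m5, "enhancer")
  expect_setequal(sel_e$a_states, c(1, 2))
  expect_equal(sel_e$n_states, c(3, 4))
  expect_equal(sel_e$discarded, 5)
  sel_p <- select_states(m5, "promoter")
  expect_setequal(sel_p$a_states, c(1, 2))
  expect_equal(sel_p$n_states, c(5, 4))
  expect_equal(sel_p$discarded, 3)
})

test_that("state selection is invariant to a global scale on emission means", {
  m5 <- hand_model5()
  m5b <- m5
  m5b$emissions$mu <- m5$emissions$mu + log(37) # multiply all means by 37
  expect_identical(select_states(m5, "enhancer"), select_states(m5b, "enhancer"))
  expect_identical(select_states(m5, "promoter"), select_states(m5b, "promoter"))
})

test_that("foreground module forbids transitions against the directed order", {
  m5 <- hand_model5()
  mod <- build_foreground_module(m5, select_states(m5, "enhancer"), "enhancer")
  expect_equal(mod$roles, c("E_N1", "E_N1", "E_A", "E_A", "E_N2", "E_N2"))
  N1 <- 1:2; A <- 3:4; N2 <- 5:6
  expect_false(any(mod$mask[A, N1]))   # A cannot go back to N1
  expect_false(any(mod$mask[N2, A]))   # N2 cannot go back to A
  expect_false(any(mod$mask[N1, N2]))  # A cannot be skipped
  expect_true(all(mod$mask[N1, A]))
  expect_true(all(mod$mask[A, N2]))
  # N2 emissions are exact copies of N1's
  expect_identical(mod$emissions$mu[N2, ], mod$emissions$mu[N1, ],
                   ignore_attr = TRUE)
  expect_identical(mod$emissions$sigma[N2, ], mod$emissions$sigma[N1, ],
                   ignore_attr = TRUE)
  expect_equal(rowSums(mod$transitions), rep(1, 6), tolerance = 1e-12)
  expect_equal(mod$initial, c(0.5, 0.5, 0, 0, 0, 0))
})

test_that("refinement never touches emissions and ends paths at N2", {
  truth <- small_truth()
  tr <- truth_training_regions(truth, n_enhancers = 40, n_promoters = 0,
                               n_background = 10, seed = 1)
  obs <- region_observations(truth$tracks, tr$enhancers)
  m5 <- fit_foreground_5state(obs, seed = 0, max_iter = 30)
  mod <- build_foreground_module(m5, select_states(m5, "enhancer"), "enhancer")
  ref <- refine_foreground(mod, obs)
  expect_identical(ref$emissions$mu, mod$emissions$mu)
  expect_identical(ref$emissions$sigma, mod$emissions$sigma)
  v <- viterbi(ref, obs, start_roles = "E_N1", end_roles = "E_N2")
  roles_at <- function(sel) ref$roles[vapply(v$paths, sel, integer(1))]
  expect_true(all(roles_at(function(p) p[length(p)]) == "E_N2"))
  expect_true(all(roles_at(function(p) p[1]) == "E_N1"))
})

test_that("entry rates follow the genome composition arithmetic", {
  r <- entry_rates(composition_config())
  expect_equal(round(100 * r$enhancer, 2), 1.33)
  expect_equal(round(100 * r$promoter, 2), 0.23)
  expect_equal(r$enhancer, 399124 / 3e7)
  expect_equal(entry_rates(composition_config(n_enhancers_genome = 0))$enhancer, 0)
  expect_error(entry_rates(composition_config(n_enhancers_genome = 4e7)))
})

test_that("composition yields a stochastic 22-state model with the stated entry masses", {
  m5 <- hand_model5()
  e_mod <- build_foreground_module(m5, select_states(m5, "enhancer"), "enhancer")
  p_mod <- build_foreground_module(m5, select_states(m5, "promoter"), "promoter")
  set.seed(8)
  bg_trans <- matrix(rexp(100), 10); bg_trans <- bg_trans / rowSums(bg_trans)
  bg <- constricted_hmm(rep("BG", 10), rep(0.1, 10), bg_trans,
                        emissions = emission_model(
                          paste0("B", 1:10), feats,
                          matrix(runif(40), 10), matrix(0.5, 10, 4)))
  full <- compose(bg, e_mod, p_mod)
  expect_equal(full$n_states, 22)
  expect_equal(rowSums(full$transitions), rep(1, 22), tolerance = 1e-9)
  e_n1 <- which(full$roles == "E_N1"); p_n1 <- which(full$roles == "P_N1")
  bg_idx <- which(full$roles == "BG")
  expect_equal(unname(rowSums(full$transitions[bg_idx, e_n1])),
               rep(399124 / 3e7, 10))
  expect_equal(unname(rowSums(full$transitions[bg_idx, p_n1])),
               rep(70292 / 3e7, 10))
  # no mass between the enhancer and promoter modules
  e_idx <- which(startsWith(full$roles, "E_"))
  p_idx <- which(startsWith(full$roles, "P_"))
  expect_true(all(full$transitions[e_idx, p_idx] == 0))
  expect_true(all(full$transitions[p_idx, e_idx] == 0))
  expect_false(any(full$mask[e_idx, p_idx]) || any(full$mask[p_idx, e_idx]))
  # composition never alters sub-model emissions
  expect_identical(full$emissions$mu[bg_idx, ], bg$emissions$mu,
                   ignore_attr = TRUE)
  expect_identical(full$emissions$mu[e_idx, ], e_mod$emissions$mu,
                   ignore_attr = TRUE)
  # N2 exit mass equals the matching N1 state's N1 -> A mass
  e_n2 <- which(full$roles == "E_N2")
  a_local <- 3:4
  for (i in 1:2) {
    expect_equal(sum(full$transitions[e_n2[i], bg_idx]),
                 sum(e_mod$transitions[i, a_local]), tolerance = 1e-12)
  }
})

test_that("model files round-trip byte-identically and validate on load", {
  truth <- small_truth()
  m <- truth$model
  m$ref_quantiles <- list(atac = c(0, 1, 5, 20), h3k27ac = c(0, 2, 4, 8),
                          h3k4me1 = c(0, 1, 2, 3), h3k4me3 = c(0, 0, 1, 2))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "m1.json"); p2 <- file.path(dir, "m2.json")
  save_model(m, p1)
  m2 <- load_model(p1)
  expect_identical(m2$transitions, m$transitions)
  expect_identical(m2$emissions$mu, m$emissions$mu)
  expect_identical(m2$mask, m$mask)
  expect_identical(m2$roles, m$roles)
  expect_identical(m2$ref_quantiles, m$ref_quantiles)
  save_model(m2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # corrupt files are rejected
  writeLines('{"format":"something-else"}', p2)
  expect_error(load_model(p2), "not a crehmm model")
  bad <- jsonlite::fromJSON(p1)
  bad$features <- NULL
  jsonlite::write_json(bad, p2, auto_unbox = TRUE)
  expect_error(load_model(p2))
})

test_that("5-state foreground fit recovers planted structure", {
  truth <- small_truth()
  tr <- truth_training_regions(truth, n_enhancers = 60, n_promoters = 0,
                               n_background = 10, seed = 2)
  obs <- region_observations(truth$tracks, tr$enhancers)
  m5 <- fit_foreground_5state(obs, seed = 0, max_iter = 40)
  expect_equal(m5$n_states, 5)
  sel <- select_states(m5, "enhancer")
  # the selected A states are the accessible ones: atac mu near the truth A
  # means (4.4 / 3.8), far above the nucleosome level (~1.2)
  atac_mu <- m5$emissions$mu[sel$a_states, "atac"]
  expect_true(all(atac_mu > 3))
  expect_true(all(m5$emissions$mu[sel$n_states, "atac"] < 2.5))
})
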