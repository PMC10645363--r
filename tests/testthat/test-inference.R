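test_that("parameter counting follows the declared convention", {
  expect_equal(count_parameters(1, 3, 4, modalities = 2, mode = "multiome"),
               0 + 1 * 3 * 3 + 6 + 6)
  expect_equal(count_parameters(2, 1, 2, modalities = 1, mode = "flat"),
               1 + 2 + 1 + 1)
  for (K in 2:5) {
    expect_equal(count_parameters(K, 4, 4, 2, "flat") -
                   count_parameters(K, 4, 4, 2, "flat_shared_pi"), K - 1)
  }
})

test_that("information criteria match their formulas", {
  hard <- diag(2)[c(1, 2, 1, 2), ]  # one-hot responsibilities
  s <- compute_scores(loglik = -50, v = 2, n = 100, hard)
  expect_equal(s$BIC, 2 * log(100) + 100)
  expect_equal(s$AIC, 104)
  expect_equal(s$entropy, 0)
  expect_equal(s$ICL, s$BIC)
  # uniform responsibilities: maximal entropy n log 2
  unif <- matrix(0.5, 10, 2)
  s2 <- compute_scores(-50, 2, 10, unif)
  expect_equal(s2$entropy, 10 * log(2))
  expect_equal(s2$ICL, s2$BIC + 10 * log(2))
  expect_gte(s2$ICL, s2$BIC)
  expect_error(compute_scores(-50, 2, 10, matrix(0.4, 2, 2)), "sum to 1")
})

test_that("MAP copy numbers take the argmax with low tie-break", {
  Phi <- array(0, c(1, 3, 3))
  Phi[1, 1, ] <- c(0.1, 0.8, 0.1)
  Phi[1, 2, ] <- c(0.5, 0.5, 0)
  Phi[1, 3, ] <- c(0, 0, 1)
  expect_equal(as.integer(map_copy_numbers(Phi)), c(2L, 1L, 3L))
})

test_that("K = 1 fits degenerate cleanly and match the exact likelihood", {
  set.seed(15)
  sim <- strong_two_clone(seed = 15, n = 40, I = 4)
  prior <- default_prior(rep(2, 4), H = 4,
                         segment_ids = sim$rna$segment_ids)
  cfg <- fit_config(lam = 0.5, steps = 120, restarts = 1, seed = 15,
                    mode = "flat")
  f <- fit(sim$rna, sim$atac, prior, K = 1, config = cfg)
  expect_true(all(f$responsibilities$rna == 1))
  expect_true(all(f$responsibilities$atac == 1))
  expect_equal(f$loglik, joint_loglik(sim$rna, sim$atac, f$params),
               tolerance = 1e-8)
  expect_equal(dim(f$map_cn), c(1, 4))
})

test_that("a strong two-clone signal is recovered exactly", {
  sim <- strong_two_clone(seed = 16, n = 200, I = 6)
  prior <- default_prior(rep(2, 6), H = 4, segment_ids = sim$rna$segment_ids)
  cfg <- fit_config(lam = 0.5, steps = 300, restarts = 2, seed = 16,
                    mode = "flat")
  f <- fit(sim$rna, sim$atac, prior, K = 2, config = cfg)
  labels <- c(sim$labels_rna, sim$labels_atac)
  inferred <- c(f$assignments$rna, f$assignments$atac)
  expect_equal(adjusted_rand_index(labels, inferred), 1)
  ev <- evaluate_fit(f, sim)
  expect_equal(ev$mae, 0)
})

test_that("identical seeds give identical traces and assignments", {
  sim <- strong_two_clone(seed = 17, n = 60, I = 4)
  prior <- default_prior(rep(2, 4), H = 4, segment_ids = sim$rna$segment_ids)
  cfg <- fit_config(lam = 0.5, steps = 150, restarts = 2, seed = 99,
                    mode = "flat")
  f1 <- fit(sim$rna, sim$atac, prior, K = 2, config = cfg)
  f2 <- fit(sim$rna, sim$atac, prior, K = 2, config = cfg)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$params$Phi, f2$params$Phi)
})

test_that("responsibilities equal the exact Bayes rule at the MAP", {
  sim <- strong_two_clone(seed = 18, n = 50, I = 4)
  prior <- default_prior(rep(2, 4), H = 4, segment_ids = sim$rna$segment_ids)
  cfg <- fit_config(lam = 0.5, steps = 150, restarts = 1, seed = 18,
                    mode = "flat")
  f <- fit(sim$rna, sim$atac, prior, K = 2, config = cfg)
  # oracle: direct Bayes rule with the brute-force likelihood pieces
  p <- f$params
  W <- f$responsibilities$rna
  for (n in sample(nrow(W), 5)) {
    lp <- vapply(1:2, function(k) {
      log(p$pi_rna[k]) + sum(vapply(1:4, function(i) {
        cexp <- sum(p$Phi[k, i, ] * seq_len(p$H))
        oracle_nb_logpmf(sim$rna$counts[n, i],
                         sim$rna$library_factors[n] * p$theta_rna[i] * cexp,
                         p$size_rna[i])
      }, numeric(1)))
    }, numeric(1))
    expect_equal(unname(W[n, ]), exp(lp - max(lp)) / sum(exp(lp - max(lp))),
                 tolerance = 1e-6)
  }
  # rows sum to one
  expect_equal(unname(rowSums(W)), rep(1, nrow(W)), tolerance = 1e-12)
  # scoring fresh data reuses the same rule
  W2 <- responsibilities(f, sim$rna)
  expect_equal(W2, W, tolerance = 1e-8)
})

test_that("cluster label permutations leave likelihood and scores unchanged", {
  sim <- strong_two_clone(seed = 19, n = 40, I = 4)
  prior <- default_prior(rep(2, 4), H = 4, segment_ids = sim$rna$segment_ids)
  cfg <- fit_config(lam = 0.5, steps = 120, restarts = 1, seed = 19,
                    mode = "flat")
  f <- fit(sim$rna, sim$atac, prior, K = 2, config = cfg)
  p <- f$params
  perm <- c(2, 1)
  p_perm <- model_params(p$Phi[perm, , , drop = FALSE],
                         pi_rna = p$pi_rna[perm], pi_atac = p$pi_atac[perm],
                         theta_rna = p$theta_rna, theta_atac = p$theta_atac,
                         size_rna = p$size_rna, size_atac = p$size_atac,
                         lam = p$lam)
  expect_equal(joint_loglik(sim$rna, sim$atac, p_perm),
               joint_loglik(sim$rna, sim$atac, p), tolerance = 1e-10)
})

test_that("restart bookkeeping returns the best objective", {
  sim <- strong_two_clone(seed = 20, n = 50, I = 4)
  prior <- default_prior(rep(2, 4), H = 4, segment_ids = sim$rna$segment_ids)
  cfg <- fit_config(lam = 0.5, steps = 120, restarts = 3, seed = 20,
                    mode = "flat")
  f <- fit(sim$rna, sim$atac, prior, K = 2, config = cfg)
  expect_equal(length(f$restart_objectives), 3)
  # ICL >= BIC on every fitted model
  expect_gte(f$scores$ICL, f$scores$BIC)
})

test_that("fit validates inputs and modality/lambda consistency", {
  sim <- strong_two_clone(seed = 22, n = 20, I = 4)
  prior <- default_prior(rep(2, 4), H = 4, segment_ids = sim$rna$segment_ids)
  cfg <- fit_config(lam = 0.5, steps = 50, restarts = 1, seed = 1)
  expect_error(fit(NULL, NULL, prior, 2, cfg), "at least one modality")
  expect_error(fit(sim$rna, NULL, prior, 2, cfg), "lam")
  expect_error(fit(sim$rna, sim$atac, prior, K = 5000, cfg), "number of cells")
  cfg_m <- fit_config(lam = 0.5, steps = 50, restarts = 1, seed = 1,
                      mode = "multiome")
  expect_error(fit(sim$rna, sim$atac, prior, 2, cfg_m), "pair_multiome")
  cfg_s <- fit_config(lam = 1, steps = 50, restarts = 1, seed = 1,
                      mode = "flat_shared_pi")
  expect_error(fit(sim$rna, NULL, prior, 2, cfg_s), "both modalities")
  # RNA-only at the lambda boundary works
  cfg1 <- fit_config(lam = 1, steps = 80, restarts = 1, seed = 1)
  f <- fit(sim$rna, NULL, prior, 2, cfg1)
  expect_null(f$params$theta_atac)
})

test_that("model selection scans K and returns the score table", {
  sim <- strong_two_clone(seed = 24, n = 150, I = 5)
  prior <- default_prior(rep(2, 5), H = 4, segment_ids = sim$rna$segment_ids)
  cfg <- fit_config(K_range = 1:4, lam = 0.5, steps = 250, restarts = 1,
                    seed = 24, mode = "flat")
  sel <- select_model(sim$rna, sim$atac, prior, cfg)
  expect_equal(nrow(sel$table), 4)
  expect_equal(sel$table$K, 1:4)
  expect_equal(sel$best_K, 2)
  expect_equal(sel$best_K, sel$table$K[which.min(sel$table$BIC)])
  # single-K range returns that fit
  cfg2 <- fit_config(K_range = 2, lam = 0.5, steps = 100, restarts = 1,
                     seed = 24, mode = "flat")
  sel2 <- select_model(sim$rna, sim$atac, prior, cfg2)
  expect_equal(nrow(sel2$table), 1)
  expect_equal(sel2$best_K, 2)
})
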