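# Shared fixtures and independent oracles, built in code at test time.

# Brute-force NB log pmf from the lgamma formula (independent of dnbinom).
oracle_nb_logpmf <- function(x, mu, size) {
  lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
    size * log(size / (size + mu)) + x * log(mu / (size + mu))
}

# Brute-force mixture log-likelihood: explicit triple loop over cells,
# clusters and segments, probabilities accumulated on the natural scale.
oracle_modality_loglik <- function(counts, rho, pi, Phi, theta, size) {
  N <- nrow(counts); I <- ncol(counts); K <- dim(Phi)[1]; H <- dim(Phi)[3]
  total <- 0
  for (n in seq_len(N)) {
    cell_lik <- 0
    for (k in seq_len(K)) {
      comp <- pi[k]
      for (i in seq_len(I)) {
        cexp <- sum(Phi[k, i, ] * seq_len(H))
        mu <- rho[n] * theta[i] * cexp
        comp <- comp * exp(oracle_nb_logpmf(counts[n, i], mu, size[i]))
      }
      cell_lik <- cell_lik + comp
    }
    total <- total + log(cell_lik)
  }
  total
}

# Brute-force ARI by enumerating all item pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- n * (n - 1) / 2
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Random small model instance for oracle comparisons.
random_instance <- function(N, I, K, H) {
  counts <- matrix(rpois(N * I, lambda = 20), N, I)
  counts[1, 1] <- 0  # keep a zero count in play
  rho <- exp(rnorm(N, 0, 0.2)); rho <- rho / mean(rho)
  pi <- rgamma(K, 1); pi <- pi / sum(pi)
  Phi <- array(rgamma(K * I * H, 1), c(K, I, H))
  for (k in 1:K) for (i in 1:I) Phi[k, i, ] <- Phi[k, i, ] / sum(Phi[k, i, ])
  theta <- runif(I, 5, 15)
  size <- runif(I, 5, 50)
  list(counts = counts, rho = rho, pi = pi, Phi = Phi, theta = theta,
       size = size)
}

make_sc <- function(counts, modality = "RNA", rho = NULL,
                    prefix = tolower(modality)) {
  segmented_counts(counts,
                   barcodes = sprintf("%s%03d", prefix, seq_len(nrow(counts))),
                   segment_ids = paste0("seg", seq_len(ncol(counts))),
                   modality = modality, library_factors = rho)
}

params_from_instance <- function(inst, modality = "RNA", lam = 0.5) {
  if (modality == "RNA")
    model_params(inst$Phi, pi_rna = inst$pi, theta_rna = inst$theta,
                 size_rna = inst$size, lam = lam)
  else
    model_params(inst$Phi, pi_atac = inst$pi, theta_atac = inst$theta,
                 size_atac = inst$size, lam = lam)
}

# All permutations of 1..n as a list (for exhaustive assignment search).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

# Small deterministic two-clone dataset with strong CNAs: the clones carry
# 1 vs 3 copies at segment 3 and 3 vs 1 at segment 5 (3x mean contrasts in
# opposite directions, so total library size carries no clone signal).
strong_two_clone <- function(seed = 42, n = 120, I = 6, paired = FALSE) {
  set.seed(seed)
  tree <- sample_clone_tree(2, I, max_new_segments = 2, H = 4)
  tree$cn_matrix[1, ] <- rep(2L, I)
  tree$cn_matrix[2, ] <- rep(2L, I)
  tree$cn_matrix[1, 3] <- 1L
  tree$cn_matrix[2, 3] <- 3L
  j2 <- if (I >= 5) 5L else I  # second, opposite event (I >= 4)
  tree$cn_matrix[1, j2] <- 3L
  tree$cn_matrix[2, j2] <- 1L
  truth <- simulation_truth(tree, c(0.5, 0.5))
  simulate_counts(truth, n, n,
                  theta_rna = rep(120, I), theta_atac = rep(90, I),
                  size_rna = rep(30, I), size_atac = rep(60, I),
                  library_sd = 0.15, paired = paired)
}
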