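#' Sample a clonal tree with copy-number events
#'
#' Builds a random clone tree of K clones over I segments. The root clone is
#' diploid everywhere (copy number 2); each subsequent clone attaches to a
#' uniformly chosen existing clone and draws 1..`max_new_segments` segments
#' that are still unaltered along its path to the root, assigning each a new
#' copy number different from the parent's, uniform over `{1..H} \ {parent}`.
#' Copy-number profiles propagate down the tree.
#'
#' @param K Number of clones (>= 2).
#' @param I Number of segments.
#' @param max_new_segments Maximum new CNA segments per clone (default 3).
#' @param H Maximum copy number (default 4).
#' @param seed Optional integer seed.
#' @return A list of class `clone_tree` with `parent` (integer vector, 0 for
#'   the root), `events` (list per clone of named copy-number changes) and
#'   `cn_matrix` (K x I integer matrix of clone profiles).
#' @export
sample_clone_tree <- function(K, I, max_new_segments = 3, H = 4,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(K >= 2, I >= 1, max_new_segments >= 1, H >= 2)
  cn <- matrix(2L, K, I)
  parent <- integer(K)
  events <- vector("list", K)
  events[[1]] <- integer(0)
  altered_on_path <- vector("list", K)  # segments altered on root path
  altered_on_path[[1]] <- integer(0)
  for (k in 2:K) {
    p <- if (k == 2) 1L else sample.int(k - 1, 1)
    parent[k] <- p
    cn[k, ] <- cn[p, ]
    avail <- setdiff(seq_len(I), altered_on_path[[p]])
    if (length(avail) == 0)
      stop("not enough unaltered segments to add events for clone ", k)
    n_ev <- sample.int(min(max_new_segments, length(avail)), 1)
    segs <- if (length(avail) == 1) avail else sample(avail, n_ev)
    ev <- integer(0)
    for (s in segs) {
      choices <- setdiff(seq_len(H), cn[p, s])
      new_cn <- if (length(choices) == 1) choices else sample(choices, 1)
      cn[k, s] <- as.integer(new_cn)
      ev[as.character(s)] <- as.integer(new_cn)
    }
    events[[k]] <- ev
    altered_on_path[[k]] <- union(altered_on_path[[p]], segs)
  }
  rownames(cn) <- paste0("clone", seq_len(K))
  colnames(cn) <- paste0("seg", seq_len(I))
  structure(list(parent = parent, events = events, cn_matrix = cn,
                 K = K, I = I, H = H),
            class = "clone_tree")
}

#' Sample mixing proportions from a uniform Dirichlet
#'
#' @param K Number of clones.
#' @param seed Optional integer seed.
#' @return A length-K probability vector drawn from Dirichlet(1, ..., 1).
#' @export
sample_mixing_proportions <- function(K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(K >= 1)
  g <- stats::rgamma(K, shape = 1)
  g / sum(g)
}

#' Simulation ground truth container
#'
#' @param tree A [sample_clone_tree()] result.
#' @param proportions Clone mixing proportions (simplex over K clones).
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(tree, proportions) {
  stopifnot(inherits(tree, "clone_tree"),
            length(proportions) == nrow(tree$cn_matrix),
            abs(sum(proportions) - 1) < 1e-8)
  structure(list(tree = tree, cn_matrix = tree$cn_matrix,
                 proportions = as.numeric(proportions)),
            class = "simulation_truth")
}

#' Simulate clone-structured RNA and ATAC segment counts
#'
#' Draws per-cell clone labels from the truth's mixing proportions (in paired
#' mode one draw per physical cell serves both modalities), log-normal
#' library factors (mean-normalised to 1), and Negative Binomial counts with
#' mean `rho_n * theta_i * c[k(n), i]` — linear in the clone's copy number —
#' and per-segment size (inverse overdispersion) parameters.
#'
#' @param truth A [simulation_truth()].
#' @param n_rna,n_atac Number of cells per modality (equal in paired mode).
#' @param theta_rna,theta_atac Positive per-segment rates (expected counts per
#'   copy for an average cell).
#' @param size_rna,size_atac Positive per-segment NB size parameters.
#' @param library_sd Standard deviation of log library factors (default 0.2).
#' @param paired If `TRUE`, both modalities measure the same cells: identical
#'   barcodes and clone labels.
#' @param seed Optional integer seed.
#' @return List with `rna`, `atac` ([segmented_counts()]), `labels_rna`,
#'   `labels_atac` (integer clone ids) and `truth`.
#' @export
simulate_counts <- function(truth, n_rna, n_atac,
                            theta_rna, theta_atac,
                            size_rna, size_atac,
                            library_sd = 0.2, paired = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "simulation_truth"))
  cn <- truth$cn_matrix
  K <- nrow(cn); I <- ncol(cn)
  stopifnot(length(theta_rna) == I, length(theta_atac) == I,
            all(theta_rna > 0), all(theta_atac > 0),
            all(size_rna > 0), all(size_atac > 0))
  if (paired && n_rna != n_atac)
    stop("paired mode requires n_rna == n_atac")
  if (min(n_rna, n_atac) < K)
    warning("fewer cells than clones; some clones may be empty")
  draw_labels <- function(n)
    sample.int(K, n, replace = TRUE, prob = truth$proportions)
  labels_rna <- draw_labels(n_rna)
  labels_atac <- if (paired) labels_rna else draw_labels(n_atac)
  sim_mod <- function(labels, theta, size, prefix, modality) {
    n <- length(labels)
    rho <- exp(stats::rnorm(n, 0, library_sd))
    rho <- rho / mean(rho)
    mu <- rho * t(theta * t(cn[labels, , drop = FALSE]))
    x <- matrix(stats::rnbinom(n * I, mu = mu, size = rep(size, each = n)),
                n, I)
    segmented_counts(x, sprintf("%s_cell%04d", prefix, seq_len(n)),
                     colnames(cn), modality = modality,
                     library_factors = NULL)
  }
  rna <- sim_mod(labels_rna, theta_rna, size_rna,
                 if (paired) "cell" else "rna", "RNA")
  atac <- sim_mod(labels_atac, theta_atac, size_atac,
                  if (paired) "cell" else "atac", "ATAC")
  list(rna = rna, atac = atac, labels_rna = labels_rna,
       labels_atac = labels_atac, truth = truth)
}

#' Simulate a complete two-modality dataset with defaults
#'
#' Convenience wrapper: samples a clone tree, uniform-Dirichlet mixing
#' proportions, per-segment rates log-normal around the given means, and NB
#' counts for both modalities. Defaults emulate chromosome-arm-scale segments
#' at typical 10x sequencing depth (about 5000 UMI and 4000 in-peak fragments
#' per diploid cell over 20 segments): RNA rate 125 and ATAC rate 100 counts
#' per copy per average cell, NB sizes 25 (RNA, more dispersed) and 50 (ATAC;
#' aggregating hundreds of features per segment averages out feature-level
#' overdispersion), library factor log-sd 0.2, maximum copy number 4.
#'
#' @param K Number of clones.
#' @param I Number of segments (default 20).
#' @param n_rna,n_atac Cells per modality.
#' @param H Maximum copy number (default 4).
#' @param max_new_segments Maximum CNA events per clone (default 3).
#' @param theta_rna_mean,theta_atac_mean Mean per-copy segment rates.
#' @param theta_sdlog Log-sd of the per-segment rate draw (default 0.25).
#' @param size_rna,size_atac NB size parameters (scalar or per segment).
#' @param library_sd Log-sd of library factors.
#' @param paired Paired (multiome-like) cells.
#' @param seed Integer seed.
#' @return As [simulate_counts()], plus `theta` and `size` per modality.
#' @export
simulate_dataset <- function(K, I = 20, n_rna = 300, n_atac = 300, H = 4,
                             max_new_segments = 3,
                             theta_rna_mean = 125, theta_atac_mean = 100,
                             theta_sdlog = 0.25,
                             size_rna = 25, size_atac = 50,
                             library_sd = 0.2, paired = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- sample_clone_tree(K, I, max_new_segments, H)
  props <- sample_mixing_proportions(K)
  truth <- simulation_truth(tree, props)
  theta_rna <- stats::rlnorm(I, log(theta_rna_mean), theta_sdlog)
  theta_atac <- stats::rlnorm(I, log(theta_atac_mean), theta_sdlog)
  size_rna <- rep_len(size_rna, I)
  size_atac <- rep_len(size_atac, I)
  out <- simulate_counts(truth, n_rna, n_atac, theta_rna, theta_atac,
                         size_rna, size_atac, library_sd, paired)
  out$theta <- list(rna = theta_rna, atac = theta_atac)
  out$size <- list(rna = size_rna, atac = size_atac)
  out
}

#' End-to-end simulation benchmark
#'
#' For each requested clone number K and replicate: simulate a two-modality
#' dataset, fit with [select_model()] (flat model, shrinkage `lam`, score as
#' configured) and evaluate cluster recovery (ARI against the true clone
#' labels of all cells, both modalities concatenated) and copy-number
#' recovery (MAE over optimally matched clone/segment pairs).
#'
#' @param K_values Integer vector of clone numbers to simulate.
#' @param replicates Replicates per K.
#' @param n_rna,n_atac Cells per modality per dataset.
#' @param I Segments per dataset.
#' @param K_max Largest K scored during model selection.
#' @param lam Shrinkage weight used for fitting (default 0.5).
#' @param score Selection score (default BIC).
#' @param steps,restarts SVI steps and restarts per fit.
#' @param seed Integer seed for the whole benchmark.
#' @param ... Further arguments passed to [simulate_dataset()].
#' @return A list with `results` (data.frame: K_true, replicate, K_inferred,
#'   ari, mae, seed) and `summary` (median ARI and MAE).
#' @export
paper_benchmark <- function(K_values = c(2, 3, 4, 6), replicates = 3,
                            n_rna = 300, n_atac = 300, I = 20, K_max = 8,
                            lam = 0.5, score = "BIC", steps = 400,
                            restarts = 2, seed = 1, ...) {
  rows <- list()
  idx <- 0
  for (K in K_values) {
    for (rep_i in seq_len(replicates)) {
      idx <- idx + 1
      ds_seed <- seed * 1000 + idx
      sim <- simulate_dataset(K, I = I, n_rna = n_rna, n_atac = n_atac,
                              seed = ds_seed, ...)
      prior <- default_prior(rep(2L, I), H = sim$truth$tree$H,
                             segment_ids = colnames(sim$truth$cn_matrix))
      cfg <- fit_config(K_range = 1:K_max, lam = lam, steps = steps,
                        restarts = restarts, score = score,
                        seed = ds_seed, mode = "flat")
      sel <- select_model(sim$rna, sim$atac, prior, cfg)
      ev <- evaluate_fit(sel$best_fit, sim)
      rows[[idx]] <- data.frame(K_true = K, replicate = rep_i,
                                K_inferred = sel$best_K, ari = ev$ari,
                                mae = ev$mae, seed = ds_seed)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(K_true = integer(0), replicate = integer(0),
               K_inferred = integer(0), ari = numeric(0), mae = numeric(0),
               seed = integer(0))
  summary <- list(median_ari = stats::median(results$ari),
                  median_mae = stats::median(results$mae),
                  n_datasets = nrow(results))
  list(results = results, summary = summary)
}

#' Write a simulated dataset to disk as plain text
#'
#' Counts go to `rna_counts.tsv` / `atac_counts.tsv` (cells x segments with a
#' barcode column, readable by [read_segment_table()]); truth to
#' `truth_labels.tsv`, `truth_cn.tsv` and `truth_proportions.tsv`.
#'
#' @param sim A [simulate_dataset()] / [simulate_counts()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts <- function(d, path) {
    df <- data.frame(barcode = d$barcodes, d$counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- c(rna = file.path(dir, "rna_counts.tsv"),
             atac = file.path(dir, "atac_counts.tsv"),
             labels = file.path(dir, "truth_labels.tsv"),
             cn = file.path(dir, "truth_cn.tsv"),
             props = file.path(dir, "truth_proportions.tsv"))
  write_counts(sim$rna, paths["rna"])
  write_counts(sim$atac, paths["atac"])
  labs <- rbind(
    data.frame(barcode = sim$rna$barcodes, modality = "RNA",
               clone = sim$labels_rna),
    data.frame(barcode = sim$atac$barcodes, modality = "ATAC",
               clone = sim$labels_atac))
  utils::write.table(labs, paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cn <- data.frame(clone = rownames(sim$truth$cn_matrix),
                   sim$truth$cn_matrix, check.names = FALSE)
  utils::write.table(cn, paths["cn"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(clone = rownames(sim$truth$cn_matrix),
               proportion = sim$truth$proportions),
    paths["props"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
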