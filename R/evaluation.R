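#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pair-counting agreement between two labelings of the same
#' items: 1 for identical partitions (up to relabeling), about 0 for
#' independent random labels.
#'
#' @param labels_a,labels_b Vectors of equal length (>= 2 items).
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 items")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Optimal one-to-one matching of inferred clusters to true clones
#'
#' Pairwise cost is the mean absolute copy-number difference between two
#' profiles; the assignment minimising the total cost is found exactly by
#' dynamic programming over subsets. Extra clusters on the larger side are
#' left unmatched and reported.
#'
#' @param true_cn True clones x segments integer matrix.
#' @param inferred_cn Inferred clusters x segments integer matrix (same
#'   segment set).
#' @return A list with `matching` (named integer vector: inferred cluster ->
#'   true clone), `unmatched_true`, `unmatched_inferred` and `cost` (total
#'   matched cost).
#' @export
match_clusters <- function(true_cn, inferred_cn) {
  true_cn <- as.matrix(true_cn)
  inferred_cn <- as.matrix(inferred_cn)
  if (ncol(true_cn) != ncol(inferred_cn))
    stop("profiles must share the segment set")
  Kt <- nrow(true_cn); Ki <- nrow(inferred_cn)
  cost <- matrix(0, Ki, Kt)
  for (a in seq_len(Ki)) for (b in seq_len(Kt))
    cost[a, b] <- mean(abs(inferred_cn[a, ] - true_cn[b, ]))
  # exact assignment: DP over subsets of the smaller side (columns of M),
  # scanning rows of the larger side in order with optional skips
  transpose <- Ki < Kt
  M <- if (transpose) t(cost) else cost       # nr >= nc
  nr <- nrow(M); nc <- ncol(M)
  n_states <- bitwShiftL(1L, nc)
  popcount <- vapply(0:(n_states - 1L), function(s)
    sum(bitwAnd(s, bitwShiftL(1L, 0:(nc - 1L))) > 0L), numeric(1))
  best <- matrix(Inf, nr + 1L, n_states)       # best[r+1, s+1]
  choice <- matrix(NA_integer_, nr + 1L, n_states)  # 0 = row skipped
  best[1, 1] <- 0
  for (r in seq_len(nr)) {
    for (s in 0:(n_states - 1L)) {
      b <- best[r, s + 1L]
      if (!is.finite(b)) next
      if (b < best[r + 1L, s + 1L]) {          # skip row r
        best[r + 1L, s + 1L] <- b
        choice[r + 1L, s + 1L] <- 0L
      }
      for (cc in seq_len(nc)) {
        bit <- bitwShiftL(1L, cc - 1L)
        if (bitwAnd(s, bit) > 0L) next
        s2 <- bitwOr(s, bit)
        val <- b + M[r, cc]
        if (val < best[r + 1L, s2 + 1L]) {
          best[r + 1L, s2 + 1L] <- val
          choice[r + 1L, s2 + 1L] <- cc
        }
      }
    }
  }
  full <- n_states - 1L                        # all of the smaller side matched
  row_to_col <- integer(nr)
  s <- full
  for (r in nr:1) {
    cc <- choice[r + 1L, s + 1L]
    row_to_col[r] <- cc
    if (cc > 0L) s <- bitwAnd(s, bitwNot(bitwShiftL(1L, cc - 1L)))
  }
  if (transpose) {
    # rows of M = true clones, cols = inferred clusters
    inferred_to_true <- rep(NA_integer_, Ki)
    for (r in seq_len(nr)) if (row_to_col[r] > 0L)
      inferred_to_true[row_to_col[r]] <- r
  } else {
    inferred_to_true <- rep(NA_integer_, Ki)
    for (r in seq_len(nr)) if (row_to_col[r] > 0L)
      inferred_to_true[r] <- row_to_col[r]
  }
  matched <- which(!is.na(inferred_to_true))
  matching <- stats::setNames(inferred_to_true[matched], matched)
  total <- sum(cost[cbind(matched, inferred_to_true[matched])])
  list(matching = matching,
       unmatched_true = setdiff(seq_len(Kt), matching),
       unmatched_inferred = setdiff(seq_len(Ki),
                                    as.integer(names(matching))),
       cost = total)
}

#' Mean absolute copy-number error over matched clones
#'
#' Mean over matched (clone, segment) pairs of the absolute difference
#' between true and inferred integer copy numbers.
#'
#' @param true_cn,inferred_cn Integer matrices (clones/clusters x segments).
#' @param matching Named vector from [match_clusters()] (inferred -> true);
#'   computed automatically when `NULL`.
#' @return Scalar MAE.
#' @export
cna_mae <- function(true_cn, inferred_cn, matching = NULL) {
  if (is.null(matching)) matching <- match_clusters(true_cn, inferred_cn)$matching
  if (length(matching) == 0) stop("empty matching")
  errs <- vapply(seq_along(matching), function(j) {
    a <- as.integer(names(matching))[j]
    b <- as.integer(matching[j])
    abs(inferred_cn[a, ] - true_cn[b, ])
  }, numeric(ncol(as.matrix(true_cn))))
  mean(errs)
}

#' Evaluate a fit against simulation ground truth
#'
#' Computes the ARI between true clone labels and hard assignments (per
#' modality in flat mode, on the shared labels in multiome mode, plus a
#' combined ARI over all cells), matches inferred clusters to true clones by
#' minimal copy-number distance, and reports the MAE and per-segment error.
#'
#' @param fit A `cna_fit`.
#' @param sim A [simulate_counts()] / [simulate_dataset()] result.
#' @return A list of class `evaluation_report`: `ari` (combined), `ari_rna`,
#'   `ari_atac`, `mae`, `matching`, `per_segment_error`,
#'   `unmatched_true`, `unmatched_inferred`.
#' @export
evaluate_fit <- function(fit, sim) {
  stopifnot(inherits(fit, "cna_fit"))
  if (fit$mode == "multiome") {
    inferred <- fit$assignments
    truth_labels <- sim$labels_rna
    ari_rna <- ari_atac <- ari <- adjusted_rand_index(truth_labels, inferred)
    combined_true <- truth_labels
    combined_inf <- inferred
  } else {
    ari_rna <- if (!is.null(fit$assignments$rna))
      adjusted_rand_index(sim$labels_rna, fit$assignments$rna) else NA_real_
    ari_atac <- if (!is.null(fit$assignments$atac))
      adjusted_rand_index(sim$labels_atac, fit$assignments$atac) else NA_real_
    combined_true <- c(if (!is.null(fit$assignments$rna)) sim$labels_rna,
                       if (!is.null(fit$assignments$atac)) sim$labels_atac)
    combined_inf <- c(fit$assignments$rna, fit$assignments$atac)
    ari <- adjusted_rand_index(combined_true, combined_inf)
  }
  m <- match_clusters(sim$truth$cn_matrix, fit$map_cn)
  mae <- cna_mae(sim$truth$cn_matrix, fit$map_cn, m$matching)
  per_seg <- colMeans(do.call(rbind, lapply(seq_along(m$matching), function(j) {
    a <- as.integer(names(m$matching))[j]
    b <- as.integer(m$matching[j])
    abs(fit$map_cn[a, ] - sim$truth$cn_matrix[b, ])
  })))
  names(per_seg) <- colnames(sim$truth$cn_matrix)
  structure(list(ari = ari, ari_rna = ari_rna, ari_atac = ari_atac,
                 mae = mae, matching = m$matching,
                 per_segment_error = per_seg,
                 unmatched_true = m$unmatched_true,
                 unmatched_inferred = m$unmatched_inferred),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> ARI %.3f (RNA %.3f, ATAC %.3f) | MAE %.3f\n",
              x$ari, x$ari_rna, x$ari_atac, x$mae))
  invisible(x)
}
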