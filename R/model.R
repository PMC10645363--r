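#' Dirichlet prior over per-segment copy-number states
#'
#' The latent copy number of segment i in clone k is a categorical variable
#' over states h = 1..H (no zero-copy state: the NB mean would degenerate).
#' Its prior is a Dirichlet with one concentration vector per segment.
#'
#' @param alpha Numeric matrix, segments x H, strictly positive concentrations.
#' @param segment_ids Optional segment identifiers (rownames used otherwise).
#' @return Object of class `cna_prior` with elements `alpha`, `H`,
#'   `segment_ids`.
#' @seealso [default_prior()]
#' @export
cna_prior <- function(alpha, segment_ids = rownames(alpha)) {
  alpha <- as.matrix(alpha)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("all Dirichlet concentrations must be strictly positive")
  if (ncol(alpha) < 2) stop("need at least 2 copy-number states")
  if (is.null(segment_ids)) segment_ids <- paste0("seg", seq_len(nrow(alpha)))
  rownames(alpha) <- segment_ids
  colnames(alpha) <- paste0("CN", seq_len(ncol(alpha)))
  structure(list(alpha = alpha, H = ncol(alpha),
                 segment_ids = as.character(segment_ids)),
            class = "cna_prior")
}

#' Default skewed Dirichlet prior from expected copy numbers
#'
#' For a segment expected to carry p copies, the concentration vector gets
#' value 0.6 at entry p and 0.1 at every other state, skewing the Dirichlet
#' towards the expected ploidy while keeping all states reachable.
#'
#' @param expected_cn Integer vector of expected copies per segment (1..H).
#' @param H Maximum copy number; default `min(max(expected_cn) + 2, 6)`.
#' @param segment_ids Optional segment identifiers.
#' @return A [cna_prior()] object.
#' @export
default_prior <- function(expected_cn, H = NULL, segment_ids = NULL) {
  expected_cn <- as.integer(expected_cn)
  if (is.null(H)) H <- min(max(expected_cn) + 2L, 6L)
  if (any(expected_cn < 1L) || any(expected_cn > H))
    stop("expected_cn must lie in 1..H (H = ", H, ")")
  alpha <- matrix(0.1, nrow = length(expected_cn), ncol = H)
  alpha[cbind(seq_along(expected_cn), expected_cn)] <- 0.6
  cna_prior(alpha, segment_ids = segment_ids)
}

#' Negative Binomial mean under a copy-number mixture
#'
#' Expected count for one cell and segment: the per-cell library factor times
#' the segment rate per copy times the expected copy number under the state
#' probabilities, `rho * theta * sum_h phi_h * h`.
#'
#' @param rho Positive library size factor of the cell.
#' @param theta Positive segment rate (expected counts per copy, average cell).
#' @param phi_vec Probability vector over copy states 1..H (must sum to 1).
#' @return Positive scalar mean.
#' @export
nb_mean <- function(rho, theta, phi_vec) {
  if (abs(sum(phi_vec) - 1) > 1e-6)
    stop("phi_vec must sum to 1")
  if (any(phi_vec < 0)) stop("phi_vec must be non-negative")
  stopifnot(rho > 0, theta > 0)
  rho * theta * sum(phi_vec * seq_along(phi_vec))
}

#' Negative Binomial log pmf (mean / size parameterisation)
#'
#' @param x Non-negative integer counts.
#' @param mu Positive mean.
#' @param size Positive size (inverse-overdispersion) parameter; variance is
#'   `mu + mu^2 / size`.
#' @return Log probability mass, vectorised over `x`.
#' @export
nb_logpmf <- function(x, mu, size) {
  if (any(x < 0)) stop("x must be non-negative")
  stopifnot(all(mu > 0), all(size > 0))
  stats::dnbinom(x, mu = mu, size = size, log = TRUE)
}

#' Fitted model parameters
#'
#' Container for the parameters of the shrinkage NB mixture: mixing
#' proportions per modality (or one shared/multiome vector), the clusters x
#' segments x states copy-number probability tensor Phi, per-segment rates and
#' NB sizes per modality, and the shrinkage weight lambda.
#'
#' @param Phi Numeric array K x I x H; each `Phi[k, i, ]` a probability vector.
#' @param pi_rna,pi_atac Mixing proportions; pass the same vector (or use
#'   `pi_rna` only) for shared/multiome modes.
#' @param theta_rna,theta_atac Positive per-segment rates (length I), `NULL`
#'   for an absent modality.
#' @param size_rna,size_atac Positive per-segment NB size parameters.
#' @param lam Shrinkage weight in `[0, 1]`; 1 = RNA only, 0 = ATAC only.
#' @return Object of class `model_params`.
#' @export
model_params <- function(Phi, pi_rna = NULL, pi_atac = NULL,
                         theta_rna = NULL, theta_atac = NULL,
                         size_rna = NULL, size_atac = NULL, lam = 0.5) {
  stopifnot(length(dim(Phi)) == 3)
  K <- dim(Phi)[1]; I <- dim(Phi)[2]; H <- dim(Phi)[3]
  sums <- apply(Phi, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6) || any(Phi < 0))
    stop("every Phi[k, i, ] must be a probability vector")
  check_simplex <- function(p, what) {
    if (!is.null(p)) {
      if (length(p) != K || abs(sum(p) - 1) > 1e-6 || any(p < 0))
        stop(what, " must be a length-K probability vector")
    }
  }
  check_simplex(pi_rna, "pi_rna"); check_simplex(pi_atac, "pi_atac")
  check_pos <- function(v, what) {
    if (!is.null(v)) {
      if (length(v) != I || any(v <= 0)) stop(what, " must be positive, length I")
    }
  }
  check_pos(theta_rna, "theta_rna"); check_pos(theta_atac, "theta_atac")
  check_pos(size_rna, "size_rna"); check_pos(size_atac, "size_atac")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  structure(list(K = K, I = I, H = H, Phi = Phi,
                 pi_rna = pi_rna, pi_atac = pi_atac,
                 theta_rna = theta_rna, theta_atac = theta_atac,
                 size_rna = size_rna, size_atac = size_atac, lam = lam),
            class = "model_params")
}

# Expected copy number per (cluster, segment): C[k, i] = sum_h Phi[k,i,h] * h
expected_copy <- function(Phi) {
  H <- dim(Phi)[3]
  apply(Phi, c(1, 2), function(p) sum(p * seq_len(H)))
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# N x K matrix of per-cell mixture component log-densities (no mixing
# proportions): L[n, k] = sum_i log NB(x[n,i] | rho_n theta_i C[k,i], size_i)
component_logdens <- function(data, theta, size, C) {
  x <- data$counts
  rho <- data$library_factors
  N <- nrow(x); I <- ncol(x); K <- nrow(C)
  L <- matrix(0, N, K)
  for (k in seq_len(K)) {
    mu <- outer(rho, theta * C[k, ])
    L[, k] <- rowSums(stats::dnbinom(x, mu = mu,
                                     size = rep(size, each = N), log = TRUE))
  }
  L
}

params_for_modality <- function(params, modality) {
  if (modality == "RNA")
    list(pi = params$pi_rna, theta = params$theta_rna, size = params$size_rna)
  else
    list(pi = params$pi_atac, theta = params$theta_atac, size = params$size_atac)
}

#' Marginal mixture log-likelihood of one modality
#'
#' Log-likelihood of the data after marginalising the per-cell cluster
#' assignment: `sum_n log sum_k pi_k prod_i NB(x[n,i] | mu[k,i,n], size_i)`,
#' with the NB mean linear in the expected copy number under Phi.
#'
#' @param data A [segmented_counts()] object.
#' @param params A [model_params()] object.
#' @param modality `"RNA"` or `"ATAC"`; must match `data$modality`.
#' @return Scalar log-likelihood.
#' @export
modality_loglik <- function(data, params, modality = data$modality) {
  if (!identical(data$modality, modality))
    stop("data modality does not match requested modality")
  pm <- params_for_modality(params, modality)
  if (is.null(pm$pi) || is.null(pm$theta) || is.null(pm$size))
    stop("params carry no ", modality, " component")
  if (ncol(data$counts) != params$I)
    stop("segment count mismatch between data and params")
  C <- expected_copy(params$Phi)
  L <- component_logdens(data, pm$theta, pm$size, C)
  sum(log_sum_exp_rows(sweep(L, 2, log(pm$pi), `+`)))
}

#' Shrinkage joint log-likelihood of RNA and ATAC
#'
#' Weighted combination of the per-modality mixture log-likelihoods,
#' `lam * loglik(RNA) + (1 - lam) * loglik(ATAC)`, sharing the copy-number
#' tensor Phi across modalities. At the boundaries (`lam` 1 or 0) a single
#' modality suffices.
#'
#' @param rna,atac [segmented_counts()] objects (either may be `NULL` at the
#'   matching `lam` boundary).
#' @param params A [model_params()] object carrying `lam`.
#' @return Scalar weighted log-likelihood.
#' @export
joint_loglik <- function(rna, atac, params) {
  lam <- params$lam
  if (is.null(rna) && lam > 0)
    stop("RNA data required when lam > 0")
  if (is.null(atac) && lam < 1)
    stop("ATAC data required when lam < 1")
  ll <- 0
  if (lam > 0) ll <- ll + lam * modality_loglik(rna, params, "RNA")
  if (lam < 1) ll <- ll + (1 - lam) * modality_loglik(atac, params, "ATAC")
  ll
}
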