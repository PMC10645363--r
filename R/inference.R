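#' Configuration for model fitting
#'
#' @param K_range Integer vector of cluster numbers to score in
#'   [select_model()].
#' @param lam Shrinkage weight in `[0, 1]` balancing RNA (weight `lam`) and
#'   ATAC (weight `1 - lam`); default 0.5 (both modalities weighted equally).
#' @param steps Maximum number of stochastic gradient steps.
#' @param learning_rate Adam learning rate.
#' @param temperature Initial Gumbel-Softmax temperature.
#' @param temperature_anneal Multiplicative temperature decay per step in
#'   `(0, 1]`; by default chosen so the temperature decays from its initial
#'   value to 0.1 over the run.
#' @param seed Integer seed; all randomness (initialisation, Gumbel noise)
#'   flows from it.
#' @param mode `"flat"` (independent assignments per modality),
#'   `"flat_shared_pi"` (independent assignments, shared mixing proportions)
#'   or `"multiome"` (one assignment per physical cell driving both
#'   modalities).
#' @param score Model-selection score: `"BIC"` (default), `"AIC"` or `"ICL"`.
#' @param restarts Number of random restarts; the best final objective wins.
#' @param relax_frac Fraction of the run using Gumbel-Softmax sampled
#'   (relaxed) copy-state configurations; the remainder refines the mean
#'   relaxed configuration deterministically (default 0.5). The first
#'   restart always runs without relaxation noise, preserving the
#'   data-driven initialisation; later restarts explore with it.
#' @param tol Relative objective change below which convergence is declared
#'   (checked every `eval_every` steps).
#' @param eval_every Interval (in steps) between deterministic objective
#'   evaluations used for convergence checks.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(K_range = 1:8, lam = 0.5, steps = 1000,
                       learning_rate = 0.05, temperature = 1.0,
                       temperature_anneal = NULL, seed = 1,
                       mode = c("flat", "flat_shared_pi", "multiome"),
                       score = c("BIC", "AIC", "ICL"), restarts = 3,
                       relax_frac = 0.5, tol = 1e-5, eval_every = 20) {
  mode <- match.arg(mode)
  score <- match.arg(score)
  if (length(K_range) < 1 || any(K_range < 1))
    stop("K_range must be a non-empty set of integers >= 1")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  stopifnot(steps >= 1, learning_rate > 0, temperature > 0, restarts >= 1)
  if (relax_frac < 0 || relax_frac > 1)
    stop("relax_frac must lie in [0, 1]")
  if (is.null(temperature_anneal))
    temperature_anneal <-
      (0.1 / temperature)^(1 / max(ceiling(steps * max(relax_frac, 1e-3)), 1))
  if (temperature_anneal <= 0 || temperature_anneal > 1)
    stop("temperature_anneal must lie in (0, 1]")
  structure(list(K_range = as.integer(K_range), lam = lam,
                 steps = as.integer(steps), learning_rate = learning_rate,
                 temperature = temperature,
                 temperature_anneal = temperature_anneal,
                 seed = as.integer(seed), mode = mode, score = score,
                 restarts = as.integer(restarts), relax_frac = relax_frac,
                 tol = tol, eval_every = as.integer(eval_every)),
            class = "fit_config")
}

# ---- internal helpers -------------------------------------------------------

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# phi stored as (K*I) x H matrix of state probabilities; C = phi %*% h
phi_from_logits <- function(y, noise = NULL, tau = 1) {
  z <- if (is.null(noise)) y else (y + noise) / tau
  softmax_rows(z)
}

rgumbel <- function(n) -log(-log(stats::runif(n)))

adam_new <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0)
}

adam_step <- function(opt, par, grad, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(par)) {
    g <- grad[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / (1 - b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - b2^opt$t)
    par[[nm]] <- par[[nm]] + lr * mhat / (sqrt(vhat) + eps)
  }
  list(opt = opt, par = par)
}

# Dirichlet log prior of phi rows (rows of the (K*I) x H matrix), alpha is
# I x H recycled over clusters; returns total log density and gradient d/dphi.
dirichlet_prior_terms <- function(phi, alpha_rep) {
  ph <- pmax(phi, 1e-6)
  const <- sum(lgamma(rowSums(alpha_rep)) - rowSums(lgamma(alpha_rep)))
  val <- const + sum((alpha_rep - 1) * log(ph))
  list(value = val, grad = (alpha_rep - 1) / ph)
}

# Collect the per-modality design: counts, rho and shrinkage weight.
modality_inputs <- function(rna, atac, lam) {
  out <- list()
  if (!is.null(rna) && lam > 0)
    out$RNA <- list(data = rna, weight = lam)
  if (!is.null(atac) && lam < 1)
    out$ATAC <- list(data = atac, weight = 1 - lam)
  out
}

# k-means based initialisation on per-cell copy estimates. Clusters, integer
# profiles, rates, dispersion and proportions are initialised consistently
# with each other: theta is anchored so the largest cluster sits on integer
# copy numbers, and NB sizes come from within-cluster moments. `source`
# selects which modality's cells seed the k-means ("all", "RNA" or "ATAC"):
# with unbalanced shrinkage weights a noisy modality can otherwise drown the
# informative one; the caller scores the candidate initialisations by the
# exact objective.
init_state <- function(mods, prior, K, mode, restart, source = "all") {
  H <- prior$H
  I <- length(prior$segment_ids)
  exp_cn <- apply(prior$alpha, 1, which.max)
  chat_list <- list()
  theta0 <- list()
  for (nm in names(mods)) {
    d <- mods[[nm]]$data
    theta0[[nm]] <- pmax(colMeans(d$counts / d$library_factors), 1e-3) / exp_cn
    chat <- sweep(d$counts / d$library_factors, 2, theta0[[nm]], `/`)
    chat_list[[nm]] <- pmin(pmax(chat, 0.5), H + 0.5)
  }
  mat <- if (source == "all") do.call(rbind, chat_list) else chat_list[[source]]
  centers <- NULL
  if (K == 1) {
    centers <- matrix(colMeans(mat), 1, I)
  } else {
    km <- tryCatch(
      stats::kmeans(mat, centers = K, nstart = if (restart > 1) 1 else 5,
                    iter.max = 30),
      error = function(e) NULL)
    if (!is.null(km)) centers <- km$centers
  }
  if (is.null(centers))
    centers <- matrix(stats::runif(K * I, 1, H), K, I)
  if (restart > 1)
    centers <- centers + matrix(stats::rnorm(K * I, 0, 0.4), K, I)
  centers <- pmin(pmax(centers, 1), H)
  # assign every cell of every modality to its nearest centre
  assign_nearest <- function(m) {
    d2 <- vapply(seq_len(nrow(centers)), function(k)
      rowSums(sweep(m, 2, centers[k, ], `-`)^2), numeric(nrow(m)))
    max.col(-matrix(d2, nrow(m), nrow(centers)), ties.method = "first")
  }
  cl_all <- lapply(chat_list, assign_nearest)
  sizes <- pmax(tabulate(unlist(cl_all), K), 1)
  # anchor theta so the largest cluster's centre snaps to integer copies;
  # all centres rescale with it, keeping profiles and rates consistent
  k_big <- which.max(sizes)
  anchor <- pmin(pmax(round(centers[k_big, ]), 1), H)
  scale_i <- centers[k_big, ] / anchor
  centers <- sweep(centers, 2, scale_i, `/`)
  centers <- pmin(pmax(centers, 1), H)
  state <- list()
  for (nm in names(mods)) {
    d <- mods[[nm]]$data
    state[[paste0("lt_", nm)]] <- log(theta0[[nm]] * scale_i)
    # pooled within-cluster method-of-moments NB size
    norm <- d$counts / d$library_factors
    cl_m <- cl_all[[nm]]
    size0 <- vapply(seq_len(I), function(i) {
      mu_k <- tapply(norm[, i], cl_m, mean)
      v_k <- tapply(norm[, i], cl_m, stats::var)
      w_k <- tabulate(cl_m, K)[sort(unique(cl_m))]
      mu <- sum(w_k * mu_k, na.rm = TRUE) / sum(w_k)
      ex <- sum(w_k * pmax(v_k - mu_k, mu_k^2 / 1e3), na.rm = TRUE) /
        sum(w_k)
      if (!is.finite(ex) || ex <= 0) ex <- mu^2 / 10
      min(max(mu^2 / ex, 2), 1e3)
    }, numeric(1))
    state[[paste0("ls_", nm)]] <- log(size0)
  }
  y <- matrix(0, K * I, H)
  for (k in seq_len(K)) for (i in seq_len(I)) {
    y[(i - 1) * K + k, ] <- -2 * (seq_len(H) - centers[k, i])^2
  }
  noise_sd <- if (restart > 1) 0.3 else 0.05
  y <- y + matrix(stats::rnorm(K * I * H, 0, noise_sd), K * I, H)
  state$y <- y
  pl <- log(sizes / sum(sizes))
  if (mode == "flat") {
    for (nm in names(mods)) state[[paste0("pl_", nm)]] <- pl
  } else {
    state$pl <- pl
  }
  state
}

# Deterministic (noise-free) penalised objective and exact responsibilities
# at the current state. Returns objective, per-modality loglik, W list.
eval_state <- function(state, mods, prior, K, mode, alpha_rep) {
  H <- prior$H
  I <- length(prior$segment_ids)
  phi <- phi_from_logits(state$y)
  C <- matrix(phi %*% seq_len(H), K, I)
  Ls <- lapply(names(mods), function(nm) {
    d <- mods[[nm]]$data
    nb_component_logdens_cpp(d$counts, d$library_factors,
                             exp(state[[paste0("lt_", nm)]]),
                             exp(state[[paste0("ls_", nm)]]), C)
  })
  names(Ls) <- names(mods)
  prior_term <- dirichlet_prior_terms(phi, alpha_rep)$value
  W <- list()
  ll_w <- 0
  if (mode == "multiome") {
    logpi <- state$pl - log(sum(exp(state$pl)))
    mix <- matrix(logpi, nrow(Ls[[1]]), K, byrow = TRUE)
    for (nm in names(mods)) mix <- mix + mods[[nm]]$weight * Ls[[nm]]
    lse <- log_sum_exp_rows(mix)
    ll_w <- sum(lse)
    Wm <- exp(mix - lse)
    for (nm in names(mods)) W[[nm]] <- Wm
  } else {
    for (nm in names(mods)) {
      pl <- if (mode == "flat") state[[paste0("pl_", nm)]] else state$pl
      logpi <- pl - log(sum(exp(pl)))
      mix <- sweep(Ls[[nm]], 2, logpi, `+`)
      lse <- log_sum_exp_rows(mix)
      ll_w <- ll_w + mods[[nm]]$weight * sum(lse)
      W[[nm]] <- exp(mix - lse)
    }
  }
  list(objective = ll_w + prior_term, loglik = ll_w, W = W, phi = phi, C = C)
}

# Discrete mode-seeking sweep (iterated conditional modes): for each
# (cluster, segment), test every copy state against the exact marginal
# objective (responsibilities re-enumerated implicitly via the mixture
# log-sum-exp) and accept the best. Gradient flow is slow at crossing the
# logit barrier between integer states; this sweep snaps the profile to a
# local discrete optimum. Returns updated logits and whether anything moved.
icm_sweep <- function(state, mods, prior, K, mode) {
  H <- prior$H
  I <- length(prior$segment_ids)
  y <- state$y
  phi <- phi_from_logits(y)
  cn <- matrix(max.col(phi, ties.method = "first"), K, I)
  # state-wise log densities: D[[m]][[h]] is N x I at copy number h
  D <- list(); Lm <- list(); logpi <- list()
  for (nm in names(mods)) {
    d <- mods[[nm]]$data
    theta <- exp(state[[paste0("lt_", nm)]])
    size <- exp(state[[paste0("ls_", nm)]])
    N <- nrow(d$counts)
    D[[nm]] <- lapply(seq_len(H), function(h)
      stats::dnbinom(d$counts, mu = outer(d$library_factors, theta * h),
                     size = rep(size, each = N), log = TRUE))
    L <- matrix(0, N, K)
    for (k in seq_len(K)) for (i in seq_len(I))
      L[, k] <- L[, k] + D[[nm]][[cn[k, i]]][, i]
    Lm[[nm]] <- L
    pl <- if (mode == "flat") state[[paste0("pl_", nm)]] else state$pl
    logpi[[nm]] <- pl - log(sum(exp(pl)))
  }
  # prior difference between peaked configurations at different states
  log_p1 <- log(0.95); log_p0 <- log(0.05 / (H - 1))
  prior_peaked <- function(i, h) {
    a <- prior$alpha[i, ]
    (a[h] - 1) * log_p1 + sum((a[-h] - 1)) * log_p0
  }
  lse2 <- function(a, b) { m <- pmax(a, b); m + log(exp(a - m) + exp(b - m)) }
  changed <- FALSE
  for (k in seq_len(K)) {
    rest <- list()  # per-cell log-sum-exp over the other clusters
    for (nm in names(mods)) {
      if (mode == "multiome") next
      mix <- sweep(Lm[[nm]], 2, logpi[[nm]], `+`)
      rest[[nm]] <- if (K == 1) rep(-Inf, nrow(mix)) else
        log_sum_exp_rows(mix[, -k, drop = FALSE])
    }
    if (mode == "multiome") {
      Lj <- Reduce(`+`, lapply(names(mods), function(nm)
        mods[[nm]]$weight * Lm[[nm]]))
      mix <- sweep(Lj, 2, logpi[[1]], `+`)
      rest_j <- if (K == 1) rep(-Inf, nrow(mix)) else
        log_sum_exp_rows(mix[, -k, drop = FALSE])
    }
    for (i in seq_len(I)) {
      cur <- cn[k, i]
      if (mode == "multiome") {
        base <- 0
        for (nm in names(mods))
          base <- base + mods[[nm]]$weight *
            (Lm[[nm]][, k] - D[[nm]][[cur]][, i])
        cand <- logpi[[1]][k] + base +
          vapply(seq_len(H), function(h) {
            v <- 0
            for (nm in names(mods))
              v <- v + mods[[nm]]$weight * D[[nm]][[h]][, i]
            v
          }, numeric(length(base)))
        obj_h <- colSums(lse2(matrix(rest_j, nrow(cand), H), cand))
      } else {
        obj_h <- numeric(H)
        for (nm in names(mods)) {
          base <- logpi[[nm]][k] + Lm[[nm]][, k] - D[[nm]][[cur]][, i]
          cand <- base + vapply(seq_len(H), function(h) D[[nm]][[h]][, i],
                                numeric(length(base)))
          obj_h <- obj_h + mods[[nm]]$weight *
            colSums(lse2(matrix(rest[[nm]], nrow(cand), H), cand))
        }
      }
      obj_h <- obj_h + vapply(seq_len(H), function(h) prior_peaked(i, h),
                              numeric(1))
      best_h <- which.max(obj_h)
      if (best_h != cur && obj_h[best_h] > obj_h[cur] + 1e-9) {
        for (nm in names(mods))
          Lm[[nm]][, k] <- Lm[[nm]][, k] - D[[nm]][[cur]][, i] +
            D[[nm]][[best_h]][, i]
        if (mode == "multiome") {
          Lj <- Reduce(`+`, lapply(names(mods), function(nm)
            mods[[nm]]$weight * Lm[[nm]]))
          mix <- sweep(Lj, 2, logpi[[1]], `+`)
          rest_j <- if (K == 1) rep(-Inf, nrow(mix)) else
            log_sum_exp_rows(mix[, -k, drop = FALSE])
        } else {
          for (nm in names(mods)) {
            mix <- sweep(Lm[[nm]], 2, logpi[[nm]], `+`)
            rest[[nm]] <- if (K == 1) rep(-Inf, nrow(mix)) else
              log_sum_exp_rows(mix[, -k, drop = FALSE])
          }
        }
        cn[k, i] <- best_h
        row <- (i - 1) * K + k
        y[row, ] <- log_p0
        y[row, best_h] <- log_p1
        changed <- TRUE
      }
    }
  }
  list(y = y, changed = changed)
}

# One SVI run from a given initial state. Returns state, trace, final eval.
# use_relax toggles the Gumbel-Softmax sampled phase: the first restart runs
# deterministically (protecting the data-driven initialisation), later
# restarts explore with relaxed samples.
svi_run <- function(state, mods, prior, K, mode, config, alpha_rep,
                    use_relax = TRUE) {
  H <- prior$H
  I <- length(prior$segment_ids)
  h_vec <- seq_len(H)
  opt <- adam_new(state)
  trace <- numeric(0)
  tau <- config$temperature
  last_obj <- NULL
  converged_step <- NA_integer_
  n_relax <- if (use_relax) ceiling(config$steps * config$relax_frac) else 0L
  for (step in seq_len(config$steps)) {
    relaxed <- step <= n_relax
    if (relaxed) {
      noise <- matrix(rgumbel(K * I * H), K * I, H)
      phi <- phi_from_logits(state$y, noise, tau)
    } else {
      phi <- phi_from_logits(state$y)
    }
    C <- matrix(phi %*% h_vec, K, I)
    grad <- lapply(state, function(p) p * 0)
    prior_t <- dirichlet_prior_terms(phi, alpha_rep)
    obj <- prior_t$value
    gPhi <- prior_t$grad
    gC_tot <- matrix(0, K, I)
    if (mode == "multiome") {
      logpi <- state$pl - log(sum(exp(state$pl)))
      Ls <- list()
      for (nm in names(mods)) {
        d <- mods[[nm]]$data
        Ls[[nm]] <- nb_component_logdens_cpp(
          d$counts, d$library_factors, exp(state[[paste0("lt_", nm)]]),
          exp(state[[paste0("ls_", nm)]]), C)
      }
      mix <- matrix(logpi, nrow(Ls[[1]]), K, byrow = TRUE)
      for (nm in names(mods)) mix <- mix + mods[[nm]]$weight * Ls[[nm]]
      lse <- log_sum_exp_rows(mix)
      obj <- obj + sum(lse)
      W <- exp(mix - lse)
      pi_cur <- exp(logpi)
      grad$pl <- colSums(W) - nrow(W) * pi_cur
      for (nm in names(mods)) {
        d <- mods[[nm]]$data
        g <- nb_component_grad_cpp(d$counts, d$library_factors,
                                   exp(state[[paste0("lt_", nm)]]),
                                   exp(state[[paste0("ls_", nm)]]),
                                   C, W, mods[[nm]]$weight)
        gC_tot <- gC_tot + g$gC
        grad[[paste0("lt_", nm)]] <- g$gLogTheta
        grad[[paste0("ls_", nm)]] <- g$gLogSize
      }
    } else {
      for (nm in names(mods)) {
        d <- mods[[nm]]$data
        w <- mods[[nm]]$weight
        L <- nb_component_logdens_cpp(
          d$counts, d$library_factors, exp(state[[paste0("lt_", nm)]]),
          exp(state[[paste0("ls_", nm)]]), C)
        pl_name <- if (mode == "flat") paste0("pl_", nm) else "pl"
        pl <- state[[pl_name]]
        logpi <- pl - log(sum(exp(pl)))
        mix <- sweep(L, 2, logpi, `+`)
        lse <- log_sum_exp_rows(mix)
        obj <- obj + w * sum(lse)
        W <- exp(mix - lse)
        pi_cur <- exp(logpi)
        grad[[pl_name]] <- grad[[pl_name]] +
          w * (colSums(W) - nrow(W) * pi_cur)
        g <- nb_component_grad_cpp(d$counts, d$library_factors,
                                   exp(state[[paste0("lt_", nm)]]),
                                   exp(state[[paste0("ls_", nm)]]),
                                   C, W, w)
        gC_tot <- gC_tot + g$gC
        grad[[paste0("lt_", nm)]] <- g$gLogTheta
        grad[[paste0("ls_", nm)]] <- g$gLogSize
      }
    }
    # chain rule: dObj/dphi -> dObj/dy through the tempered softmax
    gPhi <- gPhi + matrix(as.numeric(gC_tot), K * I, H) *
      matrix(h_vec, K * I, H, byrow = TRUE)
    inner <- rowSums(gPhi * phi)
    grad$y <- (phi * (gPhi - inner)) / (if (relaxed) tau else 1)
    upd <- adam_step(opt, state, grad, config$learning_rate)
    opt <- upd$opt
    state <- upd$par
    # keep unconstrained parameters in a numerically safe range
    state$y <- pmin(pmax(state$y, -30), 30)
    for (nm in names(mods)) {
      state[[paste0("lt_", nm)]] <-
        pmin(pmax(state[[paste0("lt_", nm)]], -10), 20)
      state[[paste0("ls_", nm)]] <-
        pmin(pmax(state[[paste0("ls_", nm)]], log(1e-2)), log(1e4))
    }
    trace <- c(trace, obj)
    tau <- max(tau * config$temperature_anneal, 0.1)
    if (!relaxed && (step == n_relax + 1 || step %% 100 == 0)) {
      sw <- icm_sweep(state, mods, prior, K, mode)
      if (sw$changed) {
        state$y <- sw$y
        opt$m$y[] <- 0
        opt$v$y[] <- 0
        last_obj <- NULL  # profile moved; restart the convergence window
      }
    }
    if (step %% config$eval_every == 0) {
      ev <- eval_state(state, mods, prior, K, mode, alpha_rep)
      if (!is.finite(ev$objective)) {
        bad <- which(!is.finite(colSums(ev$C)))
        stop("non-finite objective during optimisation",
             if (length(bad)) paste0(" (segment ",
                                     paste(bad, collapse = ", "), ")"))
      }
      if (!is.null(last_obj)) {
        rel <- abs(ev$objective - last_obj) / (abs(last_obj) + 1e-12)
        if (rel < config$tol) {
          converged_step <- step
          last_obj <- ev$objective
          break
        }
      }
      last_obj <- ev$objective
    }
  }
  sw <- icm_sweep(state, mods, prior, K, mode)
  if (sw$changed) state$y <- sw$y
  final <- eval_state(state, mods, prior, K, mode, alpha_rep)
  list(state = state, trace = trace, final = final,
       converged_step = converged_step)
}

# ---- public API -------------------------------------------------------------

#' Fit the copy-number mixture for a fixed number of clusters
#'
#' Maximises the shrinkage-weighted, Dirichlet-penalised mixture objective by
#' stochastic gradient variational inference: the categorical copy-number
#' states are relaxed with Gumbel-Softmax samples whose temperature anneals
#' over the run, mixing proportions, segment rates and NB size parameters are
#' point-estimated, and cluster responsibilities are obtained exactly by
#' enumeration over the K components. The best of `config$restarts` random
#' initialisations (by final objective) is returned. Deterministic given
#' `config$seed`.
#'
#' @param rna,atac [segmented_counts()] objects; either may be `NULL` when
#'   `config$lam` sits at the matching boundary (1 = RNA only, 0 = ATAC only).
#' @param prior A [cna_prior()] whose segments match the data columns.
#' @param K Number of clusters to fit.
#' @param config A [fit_config()].
#' @return An object of class `cna_fit` with elements `params`
#'   ([model_params()]), `responsibilities` (list per modality, or shared in
#'   multiome mode), `assignments` (hard labels), `map_cn` (K x I integer
#'   matrix), `loglik` (shrinkage-weighted joint log-likelihood), `loglik_full`
#'   (complete unweighted log-likelihood of all data, used by the scores),
#'   `n_params`, `n_obs`, `scores` (BIC/AIC/ICL/entropy), `elbo_trace`,
#'   `empty_clusters`, `K`, `mode`, `lam`.
#' @export
fit <- function(rna = NULL, atac = NULL, prior, K, config = fit_config()) {
  stopifnot(inherits(prior, "cna_prior"))
  mode <- config$mode
  lam <- config$lam
  if (is.null(rna) && is.null(atac))
    stop("at least one modality is required")
  if (is.null(rna) && lam > 0)
    stop("RNA data absent but lam > 0; set lam = 0 for ATAC-only fits")
  if (is.null(atac) && lam < 1)
    stop("ATAC data absent but lam < 1; set lam = 1 for RNA-only fits")
  mods <- modality_inputs(rna, atac, lam)
  if (length(mods) == 0) stop("no modality carries positive weight")
  for (m in mods) {
    if (ncol(m$data$counts) != length(prior$segment_ids))
      stop("segment count mismatch between data and prior")
  }
  if (mode == "multiome") {
    if (length(mods) == 2 &&
        !identical(mods$RNA$data$barcodes, mods$ATAC$data$barcodes))
      stop("multiome mode requires paired data; run pair_multiome() first")
  }
  if (mode == "flat_shared_pi" && length(mods) < 2)
    stop("flat_shared_pi requires both modalities")
  n_cells <- vapply(mods, function(m) nrow(m$data$counts), integer(1))
  if (K > min(n_cells))
    stop("K exceeds the number of cells")
  K <- as.integer(K)
  H <- prior$H
  I <- length(prior$segment_ids)
  alpha_rep <- prior$alpha[rep(seq_len(I), each = K), , drop = FALSE]
  set.seed(config$seed)
  sources <- if (length(mods) > 1) c("all", names(mods)) else "all"
  best <- NULL
  restart_objs <- numeric(config$restarts)
  for (r in seq_len(config$restarts)) {
    if (r == 1) {
      # score the candidate initialisations by the exact objective
      cands <- lapply(sources, function(s)
        init_state(mods, prior, K, mode, r, source = s))
      objs <- vapply(cands, function(st)
        eval_state(st, mods, prior, K, mode, alpha_rep)$objective, numeric(1))
      state0 <- cands[[which.max(objs)]]
    } else {
      state0 <- init_state(mods, prior, K, mode, r,
                           source = sources[1 + (r - 1) %% length(sources)])
    }
    run <- svi_run(state0, mods, prior, K, mode, config, alpha_rep,
                   use_relax = r > 1)
    restart_objs[r] <- run$final$objective
    if (is.null(best) || run$final$objective > best$final$objective)
      best <- run
  }
  build_fit_result(best, mods, prior, K, mode, lam, config, restart_objs)
}

# Assemble the user-facing result from the winning restart.
build_fit_result <- function(run, mods, prior, K, mode, lam, config,
                             restart_objs) {
  H <- prior$H
  I <- length(prior$segment_ids)
  state <- run$state
  phi <- run$final$phi
  Phi <- array(0, c(K, I, H))
  for (h in seq_len(H)) Phi[, , h] <- matrix(phi[, h], K, I)
  norm_pl <- function(pl) {
    p <- exp(pl - max(pl)); p / sum(p)
  }
  theta <- list(); size <- list(); pis <- list()
  for (nm in names(mods)) {
    theta[[nm]] <- exp(state[[paste0("lt_", nm)]])
    size[[nm]] <- exp(state[[paste0("ls_", nm)]])
    pis[[nm]] <- if (mode == "flat") norm_pl(state[[paste0("pl_", nm)]])
                 else norm_pl(state$pl)
  }
  params <- model_params(
    Phi,
    pi_rna = if ("RNA" %in% names(mods)) pis$RNA,
    pi_atac = if ("ATAC" %in% names(mods)) pis$ATAC,
    theta_rna = theta$RNA, theta_atac = theta$ATAC,
    size_rna = size$RNA, size_atac = size$ATAC, lam = lam)
  W <- run$final$W
  if (mode == "multiome") {
    resp <- W[[1]]
    rownames(resp) <- mods[[1]]$data$barcodes
    responsibilities <- resp
    assignments <- max.col(resp, ties.method = "first")
    names(assignments) <- mods[[1]]$data$barcodes
    n_obs <- nrow(resp)
    total_mass <- colSums(resp)
    ent_resp <- list(resp)
  } else {
    responsibilities <- list()
    assignments <- list()
    n_obs <- 0
    total_mass <- numeric(K)
    ent_resp <- list()
    for (nm in names(mods)) {
      resp <- W[[nm]]
      rownames(resp) <- mods[[nm]]$data$barcodes
      key <- tolower(nm)
      responsibilities[[key]] <- resp
      a <- max.col(resp, ties.method = "first")
      names(a) <- mods[[nm]]$data$barcodes
      assignments[[key]] <- a
      n_obs <- n_obs + nrow(resp)
      total_mass <- total_mass + colSums(resp)
      ent_resp[[nm]] <- resp
    }
  }
  map_cn <- map_from_phi(Phi)
  rownames(map_cn) <- paste0("C", seq_len(K))
  colnames(map_cn) <- prior$segment_ids
  v <- count_parameters(K, I, H, modalities = length(mods), mode = mode)
  loglik <- run$final$loglik
  # scores use the complete (unweighted) data log-likelihood: n counts every
  # cell in both modalities, so L must too — the shrinkage-weighted objective
  # would undercount the evidence whenever lam is not at a boundary
  C_map <- expected_copy(Phi)
  Ls_full <- lapply(names(mods), function(nm) {
    d <- mods[[nm]]$data
    nb_component_logdens_cpp(d$counts, d$library_factors,
                             theta[[nm]], size[[nm]], C_map)
  })
  names(Ls_full) <- names(mods)
  if (mode == "multiome") {
    mix <- sweep(Reduce(`+`, Ls_full), 2, log(pis[[1]]), `+`)
    loglik_full <- sum(log_sum_exp_rows(mix))
  } else {
    loglik_full <- 0
    for (nm in names(mods)) {
      mix <- sweep(Ls_full[[nm]], 2, log(pis[[nm]]), `+`)
      loglik_full <- loglik_full + sum(log_sum_exp_rows(mix))
    }
  }
  scores <- compute_scores(loglik_full, v, n_obs, ent_resp)
  structure(list(
    params = params, responsibilities = responsibilities,
    assignments = assignments, map_cn = map_cn, loglik = loglik,
    loglik_full = loglik_full,
    n_params = v, n_obs = n_obs, scores = scores,
    elbo_trace = run$trace, converged_step = run$converged_step,
    restart_objectives = restart_objs,
    empty_clusters = which(total_mass < 1),
    K = K, mode = mode, lam = lam, prior = prior,
    segment_ids = prior$segment_ids, config = config
  ), class = "cna_fit")
}

#' @export
print.cna_fit <- function(x, ...) {
  cat(sprintf("<cna_fit> K = %d (%s, lambda = %.2f)\n", x$K, x$mode, x$lam))
  cat(sprintf("  loglik %.2f | BIC %.2f | AIC %.2f | ICL %.2f\n",
              x$loglik, x$scores$BIC, x$scores$AIC, x$scores$ICL))
  if (length(x$empty_clusters))
    cat("  empty clusters:", paste(x$empty_clusters, collapse = ", "), "\n")
  invisible(x)
}

map_from_phi <- function(Phi) {
  K <- dim(Phi)[1]; I <- dim(Phi)[2]
  out <- matrix(0L, K, I)
  for (k in seq_len(K)) for (i in seq_len(I))
    out[k, i] <- which.max(Phi[k, i, ])  # which.max takes the smallest on ties
  out
}

#' Posterior responsibilities at the fitted parameters
#'
#' Exact Bayes-rule responsibilities `p(z_n = k | x_n)` proportional to
#' `pi_k * prod_i f_k(x[n,i])` at the MAP parameters, recomputed from the
#' stored data-free parameters when a `segmented_counts` is supplied.
#'
#' @param result A `cna_fit`.
#' @param data Optional [segmented_counts()] to score; defaults to the
#'   responsibilities of the training data stored in the fit.
#' @param modality Modality of `data` (defaults to `data$modality`).
#' @return Matrix of per-cell probability vectors over K (rows sum to 1), or
#'   the stored responsibilities when `data` is `NULL`.
#' @export
responsibilities <- function(result, data = NULL, modality = NULL) {
  stopifnot(inherits(result, "cna_fit"))
  if (is.null(data)) return(result$responsibilities)
  if (is.null(modality)) modality <- data$modality
  pm <- params_for_modality(result$params, modality)
  C <- expected_copy(result$params$Phi)
  L <- component_logdens(data, pm$theta, pm$size, C)
  mix <- sweep(L, 2, log(pm$pi), `+`)
  lse <- log_sum_exp_rows(mix)
  W <- exp(mix - lse)
  rownames(W) <- data$barcodes
  W
}

#' MAP integer copy-number matrix
#'
#' `map_cn[k, i] = argmax_h Phi[k, i, h]`, ties broken toward the smaller
#' copy number.
#'
#' @param result A `cna_fit`, or a K x I x H probability array.
#' @return Integer matrix clusters x segments.
#' @export
map_copy_numbers <- function(result) {
  Phi <- if (inherits(result, "cna_fit")) result$params$Phi else result
  map_from_phi(Phi)
}

#' Number of free parameters of a model configuration
#'
#' Counts independent mixing weights (`2(K-1)` for flat, `K-1` for shared-pi
#' and multiome modes), `K * I * (H - 1)` free copy-state probabilities, and
#' one rate plus one NB size parameter per segment and modality.
#'
#' @param K,I,H Clusters, segments, copy states.
#' @param modalities 1 or 2.
#' @param mode `"flat"`, `"flat_shared_pi"` or `"multiome"`.
#' @return Integer parameter count `v` used by the information criteria.
#' @export
count_parameters <- function(K, I, H, modalities = 2,
                             mode = c("flat", "flat_shared_pi", "multiome")) {
  mode <- match.arg(mode)
  stopifnot(K >= 1, I >= 1, H >= 2, modalities %in% c(1, 2))
  mix <- if (mode == "flat") modalities * (K - 1) else (K - 1)
  as.integer(mix + K * I * (H - 1) + modalities * I + modalities * I)
}

#' Model-selection scores
#'
#' `BIC = v log(n) - 2 L`, `AIC = 2 v - 2 L`, `ICL = BIC + H(z)` where
#' `H(z) = -sum_n sum_k z_nk log z_nk` is the entropy of the posterior
#' cluster assignments (with `0 log 0 = 0`).
#'
#' @param loglik Maximised log-likelihood `L`.
#' @param v Number of free parameters.
#' @param n Number of observations (total cells across modalities).
#' @param responsibilities Matrix of responsibilities, or a list of such
#'   matrices (one per modality).
#' @return List with `BIC`, `AIC`, `ICL`, `entropy`.
#' @export
compute_scores <- function(loglik, v, n, responsibilities) {
  stopifnot(n >= 1)
  if (is.matrix(responsibilities)) responsibilities <- list(responsibilities)
  ent <- 0
  for (W in responsibilities) {
    if (any(abs(rowSums(W) - 1) > 1e-6))
      stop("responsibility rows must sum to 1")
    p <- W[W > 0]
    ent <- ent - sum(p * log(p))
  }
  bic <- v * log(n) - 2 * loglik
  list(BIC = bic, AIC = 2 * v - 2 * loglik, ICL = bic + ent, entropy = ent)
}

#' Fit a range of cluster numbers and select the best by score
#'
#' Fits every K in `config$K_range` and returns the fit minimising the
#' configured score (BIC by default) together with the full score table.
#'
#' @inheritParams fit
#' @param config A [fit_config()]; `K_range` and `score` drive the search.
#' @return A list of class `model_selection` with `best_fit`, `best_K`,
#'   `table` (one row per K: K, loglik, v, BIC, AIC, ICL, entropy,
#'   n_empty) and `fits` (all fitted models, named by K).
#' @export
select_model <- function(rna = NULL, atac = NULL, prior,
                         config = fit_config()) {
  fits <- list()
  rows <- list()
  for (K in config$K_range) {
    f <- tryCatch(fit(rna, atac, prior, K, config),
                  error = function(e)
                    stop("fit failed at K = ", K, ": ", conditionMessage(e)))
    fits[[as.character(K)]] <- f
    rows[[as.character(K)]] <- data.frame(
      K = K, loglik = f$loglik_full, v = f$n_params, BIC = f$scores$BIC,
      AIC = f$scores$AIC, ICL = f$scores$ICL, entropy = f$scores$entropy,
      n_empty = length(f$empty_clusters))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  crit <- tab[[config$score]]
  best_K <- tab$K[which.min(crit)]
  structure(list(best_fit = fits[[as.character(best_K)]], best_K = best_K,
                 table = tab, fits = fits, score = config$score),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> best K = %d by %s\n", x$best_K, x$score))
  print(x$table, row.names = FALSE)
  invisible(x)
}
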