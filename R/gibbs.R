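#' MCMC chain configuration
#'
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations (`burn_in < n_iter`).
#' @param thin sampling interval; the chain retains
#'   `floor((n_iter - burn_in) / thin)` draws.
#' @param seed integer seed for the whole chain.
#' @return An object of class `chain_config`.
#' @examples
#' n_retained(chain_config(1e6, 5e5, 5)) # 100000
#' @export
chain_config <- function(n_iter, burn_in, thin = 1L, seed = NULL) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (is.na(n_iter) || is.na(burn_in) || is.na(thin))
    stop("chain settings must be integers (and < 2^31)")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (burn_in < 0L) stop("burn_in must be non-negative")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "chain_config")
}

#' Number of retained draws of a chain configuration
#' @param config a [chain_config()].
#' @return Integer count `floor((n_iter - burn_in) / thin)`.
#' @export
n_retained <- function(config) {
  stopifnot(inherits(config, "chain_config"))
  (config$n_iter - config$burn_in) %/% config$thin
}

#' Default weakly informative priors for a design
#'
#' Inverse-Wishart hyperparameters per covariance structure: degrees of
#' freedom `nu = dim + 1` and scale matrix `S` set to the diagonal of the
#' empirical phenotypic variances of the combinations the structure covers,
#' divided by the number of variance structures in the model (so the prior
#' scales partition the phenotypic variance evenly).  Systematic means get
#' independent flat normals, N(0, 1e8).  The `scale_factor` multiplies every
#' `S` and exists for the documented prior-sensitivity sweep (0.1 and 10).
#'
#' @param design a [build_design()] bundle.
#' @param scale_factor multiplier on every scale matrix.
#' @param beta_var prior variance of each systematic mean.
#' @return An object of class `prior_spec`.
#' @export
default_priors <- function(design, scale_factor = 1, beta_var = 1e8) {
  stopifnot(inherits(design, "design_bundle"))
  K <- length(design$traits); E <- length(design$environments)
  phen_var <- matrix(NA_real_, E, K,
                     dimnames = list(design$environments, design$traits))
  for (e in seq_len(E)) {
    for (t in seq_len(K)) {
      v <- design$Y[design$env_idx == e, t]
      v <- v[!is.na(v)]
      pv <- if (length(v) > 1) var(v) else 0
      if (!is.finite(pv) || pv <= 0)
        stop("empirical phenotypic variance is zero for trait '",
             design$traits[t], "' in environment '", design$environments[e],
             "' -- cannot set a default prior scale")
      phen_var[e, t] <- pv
    }
  }
  n_struct <- 1L + sum(c("genotype", "replicate", "block") %in% design$terms)
  env_scales <- lapply(seq_len(E), function(e)
    diag(phen_var[e, ], nrow = K) * scale_factor / n_struct)
  names(env_scales) <- design$environments
  d_u <- design$d_u
  S_u <- if (design$model_kind == "full") {
    v <- numeric(K * E) # combination order: trait-major, environment fastest
    for (t in seq_len(K)) for (e in seq_len(E))
      v[(t - 1L) * E + e] <- phen_var[e, t]
    diag(v, nrow = K * E)
  } else {
    diag(colMeans(phen_var), nrow = K)
  }
  S_u <- S_u * scale_factor / n_struct
  structure(list(nu_u = d_u + 1, S_u = S_u,
                 nu_r = K + 1, S_r = env_scales,
                 nu_b = K + 1, S_b = env_scales,
                 nu_e = K + 1, S_e = env_scales,
                 beta_var = beta_var, scale_factor = scale_factor,
                 phen_var = phen_var),
            class = "prior_spec")
}

#' @noRd
chain_init <- function(design, priors) {
  K <- length(design$traits); E <- length(design$environments)
  beta0 <- numeric(K * E)
  for (t in seq_len(K)) for (e in seq_len(E)) {
    v <- design$Y[design$env_idx == e, t]
    beta0[(t - 1L) * E + e] <- mean(v, na.rm = TRUE)
  }
  env_init <- lapply(seq_len(E), function(e)
    diag(priors$phen_var[e, ], nrow = K) / 2)
  Su0 <- if (design$model_kind == "full") {
    v <- numeric(K * E)
    for (t in seq_len(K)) for (e in seq_len(E))
      v[(t - 1L) * E + e] <- priors$phen_var[e, t]
    diag(v / 4, nrow = K * E)
  } else diag(colMeans(priors$phen_var) / 4, nrow = K)
  list(beta = beta0, Sigma_u = Su0, Sigma_r = env_init, Sigma_b = env_init,
       Sigma_e = env_init)
}

#' Run the Gibbs sampler
#'
#' Alternates a single joint Gaussian update of all location effects
#' (solving the mixed-model equations under the current covariances) with
#' inverse-Wishart updates of every covariance structure, augmenting missing
#' trait observations from their residual conditionals.  The conditional
#' (given location effects) Gaussian deviance is recorded at every retained
#' draw for DIC computation.  Chains are reproducible: identical design,
#' priors and configuration (including seed) give identical draws.
#'
#' @param design a [build_design()] bundle.
#' @param priors a [default_priors()] spec (or a modified copy).
#' @param config a [chain_config()].
#' @param keep_u retain genotype-effect draws (needed for breeding values).
#' @return An object of class `mtme_fit` holding labeled retained draws of
#'   the systematic means, all covariance matrices, genotype effects and the
#'   per-draw deviance, plus posterior means and chain metadata.
#' @export
run_chain <- function(design, priors = default_priors(design), config,
                      keep_u = TRUE) {
  stopifnot(inherits(design, "design_bundle"),
            inherits(priors, "prior_spec"),
            inherits(config, "chain_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- length(design$traits); E <- length(design$environments)
  init <- chain_init(design, priors)
  has_rep <- "replicate" %in% design$terms
  has_blk <- "block" %in% design$terms
  has_gen <- "genotype" %in% design$terms
  res <- mtme_gibbs_cpp(
    Y = design$Y, obs = matrix(as.integer(design$obs), nrow(design$Y)),
    env = design$env_idx, rep = design$rep_idx, blk = design$blk_idx,
    gen = design$gen_idx, env_of_rep = design$env_of_rep,
    env_of_blk = design$env_of_blk,
    full_model = design$model_kind == "full", n_env = E,
    prior = priors, init = init,
    n_iter = config$n_iter, burn_in = config$burn_in, thin = config$thin,
    keep_u = keep_u, has_rep = has_rep, has_blk = has_blk,
    has_gen = has_gen)

  n_keep <- res$n_keep
  d_u <- design$d_u
  u_dim_labels <- if (design$model_kind == "full") design$combos
                  else design$traits
  to_array <- function(M, d, labels) {
    a <- array(t(M), dim = c(d, d, n_keep), dimnames = list(labels, labels))
    a
  }
  env_arrays <- function(L) {
    out <- lapply(seq_len(E), function(e) to_array(L[[e]], K, design$traits))
    names(out) <- design$environments
    out
  }
  beta <- res$beta
  colnames(beta) <- design$combos
  u <- NULL
  if (keep_u && has_gen) {
    u <- res$u
    colnames(u) <- design$u_labels
  }
  off <- res$offsets
  theta_mean <- as.numeric(res$theta_mean)
  post_mean <- list(
    beta = setNames(theta_mean[seq_len(K * E)], design$combos),
    r = if (has_rep) setNames(theta_mean[off[["off_r"]] + seq_len(length(design$rep_levels) * K)], design$r_labels) else NULL,
    b = if (has_blk) setNames(theta_mean[off[["off_b"]] + seq_len(length(design$blk_levels) * K)], design$b_labels) else NULL,
    u = if (has_gen) setNames(theta_mean[off[["off_u"]] + seq_len(length(design$genotypes) * d_u)], design$u_labels) else NULL,
    Sigma_e = {
      sem <- lapply(res$Sigma_e_mean, function(S) {
        dimnames(S) <- list(design$traits, design$traits); S
      })
      names(sem) <- design$environments
      sem
    })
  structure(list(
    beta = beta,
    Sigma_u = if (has_gen) to_array(res$Sigma_u, d_u, u_dim_labels) else NULL,
    Sigma_r = if (has_rep) env_arrays(res$Sigma_r) else NULL,
    Sigma_b = if (has_blk) env_arrays(res$Sigma_b) else NULL,
    Sigma_e = env_arrays(res$Sigma_e),
    u = u, deviance = as.numeric(res$deviance),
    dev_at_mean = res$dev_at_mean, post_mean = post_mean,
    model_kind = design$model_kind, traits = design$traits,
    environments = design$environments, combos = design$combos,
    genotypes = design$genotypes, terms = design$terms, d_u = d_u,
    n_obs = length(design$y), config = config, priors = priors,
    n_psd_repair = res$n_psd_repair),
    class = "mtme_fit")
}

#' @export
print.mtme_fit <- function(x, ...) {
  cat("MTME Gibbs fit (", x$model_kind, " model): ",
      length(x$deviance), " retained draws, ", x$n_obs, " observations\n",
      sep = "")
  cat("  traits: ", paste(x$traits, collapse = ", "), "; environments: ",
      paste(x$environments, collapse = ", "), "\n", sep = "")
  cat("  posterior mean deviance:", round(mean(x$deviance), 2), "\n")
  if (x$n_psd_repair > 0)
    cat("  note:", x$n_psd_repair, "numerical PSD repair(s) during the chain\n")
  invisible(x)
}

#' Draws of a variance component
#'
#' Extracts the retained draws of one diagonal element of a covariance
#' structure for a given trait and environment.
#'
#' @param fit an [run_chain()] fit.
#' @param structure one of `"genetic"`, `"replicate"`, `"block"`,
#'   `"residual"`.
#' @param trait,env labels.
#' @return Numeric vector of draws.
#' @export
variance_component_draws <- function(fit,
                                     structure = c("genetic", "replicate",
                                                   "block", "residual"),
                                     trait, env) {
  structure <- match.arg(structure)
  t <- match(trait, fit$traits); e <- match(env, fit$environments)
  if (is.na(t)) stop("unknown trait label: ", trait)
  if (is.na(e)) stop("unknown environment label: ", env)
  if (structure == "genetic") {
    if (is.null(fit$Sigma_u)) stop("fit has no genotype effects")
    i <- if (fit$model_kind == "full")
      (t - 1L) * length(fit$environments) + e else t
    return(fit$Sigma_u[i, i, ])
  }
  arr <- switch(structure, replicate = fit$Sigma_r, block = fit$Sigma_b,
                residual = fit$Sigma_e)
  if (is.null(arr)) stop("fit has no '", structure, "' term")
  arr[[env]][t, t, ]
}

#' One draw of all location effects from their joint full conditional
#'
#' Reference (pure R) implementation of the location-block update: given the
#' current covariance matrices, solves the mixed-model equations
#' `C theta = W' R^{-1} y` with
#' `C = W' R^{-1} W + blockdiag(B^{-1}, Sigma_r^{-1} x I, ...)` and draws
#' `theta ~ N(C^{-1} W' R^{-1} y, C^{-1})`.  The chain itself
#' ([run_chain()]) performs the identical update in compiled code; this
#' function exists as the testable single-step operation (its limits are the
#' GLS and OLS fits, which the test suite checks).
#'
#' @param state list with elements `Sigma_u`, `Sigma_r`, `Sigma_b`,
#'   `Sigma_e` (the per-environment lists as in [variance_truth()]); only
#'   the structures present in `design$terms` are used.
#' @param design a [build_design()] bundle.
#' @param priors a [default_priors()] spec (for the systematic-mean prior
#'   variance).
#' @return List with `theta` (the draw), `mean` (the conditional mean, i.e.
#'   the generalized-least-squares solution of the mixed-model equations)
#'   and the draw split into `beta`, `r`, `b`, `u`.
#' @export
sample_location_conditional <- function(state, design,
                                        priors = default_priors(design)) {
  stopifnot(inherits(design, "design_bundle"))
  K <- length(design$traits); E <- length(design$environments)
  has_rep <- "replicate" %in% design$terms
  has_blk <- "block" %in% design$terms
  has_gen <- "genotype" %in% design$terms
  W <- design$X
  if (has_rep) W <- cbind(W, design$Z1)
  if (has_blk) W <- cbind(W, design$Z2)
  if (has_gen) W <- cbind(W, design$Z3)
  W <- as.matrix(W)
  m <- nrow(W); q <- ncol(W)

  # residual precision, block per plot over its observed traits
  Rinv <- matrix(0, m, m)
  for (p in unique(design$row_map$plot)) {
    rows <- which(design$row_map$plot == p)
    e <- design$env_idx[p]
    t_obs <- match(design$row_map$trait[rows], design$traits)
    Soo <- state$Sigma_e[[e]][t_obs, t_obs, drop = FALSE]
    Rinv[rows, rows] <- solve(Soo)
  }
  Dinv <- matrix(0, q, q)
  diag(Dinv)[seq_len(K * E)] <- 1 / priors$beta_var
  off <- K * E
  if (has_rep) {
    Srinv <- lapply(state$Sigma_r, solve)
    for (l in seq_along(design$rep_levels)) {
      idx <- off + (l - 1L) * K + seq_len(K)
      Dinv[idx, idx] <- Dinv[idx, idx] + Srinv[[design$env_of_rep[l]]]
    }
    off <- off + length(design$rep_levels) * K
  }
  if (has_blk) {
    Sbinv <- lapply(state$Sigma_b, solve)
    for (l in seq_along(design$blk_levels)) {
      idx <- off + (l - 1L) * K + seq_len(K)
      Dinv[idx, idx] <- Dinv[idx, idx] + Sbinv[[design$env_of_blk[l]]]
    }
    off <- off + length(design$blk_levels) * K
  }
  if (has_gen) {
    Suinv <- solve(state$Sigma_u)
    d_u <- design$d_u
    for (g in seq_along(design$genotypes)) {
      idx <- off + (g - 1L) * d_u + seq_len(d_u)
      Dinv[idx, idx] <- Dinv[idx, idx] + Suinv
    }
  }
  C <- t(W) %*% Rinv %*% W + Dinv
  rhs <- t(W) %*% Rinv %*% design$y
  U <- chol((C + t(C)) / 2)
  mu <- backsolve(U, forwardsolve(t(U), rhs))
  theta <- mu + backsolve(U, rnorm(q))
  theta <- as.numeric(theta); mu <- as.numeric(mu)
  split_theta <- function(v) {
    out <- list(beta = setNames(v[seq_len(K * E)], design$combos))
    off <- K * E
    if (has_rep) {
      out$r <- setNames(v[off + seq_len(length(design$rep_levels) * K)],
                        design$r_labels)
      off <- off + length(design$rep_levels) * K
    }
    if (has_blk) {
      out$b <- setNames(v[off + seq_len(length(design$blk_levels) * K)],
                        design$b_labels)
      off <- off + length(design$blk_levels) * K
    }
    if (has_gen)
      out$u <- setNames(v[off + seq_len(length(design$genotypes) * design$d_u)],
                        design$u_labels)
    out
  }
  c(list(theta = theta, mean = mu), split_theta(theta),
    list(mean_parts = split_theta(mu)))
}

#' One draw from the inverse-Wishart full conditional of a covariance matrix
#'
#' Given `n` effect vectors (rows of `effects`) that are conditionally iid
#' `N(0, Sigma)` and a prior `Sigma ~ InvWishart(nu, S)`, draws from the
#' conjugate posterior `InvWishart(nu + n, S + effects' effects)`.  A 1x1
#' structure reduces to the scaled-inverse-chi-square distribution.
#'
#' @param effects numeric matrix, one row per level of the structure.
#' @param nu prior degrees of freedom (`> dim - 1` for a proper prior).
#' @param S prior scale matrix.
#' @return One covariance matrix draw.
#' @export
sample_covariance_conditional <- function(effects, nu, S) {
  effects <- as.matrix(effects)
  S <- as.matrix(S)
  d <- ncol(S)
  if (ncol(effects) != d) stop("effects and S disagree on dimension")
  if (nu <= d - 1 && nrow(effects) < d)
    stop("fewer levels (", nrow(effects), ") than dimension (", d,
         ") with a non-proper prior (nu = ", nu, ")")
  df <- nu + nrow(effects)
  Spost <- S + crossprod(effects)
  W <- stats::rWishart(1, df, solve(Spost))[, , 1]
  solve((W + t(W)) / 2)
}

#' Conditional Gaussian deviance of a model state
#'
#' `D = -2 log p(y | beta, r, b, u, Sigma_e)`: for each plot the observed
#' traits contribute `m log(2 pi) + log|S_oo| + e' S_oo^{-1} e`, with `S_oo`
#' the observed sub-block of that environment's residual covariance.  This
#' is the deviance conditional on the location effects (the convention of
#' the animal-model MCMC software family), the quantity [compute_dic()]
#' averages.
#'
#' @param state list with `beta`, and (as present in the design) `r`, `b`,
#'   `u` location-effect vectors in design column order, plus `Sigma_e`.
#' @param design a [build_design()] bundle.
#' @return The deviance (scalar).
#' @export
compute_deviance <- function(state, design) {
  stopifnot(inherits(design, "design_bundle"))
  fitted <- as.numeric(design$X %*% state$beta)
  if ("replicate" %in% design$terms && !is.null(state$r))
    fitted <- fitted + as.numeric(design$Z1 %*% state$r)
  if ("block" %in% design$terms && !is.null(state$b))
    fitted <- fitted + as.numeric(design$Z2 %*% state$b)
  if ("genotype" %in% design$terms && !is.null(state$u))
    fitted <- fitted + as.numeric(design$Z3 %*% state$u)
  resid <- design$y - fitted
  D <- 0
  for (p in unique(design$row_map$plot)) {
    rows <- which(design$row_map$plot == p)
    e <- design$env_idx[p]
    t_obs <- match(design$row_map$trait[rows], design$traits)
    Soo <- state$Sigma_e[[e]][t_obs, t_obs, drop = FALSE]
    eo <- resid[rows]
    D <- D + length(rows) * log(2 * pi) +
      determinant(Soo, logarithm = TRUE)$modulus[1] +
      as.numeric(eo %*% solve(Soo, eo))
  }
  D
}

#' Deviance information criterion of a fit
#'
#' `DIC = D(theta_bar) + 2 pD` with `pD = D_bar - D(theta_bar)`, where
#' `D_bar` is the posterior mean of the per-draw conditional deviance and
#' `D(theta_bar)` the deviance at the posterior means of all parameters.
#' Smaller DIC is preferred.  Absolute values are comparable only between
#' fits produced by this implementation (the deviance is conditional on the
#' location effects).
#'
#' @param fit an [run_chain()] fit (needs at least 2 retained draws).
#' @return A list with `D_bar`, `D_at_mean`, `pD` and `DIC`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "mtme_fit"))
  if (length(fit$deviance) < 2) stop("need at least 2 retained draws")
  D_bar <- mean(fit$deviance)
  D_at_mean <- fit$dev_at_mean
  pD <- D_bar - D_at_mean
  list(D_bar = D_bar, D_at_mean = D_at_mean, pD = pD, DIC = D_at_mean + 2 * pD)
}
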