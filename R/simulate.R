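#' Assemble plot phenotypes from effect matrices
#'
#' Shared by [simulate_trial()] and the calibrated reference trial.  `u` is
#' genotypes x combinations, `r` is rep-levels x traits, `b` block-levels x
#' traits, `e` plots x traits, all on the trait scale.
#' @noRd
assemble_phenotypes <- function(assignment, layout, mu, u, r, b, e,
                                n_supply) {
  traits <- layout$traits; envs <- layout$environments
  K <- length(traits); E <- length(envs)
  n <- nrow(assignment)
  env_idx <- match(assignment$env, envs)
  rep_lev <- (env_idx - 1L) * layout$n_replicates + assignment$replicate
  blk_lev <- (rep_lev - 1L) * layout$n_blocks_per_replicate + assignment$block
  gen_idx <- match(assignment$genotype, rownames(u))
  pheno <- matrix(NA_real_, n, K, dimnames = list(NULL, traits))
  for (t in seq_len(K)) {
    combo <- (t - 1L) * E + env_idx
    pheno[, t] <- mu[combo] + r[cbind(rep_lev, t)] + b[cbind(blk_lev, t)] +
      u[cbind(gen_idx, combo)] + e[, t]
  }
  supply <- n_supply[assignment$env]
  plant_n <- pheno[, "NUpE"] * supply
  grain_yield <- pheno[, "NUtE"] * plant_n
  records <- data.frame(genotype = assignment$genotype, env = assignment$env,
                        replicate = assignment$replicate,
                        block = assignment$block,
                        grain_yield = grain_yield, plant_n = plant_n,
                        n_supply = supply,
                        nupe = pheno[, "NUpE"], nute = pheno[, "NUtE"],
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  records
}

#' Simulate a lattice trial from the MTME generative model
#'
#' Draws genotype effects once per genotype from a zero-mean multivariate
#' normal with covariance `truth$sigma_u` over all trait-by-environment
#' combinations, replicate/block/residual effects per environment with their
#' cross-trait covariances, and builds phenotypes as
#' `mu + r + b + u + e`.  The NUpE and NUtE phenotypes are simulated on the
#' trait scale; raw measurement columns are back-derived from the definition
#' of the traits (`plant_n = nupe * n_supply`,
#' `grain_yield = nute * plant_n`) so a simulated table round-trips through
#' [compute_nue_components()].
#'
#' @param truth a [variance_truth()]; all matrices must be positive
#'   semi-definite.
#' @param layout a [trial_layout()]; its traits/environments must match the
#'   truth.
#' @param seed integer seed (single RNG stream for layout randomization and
#'   all effect draws; identical seeds give identical tables).
#' @param n_supply named total soil N supply (kg/ha) per environment, used
#'   only to back-derive the raw measurement columns.
#' @return A list of class `sim_trial` with elements `records` (plot table),
#'   `true_u` (genotypes x combinations matrix of the drawn genotype
#'   effects), `assignment` and `truth`.
#' @examples
#' sim <- simulate_trial(make_default_truth(), trial_layout(), seed = 1)
#' nrow(sim$records) # 256 plots
#' @export
simulate_trial <- function(truth, layout = trial_layout(), seed = NULL,
                           n_supply = c(LN = 30, HN = 180)) {
  stopifnot(inherits(truth, "variance_truth"), inherits(layout, "trial_layout"))
  if (!identical(truth$traits, layout$traits) ||
      !identical(truth$environments, layout$environments))
    stop("truth and layout disagree on trait/environment labels")
  if (!all(layout$environments %in% names(n_supply)))
    stop("n_supply must be named for every environment")
  if (!is.null(seed)) set.seed(seed)
  traits <- layout$traits; envs <- layout$environments
  K <- length(traits); E <- length(envs)
  G <- layout$n_genotypes
  assignment <- assign_lattice_layout(layout, seed = NULL)

  u <- MASS::mvrnorm(G, mu = rep(0, K * E), Sigma = truth$sigma_u)
  if (G == 1L) u <- matrix(u, nrow = 1L)
  dimnames(u) <- list(genotype_labels(G), combo_labels(traits, envs))

  draw_env_effects <- function(n_per_env, sigma_list) {
    out <- matrix(0, n_per_env * E, K)
    for (e in seq_len(E)) {
      d <- MASS::mvrnorm(n_per_env, mu = rep(0, K),
                         Sigma = sigma_list[[envs[e]]])
      out[(e - 1L) * n_per_env + seq_len(n_per_env), ] <-
        matrix(d, nrow = n_per_env)
    }
    out
  }
  r <- draw_env_effects(layout$n_replicates, truth$sigma_r)
  b <- draw_env_effects(layout$n_replicates * layout$n_blocks_per_replicate,
                        truth$sigma_b)
  n_plots_env <- layout$n_replicates * G
  e_eff <- matrix(0, nrow(assignment), K)
  for (e in seq_len(E)) {
    idx <- which(assignment$env == envs[e])
    e_eff[idx, ] <- matrix(MASS::mvrnorm(length(idx), rep(0, K),
                                         truth$sigma_e[[envs[e]]]),
                           nrow = length(idx))
  }
  records <- assemble_phenotypes(assignment, layout, truth$mu, u, r, b,
                                 e_eff, n_supply)
  structure(list(records = records, true_u = u, assignment = assignment,
                 truth = truth, layout = layout),
            class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("Simulated lattice trial:", nrow(x$records), "plots,",
      x$layout$n_genotypes, "genotypes,",
      length(x$layout$environments), "environments\n")
  invisible(x)
}
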