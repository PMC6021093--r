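#' Calibration truth behind the synthetic reference trial
#'
#' Genetic variances, systematic means and within-environment genetic
#' correlations are the published posterior estimates for a 64-line tropical
#' maize panel evaluated under low (30 kg/ha) and high (180 kg/ha) N supply;
#' residual variances are back-solved from the reported residual coefficients
#' of variation (CVe, in % of the trait mean), and the replicate-plus-block
#' remainder from the reported posterior-mean per-plot heritabilities, split
#' equally between replicate and block.  Cross-environment genetic
#' correlations (not reported) are set to 0.95 for NUtE and 0.20 for NUpE,
#' mirroring the reported top-10 ranking coincidence across N levels (100%
#' and 20-30% respectively); cross-trait cross-environment covariances are
#' zero.
#'
#' @return A `variance_truth` object.
#' @seealso [nue_reference_trial()]
#' @export
nue_reference_truth <- function() {
  traits <- c("NUpE", "NUtE"); envs <- c("LN", "HN")
  # combination order: NUpE:LN, NUpE:HN, NUtE:LN, NUtE:HN
  mu <- c(2.103, 0.499, 30.318, 28.842)
  sg2 <- c(0.183, 0.095, 27.534, 40.323)
  h2_mean <- c(0.057, 0.038, 0.233, 0.463)
  cve_pct <- c(21.61, 51.36, 29.49, 19.53)
  se2 <- (cve_pct / 100 * mu)^2
  remainder <- sg2 / h2_mean - sg2 - se2 # replicate + block
  stopifnot(all(remainder > 0))
  sr2 <- remainder / 2; sb2 <- remainder / 2

  sd_g <- sqrt(sg2)
  r_within <- c(LN = -0.002, HN = -0.051) # NUpE-NUtE, per environment
  r_across <- c(NUpE = 0.20, NUtE = 0.95) # same trait, LN-HN
  Su <- diag(sg2)
  Su[1, 3] <- Su[3, 1] <- r_within["LN"] * sd_g[1] * sd_g[3]
  Su[2, 4] <- Su[4, 2] <- r_within["HN"] * sd_g[2] * sd_g[4]
  Su[1, 2] <- Su[2, 1] <- r_across["NUpE"] * sd_g[1] * sd_g[2]
  Su[3, 4] <- Su[4, 3] <- r_across["NUtE"] * sd_g[3] * sd_g[4]

  env_diag <- function(v2) lapply(1:2, function(e) diag(v2[c(e, e + 2)],
                                                        nrow = 2))
  variance_truth(mu = mu, sigma_u = Su, sigma_r = env_diag(sr2),
                 sigma_b = env_diag(sb2), sigma_e = env_diag(se2),
                 traits = traits, environments = envs)
}

#' Recolour a draw matrix so its sample moments are exact
#'
#' Centres the columns and transforms so the sample covariance (denominator
#' n - 1) equals `Sigma` exactly.  Needs more rows than columns.
#' @noRd
match_moments <- function(Z, Sigma) {
  Z <- as.matrix(Z)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  S <- crossprod(Zc) / (nrow(Z) - 1)
  Zw <- Zc %*% solve(chol(S))
  out <- Zw %*% chol(Sigma)
  attr(out, "scaled:center") <- NULL
  out
}

#' Synthetic reference trial with exactly calibrated moments
#'
#' A deterministic, fully synthetic stand-in for a real 64-line maize NUE
#' lattice trial: one 8 x 8 lattice square with two replications per N level.
#' Effects are drawn once from [nue_reference_truth()] under a fixed internal
#' seed and then *moment-matched*, i.e. linearly recoloured so that the
#' realized sample moments equal the calibration targets exactly: the
#' per-combination phenotypic means equal `mu`; the 64 genotype-effect
#' vectors have sample covariance exactly `sigma_u`; block and residual
#' effects have exact per-environment covariances; the two replicate effects
#' per environment are `+a/-a` patterns with exact variance.  A correctly
#' implemented sampler fitted to this table should therefore recover the
#' published genetic-parameter estimates the calibration encodes, which makes
#' the table a reproducible end-to-end regression target that ships with the
#' package (the original field data are not redistributed here).
#'
#' @return A `sim_trial` list (see [simulate_trial()]); `$records` is the
#'   256-plot table and `$true_u` the moment-matched genotype effects.
#' @examples
#' ref <- nue_reference_trial()
#' round(mean(subset(ref$records, env == "LN")$nupe), 3) # 2.103 by construction
#' @export
nue_reference_trial <- function() {
  truth <- nue_reference_truth()
  layout <- trial_layout()
  envs <- layout$environments
  K <- 2L; E <- 2L; G <- layout$n_genotypes
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(104729L)
  assignment <- assign_lattice_layout(layout, seed = NULL)

  u <- match_moments(matrix(rnorm(G * K * E), G), truth$sigma_u)
  dimnames(u) <- list(genotype_labels(G), combo_labels(layout$traits, envs))

  # replicate effects: 2 levels per environment -> +/- pattern, exact variance
  r <- matrix(0, layout$n_replicates * E, K)
  for (e in seq_len(E)) {
    sdr <- sqrt(diag(truth$sigma_r[[envs[e]]]))
    r[(e - 1L) * 2L + 1:2, ] <- outer(c(1, -1) / sqrt(2), sdr)
  }
  nblk_env <- layout$n_replicates * layout$n_blocks_per_replicate
  b <- matrix(0, nblk_env * E, K)
  for (e in seq_len(E)) {
    b[(e - 1L) * nblk_env + seq_len(nblk_env), ] <-
      match_moments(matrix(rnorm(nblk_env * K), nblk_env),
                    truth$sigma_b[[envs[e]]])
  }
  e_eff <- matrix(0, nrow(assignment), K)
  for (e in seq_len(E)) {
    idx <- which(assignment$env == envs[e])
    e_eff[idx, ] <- match_moments(matrix(rnorm(length(idx) * K), length(idx)),
                                  truth$sigma_e[[envs[e]]])
  }
  records <- assemble_phenotypes(assignment, layout, truth$mu, u, r, b,
                                 e_eff, n_supply = c(LN = 30, HN = 180))
  structure(list(records = records, true_u = u, assignment = assignment,
                 truth = truth, layout = layout),
            class = "sim_trial")
}
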