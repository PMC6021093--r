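# Shared fixtures and memoised fits for the test suite.  Everything is built
# in code; no data files.

# A single-trait, single-environment toy table: n "genotypes" observed once,
# one replicate, one block (used for reduced-model calibration checks).
toy_single_records <- function(y, env = "LN") {
  n <- length(y)
  data.frame(genotype = sprintf("g%02d", seq_len(n)), env = env,
             replicate = 1L, block = 1L, nupe = y,
             stringsAsFactors = FALSE)
}

# Minimal hand-built mtme_fit carrying prescribed variance-component draws,
# for plug-in identity tests of the posterior summaries.
fake_fit <- function(sg2, sr2, sb2, se2, cov_g = 0,
                     traits = c("NUpE", "NUtE"), envs = c("LN", "HN"),
                     beta = NULL) {
  n <- length(sg2[[1]])
  K <- length(traits); E <- length(envs); d <- K * E
  labs <- as.vector(vapply(traits, function(tr) paste(tr, envs, sep = ":"),
                           character(E)))
  Su <- array(0, c(d, d, n), dimnames = list(labs, labs, NULL))
  for (i in seq_len(d)) Su[i, i, ] <- sg2[[i]]
  if (!identical(cov_g, 0)) {
    # cov_g: list per env of cross-trait genetic covariance draws
    for (e in seq_len(E)) {
      Su[e, E + e, ] <- cov_g[[e]]
      Su[E + e, e, ] <- cov_g[[e]]
    }
  }
  env_arr <- function(v2) {
    out <- lapply(seq_len(E), function(e) {
      a <- array(0, c(K, K, n), dimnames = list(traits, traits, NULL))
      for (t in seq_len(K)) a[t, t, ] <- v2[[(t - 1) * E + e]]
      a
    })
    names(out) <- envs
    out
  }
  if (is.null(beta)) beta <- matrix(1, n, d)
  colnames(beta) <- labs
  structure(list(beta = beta, Sigma_u = Su, Sigma_r = env_arr(sr2),
                 Sigma_b = env_arr(sb2), Sigma_e = env_arr(se2),
                 u = NULL, deviance = rep(0, n), dev_at_mean = 0,
                 model_kind = "full", traits = traits, environments = envs,
                 combos = labs, genotypes = character(0),
                 terms = c("genotype", "replicate", "block"), d_u = d,
                 n_obs = 0L, n_psd_repair = 0L),
            class = "mtme_fit")
}

const_draws <- function(x, n = 50) rep(x, n)

# --- memoised long fits on the synthetic reference trial -------------------
# Shared across the end-to-end tests so each model is fitted once.
.fit_cache <- new.env(parent = emptyenv())

reference_records <- function() {
  if (is.null(.fit_cache$ref)) .fit_cache$ref <- nue_reference_trial()
  .fit_cache$ref
}

reference_fit <- function(key) {
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  ref <- reference_records()
  spec <- switch(key,
    mtme.full = list(traits = c("NUpE", "NUtE"), kind = "full",
                     cfg = chain_config(100000, 20000, 10, seed = 1234)),
    mtme.null = list(traits = c("NUpE", "NUtE"), kind = "null",
                     cfg = chain_config(50000, 10000, 10, seed = 1234)),
    st_nupe.full = list(traits = "NUpE", kind = "full",
                        cfg = chain_config(50000, 10000, 10, seed = 1235)),
    st_nupe.null = list(traits = "NUpE", kind = "null",
                        cfg = chain_config(50000, 10000, 10, seed = 1235)),
    st_nute.full = list(traits = "NUtE", kind = "full",
                        cfg = chain_config(50000, 10000, 10, seed = 1236)),
    st_nute.null = list(traits = "NUtE", kind = "null",
                        cfg = chain_config(50000, 10000, 10, seed = 1236)),
    stop("unknown fit key: ", key))
  d <- build_design(ref$records, spec$kind, traits = spec$traits)
  .fit_cache[[key]] <- run_chain(d, default_priors(d), spec$cfg,
                                 keep_u = spec$kind == "full")
  .fit_cache[[key]]
}

# Prior-sensitivity sweep fits (scale matrices x0.1 and x10), run only when a
# reference check falls outside its band.
reference_sweep_fit <- function(scale_factor) {
  key <- paste0("mtme.full.sweep", scale_factor)
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  ref <- reference_records()
  d <- build_design(ref$records, "full")
  .fit_cache[[key]] <- run_chain(d, default_priors(d, scale_factor),
                                 chain_config(30000, 6000, 10, seed = 1234))
  .fit_cache[[key]]
}
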