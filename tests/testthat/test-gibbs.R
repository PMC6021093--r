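test_that("chain retention arithmetic matches the schedule", {
  expect_equal(n_retained(chain_config(1000000L, 500000L, 5L)), 100000L)
  expect_equal(n_retained(chain_config(1000, 500, 5)), 100L)
  expect_equal(n_retained(chain_config(1001, 500, 5)), 100L)
  expect_error(chain_config(100, 100, 5), "burn_in")
  expect_error(chain_config(100, 10, 0), "thin")
})

test_that("default priors carry the documented structure dimensions", {
  sim <- simulate_trial(make_default_truth(), trial_layout(), seed = 8)
  d <- build_design(sim$records, "full")
  pr <- default_priors(d)
  expect_equal(dim(pr$S_u), c(4L, 4L))
  expect_equal(pr$nu_u, 5)
  expect_equal(dim(pr$S_e$LN), c(2L, 2L))
  expect_equal(pr$nu_e, 3)
  # scales partition the phenotypic variance across the 4 structures
  expect_equal(pr$S_e$LN[1, 1], pr$phen_var["LN", "NUpE"] / 4)

  d1 <- build_design(sim$records, "full", traits = "NUpE")
  pr1 <- default_priors(d1)
  expect_equal(dim(pr1$S_e$LN), c(1L, 1L))
  expect_equal(dim(pr1$S_u), c(2L, 2L)) # env-specific effects, one trait

  rec <- sim$records
  rec$nupe[rec$env == "LN"] <- 1.0
  expect_error(default_priors(build_design(rec, "full")), "variance is zero")
})

test_that("location draws match the OLS oracle on a mean-only toy", {
  set.seed(31)
  y <- rnorm(60, mean = 5, sd = 2)
  d <- build_design(toy_single_records(y), "full", traits = "NUpE",
                    environments = "LN", terms = character(0))
  pr <- default_priors(d)
  state <- list(Sigma_e = list(LN = matrix(4)))
  draws <- replicate(400, sample_location_conditional(state, d, pr)$beta)
  one <- sample_location_conditional(state, d, pr)
  # conditional mean is the (flat-prior) OLS fit: the sample mean
  expect_equal(one$mean_parts$beta[["NUpE:LN"]], mean(y), tolerance = 1e-5)
  # draw distribution: N(ybar, sigma^2 / n)
  expect_equal(mean(draws), mean(y), tolerance = 4 * 2 / sqrt(60 * 400))
  expect_equal(sd(draws), 2 / sqrt(60), tolerance = 0.04)
})

test_that("location draws collapse to the GLS solution as residuals vanish", {
  # 4-observation toy: two environments with different residual variances;
  # the conditional mean is the per-environment (GLS) mean, and as the
  # residual variance shrinks the draws pin down on it
  rec <- data.frame(genotype = c("g1", "g2", "g1", "g2"),
                    env = c("LN", "LN", "HN", "HN"),
                    replicate = 1L, block = 1L,
                    nupe = c(1.0, 3.0, 10.0, 14.0), stringsAsFactors = FALSE)
  d <- build_design(rec, "full", traits = "NUpE", terms = character(0))
  pr <- default_priors(d)
  state <- list(Sigma_e = list(LN = matrix(2), HN = matrix(8)))
  set.seed(32)
  s <- sample_location_conditional(state, d, pr)
  expect_equal(unname(s$mean_parts$beta), c(2, 12), tolerance = 1e-6)
  state0 <- list(Sigma_e = list(LN = matrix(1e-12), HN = matrix(4e-12)))
  s0 <- sample_location_conditional(state0, d, pr)
  expect_equal(s0$theta, s0$mean, tolerance = 1e-4)
  expect_equal(unname(s0$beta), c(2, 12), tolerance = 1e-4)
})

test_that("location draws are reproducible under a fixed RNG state", {
  set.seed(33)
  y <- rnorm(20)
  d <- build_design(toy_single_records(y), "full", traits = "NUpE",
                    environments = "LN", terms = character(0))
  pr <- default_priors(d)
  state <- list(Sigma_e = list(LN = matrix(1)))
  set.seed(99); a <- sample_location_conditional(state, d, pr)
  set.seed(99); b <- sample_location_conditional(state, d, pr)
  expect_identical(a$theta, b$theta)
})

test_that("covariance conditional is the conjugate inverse-Wishart update", {
  # zero scatter: draw is from the prior-with-counts IW(nu + n, S);
  # check first moment of the 1x1 case, S / (df - 2)
  set.seed(41)
  n <- 6; nu <- 3; S <- matrix(8)
  draws <- replicate(4000,
    sample_covariance_conditional(matrix(0, n, 1), nu, S)[1, 1])
  df <- nu + n
  expect_equal(mean(draws), S[1, 1] / (df - 2), tolerance = 0.08)
  # scalar case is scaled-inverse-chi-square: KS against the analytic CDF
  set.seed(42)
  eff <- matrix(rnorm(50, sd = 2))
  Spost <- S[1, 1] + sum(eff^2); dfp <- nu + 50
  d2 <- replicate(4000, sample_covariance_conditional(eff, nu, S)[1, 1])
  ks <- suppressWarnings(
    stats::ks.test(d2, function(x) 1 - stats::pchisq(Spost / x, dfp)))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("a single covariance draw concentrates on the sample scatter", {
  set.seed(43)
  Sigma <- matrix(c(4, 1, 0, 0,
                    1, 2, 0, 0,
                    0, 0, 3, -1,
                    0, 0, -1, 5), 4, byrow = TRUE)
  eff <- MASS::mvrnorm(10000, rep(0, 4), Sigma)
  draw <- sample_covariance_conditional(eff, nu = 5, S = diag(4) * 0.01)
  expect_equal(draw, cov(eff) * (9999 / 10000), tolerance = 0.1)
})

test_that("improper covariance updates are refused", {
  expect_error(sample_covariance_conditional(matrix(0, 1, 3), nu = 1,
                                             S = diag(3)), "fewer levels")
})

test_that("run_chain retains the configured number of draws and is seeded", {
  sim <- simulate_trial(make_default_truth(),
                        trial_layout(n_genotypes = 16, block_size = 4,
                                     n_blocks_per_replicate = 4), seed = 10)
  d <- build_design(sim$records, "full")
  cfg <- chain_config(1000, 500, 5, seed = 77)
  f1 <- run_chain(d, default_priors(d), cfg)
  expect_equal(length(f1$deviance), 100)
  expect_equal(nrow(f1$beta), 100)
  f2 <- run_chain(d, default_priors(d), cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$Sigma_u, f2$Sigma_u)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- run_chain(d, default_priors(d), chain_config(1000, 500, 5, seed = 78))
  expect_false(identical(f1$beta, f3$beta))
})

test_that("every retained covariance draw is symmetric positive definite", {
  sim <- simulate_trial(make_default_truth(),
                        trial_layout(n_genotypes = 16, block_size = 4,
                                     n_blocks_per_replicate = 4), seed = 12)
  d <- build_design(sim$records, "full")
  fit <- run_chain(d, default_priors(d), chain_config(600, 100, 1, seed = 5))
  for (k in seq(1, 500, by = 25)) {
    Su <- fit$Sigma_u[, , k]
    expect_equal(Su, t(Su))
    expect_gt(min(eigen(Su, symmetric = TRUE, only.values = TRUE)$values), 0)
    for (en in c("LN", "HN")) {
      Se <- fit$Sigma_e[[en]][, , k]
      expect_gt(min(eigen(Se, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("conditional deviance has its closed forms and symmetries", {
  # records whose phenotypes equal the combination means exactly
  layout <- trial_layout(n_genotypes = 16, block_size = 4,
                         n_blocks_per_replicate = 4)
  truth <- make_default_truth()
  z <- variance_truth(mu = truth$mu, sigma_u = matrix(0, 4, 4),
                      sigma_r = list(matrix(0, 2, 2), matrix(0, 2, 2)),
                      sigma_b = list(matrix(0, 2, 2), matrix(0, 2, 2)),
                      sigma_e = list(matrix(0, 2, 2), matrix(0, 2, 2)))
  sim <- simulate_trial(z, layout, seed = 13)
  d <- build_design(sim$records, "full")
  n_obs <- length(d$y)
  state <- list(beta = unname(truth$mu),
                r = rep(0, ncol(d$Z1)), b = rep(0, ncol(d$Z2)),
                u = rep(0, ncol(d$Z3)),
                Sigma_e = list(diag(2), diag(2)))
  expect_equal(compute_deviance(state, d), n_obs * log(2 * pi),
               tolerance = 1e-8)
  state2 <- state
  state2$Sigma_e <- list(diag(2) * 2, diag(2) * 2)
  expect_equal(compute_deviance(state2, d),
               n_obs * log(2 * pi) + n_obs * log(2), tolerance = 1e-8)
  # permutation invariance
  d2 <- build_design(sim$records[sample(nrow(sim$records)), ], "full")
  expect_equal(compute_deviance(state, d2), compute_deviance(state, d))
})

test_that("pD is near one for a mean-only model with pinned variance", {
  set.seed(55)
  y <- rnorm(80, 3, 1)
  d <- build_design(toy_single_records(y), "full", traits = "NUpE",
                    environments = "LN", terms = character(0))
  pr <- default_priors(d)
  pr$nu_e <- 1e6
  pr$S_e <- list(LN = matrix(1e6)) # residual variance pinned at 1
  fit <- run_chain(d, pr, chain_config(6000, 1000, 1, seed = 56))
  dic <- compute_dic(fit)
  expect_equal(dic$pD, 1, tolerance = 0.25)
  expect_equal(dic$DIC, dic$D_bar + dic$pD, tolerance = 1e-9)
})

test_that("constant deviance gives pD zero by definition", {
  f <- fake_fit(sg2 = list(const_draws(1), const_draws(1), const_draws(1),
                           const_draws(1)),
                sr2 = list(const_draws(1), const_draws(1), const_draws(1),
                           const_draws(1)),
                sb2 = list(const_draws(1), const_draws(1), const_draws(1),
                           const_draws(1)),
                se2 = list(const_draws(1), const_draws(1), const_draws(1),
                           const_draws(1)))
  f$deviance <- rep(123.4, 50)
  f$dev_at_mean <- 123.4
  dic <- compute_dic(f)
  expect_equal(dic$pD, 0)
  expect_equal(dic$DIC, 123.4)
})
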