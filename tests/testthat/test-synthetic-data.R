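test_that("lattice assignment satisfies the design invariants", {
  layout <- trial_layout()
  a <- assign_lattice_layout(layout, seed = 7)
  expect_equal(nrow(a), 2 * 2 * 64)
  # every genotype exactly once per (env, replicate), 4 plots overall
  expect_true(all(table(a$genotype) == 4))
  per_rep <- table(a$env, a$replicate)
  expect_true(all(per_rep == 64))
  for (key in unique(paste(a$env, a$replicate))) {
    sub <- a[paste(a$env, a$replicate) == key, ]
    expect_equal(sort(unique(sub$genotype)), sort(unique(a$genotype)))
    expect_true(all(table(sub$block) == layout$block_size))
    expect_false(anyDuplicated(sub$genotype) > 0)
  }
  expect_identical(a, assign_lattice_layout(layout, seed = 7))
  expect_false(identical(a, assign_lattice_layout(layout, seed = 8)))
})

test_that("inconsistent layout sizing is rejected", {
  expect_error(trial_layout(n_genotypes = 63), "sizing")
})

test_that("default truth encodes the reference genetic parameters", {
  tr <- make_default_truth()
  expect_equal(unname(tr$sigma_u["NUtE:HN", "NUtE:HN"]), 40.323)
  expect_equal(unname(tr$sigma_u["NUpE:HN", "NUpE:HN"]), 0.095)
  expect_equal(unname(tr$mu["NUpE:LN"]), 2.103)
  expect_equal(unname(tr$mu["NUtE:HN"]), 28.842)
  h2 <- implied_h2(tr)
  expect_equal(unname(h2), c(0.023, 0.016, 0.215, 0.490), tolerance = 1e-10)
  # off-diagonal genetic covariances default to zero
  expect_equal(sum(abs(tr$sigma_u)) , sum(diag(abs(tr$sigma_u))))
})

test_that("simulated phenotype moments match the generative model", {
  # pure-residual truth: unit variance phenotypes per trait-environment cell
  z4 <- matrix(0, 4, 4)
  eye <- list(diag(2), diag(2))
  truth <- variance_truth(mu = rep(0, 4), sigma_u = z4,
                          sigma_r = list(matrix(0, 2, 2), matrix(0, 2, 2)),
                          sigma_b = list(matrix(0, 2, 2), matrix(0, 2, 2)),
                          sigma_e = eye)
  sim <- simulate_trial(truth, trial_layout(), seed = 11)
  for (en in c("LN", "HN")) {
    sub <- sim$records[sim$records$env == en, ]
    # MC error of a sample variance at 128 plots: sd about sqrt(2/127)
    expect_equal(var(sub$nupe), 1, tolerance = 0.4)
    expect_equal(var(sub$nute), 1, tolerance = 0.4)
  }
})

test_that("simulation is deterministic given the seed", {
  s1 <- simulate_trial(make_default_truth(), trial_layout(), seed = 3)
  s2 <- simulate_trial(make_default_truth(), trial_layout(), seed = 3)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$true_u, s2$true_u)
})

test_that("ledgered genotype effects recover sigma_u across seeds", {
  truth <- make_default_truth()
  u_all <- do.call(rbind, lapply(1:20, function(s)
    simulate_trial(truth, trial_layout(), seed = 100 + s)$true_u))
  v <- var(u_all[, "NUtE:HN"])
  se <- 40.323 * sqrt(2 / (nrow(u_all) - 1))
  expect_lt(abs(v - 40.323), 3 * se)
})

test_that("genotype-effect sample covariance converges to sigma_u at n = 512", {
  layout <- trial_layout(n_genotypes = 512, block_size = 8,
                         n_blocks_per_replicate = 64)
  truth <- make_default_truth()
  sim <- simulate_trial(truth, layout, seed = 21)
  S <- cov(sim$true_u)
  for (i in 1:4) {
    se <- truth$sigma_u[i, i] * sqrt(2 / 511)
    expect_lt(abs(S[i, i] - truth$sigma_u[i, i]), 3 * se)
  }
  for (i in 1:3) for (j in (i + 1):4) {
    se <- sqrt(truth$sigma_u[i, i] * truth$sigma_u[j, j] / 511)
    expect_lt(abs(S[i, j]), 3 * se)
  }
  # independence between genotypes: effects of disjoint genotype halves
  half <- sim$true_u[1:256, "NUtE:HN"]
  other <- sim$true_u[257:512, "NUtE:HN"]
  expect_lt(abs(cor(half, other)), 3 / sqrt(256))
})

test_that("non-PSD truth matrices are rejected before sampling", {
  bad <- matrix(c(1, 2, 2, 1), 2) # eigenvalues 3, -1
  expect_error(
    variance_truth(mu = rep(0, 4), sigma_u = diag(4),
                   sigma_r = list(diag(2), diag(2)),
                   sigma_b = list(diag(2), diag(2)),
                   sigma_e = list(bad, diag(2))),
    "positive semi-definite")
})
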