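test_that("heritability draws obey the plug-in identities", {
  ones <- function() list(const_draws(1), const_draws(1), const_draws(1),
                          const_draws(1))
  f <- fake_fit(sg2 = ones(), sr2 = ones(), sb2 = ones(), se2 = ones())
  expect_equal(heritability_draws(f, "NUpE", "LN"), const_draws(0.25))
  zs <- ones(); zs[[2]] <- const_draws(0)
  f0 <- fake_fit(sg2 = zs, sr2 = ones(), sb2 = ones(), se2 = ones())
  expect_equal(heritability_draws(f0, "NUpE", "HN"), const_draws(0))
})

test_that("heritability is invariant to rescaling a trait", {
  set.seed(61)
  rnd <- function() lapply(1:4, function(i) runif(50, 0.5, 3))
  sg2 <- rnd(); sr2 <- rnd(); sb2 <- rnd(); se2 <- rnd()
  f1 <- fake_fit(sg2, sr2, sb2, se2)
  c2 <- 7.3^2 # rescale NUpE by 7.3 in both environments
  scale_t1 <- function(v) { v[[1]] <- v[[1]] * c2; v[[2]] <- v[[2]] * c2; v }
  f2 <- fake_fit(scale_t1(sg2), scale_t1(sr2), scale_t1(sb2), scale_t1(se2))
  for (en in c("LN", "HN"))
    expect_equal(heritability_draws(f1, "NUpE", en),
                 heritability_draws(f2, "NUpE", en), tolerance = 1e-12)
  # draws always lie in [0, 1]
  h <- heritability_draws(f1, "NUtE", "HN")
  expect_true(all(h >= 0 & h <= 1))
})

test_that("genetic correlation draws hit the algebraic boundaries", {
  v <- list(const_draws(4), const_draws(4), const_draws(9), const_draws(9))
  ones <- function() list(const_draws(1), const_draws(1), const_draws(1),
                          const_draws(1))
  fpos <- fake_fit(v, ones(), ones(), ones(),
                   cov_g = list(const_draws(6), const_draws(6)))
  expect_equal(genetic_correlation_draws(fpos, "LN"), const_draws(1),
               ignore_attr = TRUE)
  fzero <- fake_fit(v, ones(), ones(), ones(),
                    cov_g = list(const_draws(0), const_draws(0)))
  expect_equal(genetic_correlation_draws(fzero, "HN"), const_draws(0),
               ignore_attr = TRUE)
  # zero-variance draws are dropped and counted
  v0 <- v; v0[[1]] <- c(0, rep(4, 49))
  f0 <- fake_fit(v0, ones(), ones(), ones(),
                 cov_g = list(const_draws(0), const_draws(0)))
  r <- genetic_correlation_draws(f0, "LN")
  expect_true(is.na(r[1]))
  expect_equal(attr(r, "n_dropped"), 1)
})

test_that("HPD intervals match analytic quantiles", {
  set.seed(62)
  z <- rnorm(1e6)
  h <- hpd_interval(z)
  expect_equal(unname(h["lower"]), -1.96, tolerance = 0.02)
  expect_equal(unname(h["upper"]), 1.96, tolerance = 0.02)
  ex <- rexp(1e6)
  he <- hpd_interval(ex)
  expect_lt(unname(he["lower"]), 0.02) # HPD of a monotone density starts at 0
  expect_equal(unname(he["upper"]), -log(0.05), tolerance = 0.02)
  expect_equal(unname(hpd_interval(rep(3.3, 10))), c(3.3, 3.3))
  expect_error(hpd_interval(c(1)), "at least 2")
})

test_that("HPD width is monotone in the mass and spans the range at 1", {
  set.seed(63)
  z <- rgamma(20000, 2, 1)
  widths <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(p) {
    h <- hpd_interval(z, p); unname(h["upper"] - h["lower"])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  h1 <- hpd_interval(z, 0.9999)
  expect_equal(unname(h1["lower"]), min(z), tolerance = 0.05)
  expect_equal(unname(h1["upper"]), max(z), tolerance = 0.25)
})

test_that("the KDE posterior mode matches analytic modes", {
  set.seed(64)
  g <- rgamma(1e6, shape = 2, scale = 1)
  expect_equal(posterior_mode(g), 1, tolerance = 0.05) # (shape-1)*scale
  z <- rnorm(1e6, mean = 2.5)
  m <- posterior_mode(z)
  expect_equal(m, mean(z), tolerance = 0.05)          # symmetric: mode = mean
  expect_equal(m, median(z), tolerance = 0.05)
  expect_equal(posterior_mode(rep(4.2, 100)), 4.2)
  expect_warning(small <- posterior_mode(c(1, 2, 3, 4, 5)), "median")
  expect_equal(small, 3)
})

test_that("variation coefficients follow their plug-in definitions", {
  ones <- function() list(const_draws(1), const_draws(1), const_draws(1),
                          const_draws(1))
  f <- fake_fit(sg2 = list(const_draws(4), const_draws(4), const_draws(4),
                           const_draws(4)),
                sr2 = ones(), sb2 = ones(), se2 = ones())
  cv <- variation_coefficients(f, "NUpE", "LN", observed_mean = 10)
  expect_equal(cv$cvg, 20)
  expect_equal(cv$cve, 10)
  expect_equal(cv$index, 2)
  feq <- fake_fit(sg2 = ones(), sr2 = ones(), sb2 = ones(), se2 = ones())
  expect_equal(variation_coefficients(feq, "NUtE", "HN", 5)$index, 1)
  expect_error(variation_coefficients(f, "NUpE", "LN", 0), "positive")
})

test_that("the Geweke diagnostic is calibrated on stationary chains", {
  set.seed(65)
  z <- vapply(1:100, function(i) geweke_diagnostic(rnorm(10000)), numeric(1))
  expect_gte(sum(abs(z) < 1.96), 94)
  # gross nonstationarity is flagged
  expect_gt(abs(geweke_diagnostic(c(rep(0, 5000) + rnorm(5000, sd = .1),
                                    rep(10, 5000) + rnorm(5000, sd = .1)))),
            10)
  expect_error(geweke_diagnostic(rep(1, 10000)), "zero-variance")
  expect_error(geweke_diagnostic(rnorm(100)), "at least 50")
})

test_that("summaries are deterministic and structurally complete", {
  sim <- simulate_trial(make_default_truth(),
                        trial_layout(n_genotypes = 16, block_size = 4,
                                     n_blocks_per_replicate = 4), seed = 14)
  d <- build_design(sim$records, "full")
  cfg <- chain_config(1200, 200, 2, seed = 15)
  s1 <- summarize_genetics(run_chain(d, default_priors(d), cfg),
                           sim$records, geweke_check = FALSE)
  s2 <- summarize_genetics(run_chain(d, default_priors(d), cfg),
                           sim$records, geweke_check = FALSE)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$trait_env), 4)
  expect_equal(s1$trait_env$trait, c("NUpE", "NUpE", "NUtE", "NUtE"))
  expect_equal(nrow(s1$correlations), 2)
  expect_true(all(s1$trait_env$h2_hpd_lower <= s1$trait_env$h2_median))
  expect_true(all(s1$trait_env$h2_median <= s1$trait_env$h2_hpd_upper))
})
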