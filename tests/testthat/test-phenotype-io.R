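test_that("NUE component construction follows the ratio definitions", {
  expect_equal(compute_nue_components(3000, 60, 30)$nupe, 2)
  expect_equal(compute_nue_components(3000, 100, 30)$nute, 30)
  z <- compute_nue_components(3000, 0, 30)
  expect_equal(z$nupe, 0)
  expect_true(is.na(z$nute))
  expect_error(compute_nue_components(3000, 60, 0), "positive")
  expect_error(compute_nue_components(3000, 60, -5), "positive")
})

test_that("nupe * nute identity holds under joint rescaling", {
  set.seed(5)
  gy <- runif(50, 500, 9000); pn <- runif(50, 10, 200)
  ns <- runif(50, 20, 200)
  for (c_scale in c(1, 2, 7.5)) {
    v <- compute_nue_components(c_scale * gy, c_scale * pn, ns)
    expect_equal(v$nupe * v$nute, c_scale * gy / ns, tolerance = 1e-12)
  }
})

test_that("plot tables round-trip through write and read", {
  sim <- simulate_trial(make_default_truth(), trial_layout(), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plot_table(sim$records, path)
  back <- read_plot_table(path)
  expect_equal(nrow(back), 256)
  for (col in c("genotype", "env", "replicate", "block"))
    expect_equal(back[[col]], sim$records[[col]])
  for (col in c("grain_yield", "plant_n", "n_supply", "nupe", "nute"))
    expect_equal(back[[col]], sim$records[[col]], tolerance = 1e-8)
})

test_that("schema violations and parse failures are addressed precisely", {
  sim <- simulate_trial(make_default_truth(), trial_layout(), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- sim$records
  rec$block <- NULL
  utils::write.csv(rec, path, row.names = FALSE)
  expect_error(read_plot_table(path), "block")

  path2 <- withr::local_tempfile(fileext = ".csv")
  rec2 <- sim$records
  rec2$grain_yield <- as.character(rec2$grain_yield)
  rec2$grain_yield[c(4, 9)] <- "NA"
  utils::write.csv(rec2, path2, row.names = FALSE, quote = FALSE)
  back <- read_plot_table(path2)
  expect_equal(nrow(back), 256) # flagged, not dropped
  expect_true(all(is.na(back$grain_yield[c(4, 9)])))

  path3 <- withr::local_tempfile(fileext = ".csv")
  rec3 <- sim$records
  rec3$nupe <- as.character(rec3$nupe)
  rec3$nupe[7] <- "oops"
  utils::write.csv(rec3, path3, row.names = FALSE, quote = FALSE)
  expect_error(read_plot_table(path3), "row.*7")
})

test_that("missing phenotypes are flagged and counted, never dropped", {
  sim <- simulate_trial(make_default_truth(), trial_layout(), seed = 2)
  rec <- sim$records
  rec$nute[c(1, 5, 6)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_plot_table(rec, path)
  back <- read_plot_table(path)
  expect_equal(attr(back, "n_missing"), 3)
  expect_equal(sum(back$missing_phenotype), 3)
})

test_that("whitespace-delimited tables and column mappings are supported", {
  sim <- simulate_trial(make_default_truth(), trial_layout(), seed = 2)
  rec <- sim$records
  names(rec)[names(rec) == "genotype"] <- "line"
  path <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(rec, path, row.names = FALSE, quote = FALSE)
  back <- read_plot_table(path, col_map = list(genotype = "line"))
  expect_equal(back$genotype, sim$records$genotype)
  expect_equal(back$nute, sim$records$nute, tolerance = 1e-8)
})

test_that("trial validation separates hard failures from warnings", {
  sim <- simulate_trial(make_default_truth(), trial_layout(), seed = 4)
  v <- validate_trial(sim$records)
  expect_true(v$pass)
  expect_equal(v$n_environments, 2)
  expect_true(all(v$genotypes_per_env_rep$n_genotypes == 64))
  expect_length(v$duplicate_keys, 0)

  dup <- rbind(sim$records, sim$records[17, ])
  vd <- validate_trial(dup)
  expect_false(vd$pass)
  expect_match(vd$duplicate_keys[1],
               paste(sim$records$genotype[17], sim$records$env[17], sep = "|"),
               fixed = TRUE)

  # one genotype absent from one replicate: warning, not failure
  drop1 <- sim$records[!(sim$records$genotype == "G001" &
                           sim$records$env == "LN" &
                           sim$records$replicate == 1), ]
  vu <- validate_trial(drop1)
  expect_true(vu$pass)
  expect_true(length(vu$warnings) > 0)
})
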