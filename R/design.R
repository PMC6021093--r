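#' Index of a trait-by-environment combination
#'
#' Combinations are ordered trait-major with environment fastest; for the
#' default labels: `(NUpE, LN) = 1`, `(NUpE, HN) = 2`, `(NUtE, LN) = 3`,
#' `(NUtE, HN) = 4`.
#'
#' @param trait,env labels.
#' @param traits,environments ordered label sets defining the indexing.
#' @return Integer index in `1:(n_traits * n_environments)`.
#' @examples
#' index_trait_env("NUpE", "LN") # 1
#' index_trait_env("NUtE", "HN") # 4
#' @export
index_trait_env <- function(trait, env, traits = c("NUpE", "NUtE"),
                            environments = c("LN", "HN")) {
  t <- match(trait, traits)
  e <- match(env, environments)
  if (any(is.na(t))) stop("unknown trait label: ", trait[is.na(t)][1])
  if (any(is.na(e))) stop("unknown environment label: ", env[is.na(e)][1])
  as.integer((t - 1L) * length(environments) + e)
}

#' @noRd
trait_column <- function(trait) tolower(trait)

#' @noRd
canonical_order <- function(records, environments) {
  order(match(records$env, environments), records$replicate, records$block,
        records$genotype)
}

#' Stack the multi-trait response vector
#'
#' Observations are ordered deterministically: plots by environment,
#' replicate, block and genotype, then trait within plot.  Missing
#' observations contribute no rows.  The returned row map is invertible: it
#' identifies each stacked entry's plot and combination.
#'
#' @param records plot records data frame.
#' @param traits,environments ordered labels.
#' @return A list with `y` (numeric vector) and `row_map` (data frame with
#'   columns `genotype`, `env`, `replicate`, `block`, `trait`, `combo`).
#' @export
stack_response <- function(records, traits = c("NUpE", "NUtE"),
                           environments = c("LN", "HN")) {
  records <- records[canonical_order(records, environments), , drop = FALSE]
  K <- length(traits)
  n <- nrow(records)
  y_all <- as.numeric(t(as.matrix(records[, trait_column(traits),
                                          drop = FALSE])))
  map <- data.frame(
    genotype = rep(records$genotype, each = K),
    env = rep(records$env, each = K),
    replicate = rep(records$replicate, each = K),
    block = rep(records$block, each = K),
    trait = rep(traits, times = n), stringsAsFactors = FALSE)
  keep <- !is.na(y_all)
  map <- map[keep, , drop = FALSE]
  map$combo <- index_trait_env(map$trait, map$env, traits, environments)
  rownames(map) <- NULL
  list(y = as.numeric(y_all[keep]), row_map = map)
}

#' Build the design bundle of the MTME model
#'
#' Translates a validated plot table into the stacked response `y` and
#' sparse incidence matrices of
#' `y = X beta + Z1 r + Z2 b + Z3 u + e`: `X` maps trait-by-environment
#' means, `Z1` replicate-within-environment effects, `Z2`
#' block-within-replicate-within-environment effects and `Z3` genotype
#' effects.  Under the **full** model genotype-effect columns are indexed by
#' genotype x trait x environment (environment-specific genotype effects,
#' i.e. G-by-E interaction); under the **null** model they are indexed by
#' genotype x trait and shared across environments.  Replicate and block
#' columns are always environment-specific.  `y`, `X`, `Z1` and `Z2` are
#' identical between the two model kinds.
#'
#' @param records plot records; must pass [validate_trial()].
#' @param model `"full"` or `"null"`.
#' @param traits,environments ordered labels; single-trait models are built
#'   by passing one trait label.
#' @param terms random terms to include (the systematic means and the
#'   residual are always present).  The default is the complete model;
#'   reduced variants are used for calibration checks.
#' @return An object of class `design_bundle` holding `y`, `X`, `Z1`, `Z2`,
#'   `Z3`, column label maps, the plot-wise arrays used by the sampler, and
#'   `model_kind`.
#' @examples
#' sim <- simulate_trial(make_default_truth(), trial_layout(), seed = 1)
#' d <- build_design(sim$records, "full")
#' length(d$y); dim(d$Z3) # 512; 512 x 256
#' @export
build_design <- function(records, model = c("full", "null"),
                         traits = c("NUpE", "NUtE"),
                         environments = c("LN", "HN"),
                         terms = c("genotype", "replicate", "block")) {
  model <- match.arg(model)
  terms <- if (length(terms))
    match.arg(terms, c("genotype", "replicate", "block"), several.ok = TRUE)
  else character(0)
  stopifnot(is.data.frame(records))
  for (tr in traits) {
    col <- trait_column(tr)
    if (!col %in% names(records))
      stop("trait column '", col, "' not found in records")
    if (all(is.na(records[[col]])))
      stop("trait column '", col, "' is entirely missing")
  }
  val <- validate_trial(records)
  if (!val$pass)
    stop("records fail validation: duplicated (genotype, env, replicate) ",
         "key(s): ", paste(head(val$duplicate_keys, 5), collapse = "; "))
  if (!all(records$env %in% environments))
    stop("records contain environments outside: ",
         paste(environments, collapse = ", "))

  records <- records[canonical_order(records, environments), , drop = FALSE]
  K <- length(traits); E <- length(environments)
  n <- nrow(records)
  env_idx <- match(records$env, environments)

  # environment-nested level enumeration (levels ordered env, then label)
  rep_key <- paste(records$env, records$replicate, sep = "|")
  rep_levels <- unique(rep_key[order(env_idx, records$replicate)])
  rep_idx <- match(rep_key, rep_levels)
  env_of_rep <- match(sub("\\|.*", "", rep_levels), environments)
  blk_key <- paste(records$env, records$replicate, records$block, sep = "|")
  blk_levels <- unique(blk_key[order(env_idx, records$replicate,
                                     records$block)])
  blk_idx <- match(blk_key, blk_levels)
  env_of_blk <- match(sub("\\|.*", "", blk_levels), environments)
  genotypes <- sort(unique(records$genotype))
  gen_idx <- match(records$genotype, genotypes)
  G <- length(genotypes)

  Y <- sapply(traits, function(tr) as.numeric(records[[trait_column(tr)]]))
  Y <- matrix(Y, nrow = n, dimnames = list(NULL, traits))
  obs <- !is.na(Y)

  combos <- combo_labels(traits, environments)
  d_u <- if (model == "full") K * E else K
  u_labels <- if (model == "full") {
    as.vector(t(outer(genotypes, combos, paste, sep = ":")))
  } else {
    as.vector(t(outer(genotypes, traits, paste, sep = ":")))
  }
  r_labels <- as.vector(t(outer(rep_levels, traits, paste, sep = ":")))
  b_labels <- as.vector(t(outer(blk_levels, traits, paste, sep = ":")))

  # stacked rows: plot-major, trait innermost, missing omitted
  row_plot <- rep(seq_len(n), each = K)[t(obs)]
  row_trait <- rep(seq_len(K), times = n)[t(obs)]
  y <- as.numeric(t(Y))[t(obs)]
  m <- length(y)
  combo_of_row <- (row_trait - 1L) * E + env_idx[row_plot]

  sp <- function(j, ncol, labels) {
    M <- Matrix::sparseMatrix(i = seq_len(m), j = j, x = 1,
                              dims = c(m, ncol))
    colnames(M) <- labels
    M
  }
  X <- sp(combo_of_row, K * E, combos)
  Z1 <- sp((rep_idx[row_plot] - 1L) * K + row_trait,
           length(rep_levels) * K, r_labels)
  Z2 <- sp((blk_idx[row_plot] - 1L) * K + row_trait,
           length(blk_levels) * K, b_labels)
  ucol_of_row <- if (model == "full") combo_of_row else row_trait
  Z3 <- sp((gen_idx[row_plot] - 1L) * d_u + ucol_of_row, G * d_u, u_labels)

  row_map <- data.frame(genotype = records$genotype[row_plot],
                        env = records$env[row_plot],
                        replicate = records$replicate[row_plot],
                        block = records$block[row_plot],
                        trait = traits[row_trait],
                        combo = combo_of_row, plot = row_plot,
                        stringsAsFactors = FALSE)

  structure(list(
    y = y, X = X, Z1 = Z1, Z2 = Z2, Z3 = Z3, row_map = row_map,
    model_kind = model, traits = traits, environments = environments,
    terms = terms, combos = combos, genotypes = genotypes,
    rep_levels = rep_levels, blk_levels = blk_levels,
    u_labels = u_labels, r_labels = r_labels, b_labels = b_labels, d_u = d_u,
    # plot-wise arrays for the sampler
    Y = Y, obs = obs, env_idx = env_idx, rep_idx = rep_idx,
    blk_idx = blk_idx, gen_idx = gen_idx, env_of_rep = env_of_rep,
    env_of_blk = env_of_blk, records = records, validation = val),
    class = "design_bundle")
}

#' @export
print.design_bundle <- function(x, ...) {
  cat("MTME design bundle (", x$model_kind, " model): ",
      length(x$y), " observations, ", nrow(x$Y), " plots\n", sep = "")
  cat("  X: ", ncol(x$X), " combination means; Z1: ", ncol(x$Z1),
      " replicate cols; Z2: ", ncol(x$Z2), " block cols; Z3: ",
      ncol(x$Z3), " genotype cols\n", sep = "")
  invisible(x)
}
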