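#' Run the full analysis pipeline
#'
#' Read (or simulate) -> validate -> design -> fit full and null models for
#' the requested trait sets -> posterior genetic-parameter summaries -> DIC
#' model comparison -> breeding-value ranking -> top-k coincidence between
#' the multi-trait and single-trait fits and between environments.  When
#' `out_dir` is given, every table is written as CSV plus a machine-readable
#' JSON manifest; a stage failure aborts with a stage-named error and leaves
#' the tables already written in place.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   * `input`: path to a plot table readable by [read_plot_table()], or
#'     `NULL` to simulate;
#'   * `simulation`: list with `truth` (`"default"`, `"reference"` or a
#'     [variance_truth()]) and `seed` (ignored when `input` is given);
#'   * `models`: subset of `"mtme"`, `"st_nupe"`, `"st_nute"`;
#'   * `chain`: list with `n_iter`, `burn_in`, `thin`, `seed`;
#'   * `k`: top-list size (default 10);
#'   * `out_dir`: output directory or `NULL`.
#' @return A list with the fits, DIC table, summaries, breeding-value
#'   tables, coincidence table and the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("stage [config]: reading YAML configs needs the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  models <- config$models %||% c("mtme", "st_nupe", "st_nute")
  known <- c("mtme", "st_nupe", "st_nute")
  if (!all(models %in% known))
    stop("stage [config]: unknown model name(s): ",
         paste(setdiff(models, known), collapse = ", "))
  ch <- config$chain %||% list()
  cfg <- chain_config(ch$n_iter %||% 20000L, ch$burn_in %||% 5000L,
                      ch$thin %||% 5L, ch$seed %||% 1L)
  k <- config$k %||% 10L

  records <- stage("input", {
    if (!is.null(config$input)) {
      read_plot_table(config$input, col_map = config$col_map)
    } else {
      sim_cfg <- config$simulation %||% list()
      truth <- sim_cfg$truth %||% "default"
      if (identical(truth, "reference")) {
        nue_reference_trial()$records
      } else {
        if (identical(truth, "default")) truth <- make_default_truth()
        if (!inherits(truth, "variance_truth"))
          stop("simulation$truth must be 'default', 'reference' or a variance_truth")
        simulate_trial(truth, trial_layout(), seed = sim_cfg$seed %||% 1L)$records
      }
    }
  })
  val <- stage("validate", {
    v <- validate_trial(records)
    if (!v$pass) stop("duplicated plot keys: ",
                      paste(head(v$duplicate_keys, 5), collapse = "; "))
    v
  })

  trait_sets <- list(mtme = c("NUpE", "NUtE"), st_nupe = "NUpE",
                     st_nute = "NUtE")
  fits <- list(); dic_rows <- list(); summaries <- list(); bv <- list()
  for (mname in models) {
    traits <- trait_sets[[mname]]
    for (kind in c("full", "null")) {
      key <- paste(mname, kind, sep = ".")
      fits[[key]] <- stage(paste0("fit:", key), {
        d <- build_design(records, kind, traits = traits)
        run_chain(d, default_priors(d), cfg, keep_u = (kind == "full"))
      })
    }
    cmp <- compare_models(compute_dic(fits[[paste0(mname, ".full")]]),
                          compute_dic(fits[[paste0(mname, ".null")]]))
    dic_rows[[mname]] <- data.frame(
      model = mname, traits = paste(traits, collapse = ","),
      dic_full = compute_dic(fits[[paste0(mname, ".full")]])$DIC,
      dic_null = compute_dic(fits[[paste0(mname, ".null")]])$DIC,
      delta = cmp$delta, preferred = cmp$preferred,
      stringsAsFactors = FALSE)
    summaries[[mname]] <- stage(paste0("summarize:", mname),
      summarize_genetics(fits[[paste0(mname, ".full")]], records))
    bv[[mname]] <- stage(paste0("rank:", mname),
      breeding_value_table(fits[[paste0(mname, ".full")]]))
  }
  dic_table <- do.call(rbind, dic_rows)
  rownames(dic_table) <- NULL

  # top-k coincidences: multi- vs single-trait per trait x env,
  # and across environments per trait within each model
  coin <- list()
  envs <- c("LN", "HN")
  st_of <- c(NUpE = "st_nupe", NUtE = "st_nute")
  for (tr in c("NUpE", "NUtE")) {
    st <- st_of[[tr]]
    if (all(c("mtme", st) %in% models)) {
      for (en in envs) {
        coin[[length(coin) + 1L]] <- data.frame(
          comparison = "mtme_vs_single", trait = tr, env = en,
          coincidence = coincidence_percentage(
            rank_top_k(bv[["mtme"]], tr, en, k),
            rank_top_k(bv[[st]], tr, en, k)), stringsAsFactors = FALSE)
      }
    }
    for (mname in intersect(c("mtme", st), models)) {
      coin[[length(coin) + 1L]] <- data.frame(
        comparison = paste0("across_env_", mname), trait = tr, env = "LN:HN",
        coincidence = coincidence_percentage(
          rank_top_k(bv[[mname]], tr, "LN", k),
          rank_top_k(bv[[mname]], tr, "HN", k)), stringsAsFactors = FALSE)
    }
  }
  coincidence <- if (length(coin)) do.call(rbind, coin) else NULL

  manifest <- list(models = models,
                   chain = unclass(cfg), k = k,
                   n_records = nrow(records),
                   n_missing = val$n_missing_phenotype,
                   outputs = character(0))
  out <- list(records = records, validation = val, fits = fits,
              dic = dic_table, summaries = summaries,
              breeding_values = bv, coincidence = coincidence,
              manifest = manifest)

  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(df, name) {
        p <- file.path(config$out_dir, name)
        utils::write.csv(df, p, row.names = FALSE)
        manifest$outputs <<- c(manifest$outputs, name)
      }
      wr(dic_table, "model_comparison.csv")
      for (mname in models) {
        wr(summaries[[mname]]$trait_env,
           paste0("genetic_summary_", mname, ".csv"))
        if (!is.null(summaries[[mname]]$correlations))
          wr(summaries[[mname]]$correlations,
             paste0("genetic_correlations_", mname, ".csv"))
        wr(as.data.frame(bv[[mname]]), paste0("breeding_values_", mname, ".csv"))
      }
      if (!is.null(coincidence)) wr(coincidence, "coincidence.csv")
      manifest$outputs <- c(manifest$outputs, "manifest.json")
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      out$manifest <- manifest
    })
  }
  invisible(out)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
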