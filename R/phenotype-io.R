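#' Compute the NUE component traits from raw measurements
#'
#' N-uptake efficiency is total aboveground plant N over total soil N supply;
#' N-utilization efficiency is grain yield over total aboveground plant N.
#' `nute` is undefined (NA) where `plant_n` is zero.
#'
#' @param grain_yield grain yield, kg/ha (at 145 g/kg moisture).
#' @param plant_n total aboveground-biomass N at maturity, kg/ha.
#' @param n_supply total soil N supply, kg/ha; must be strictly positive.
#' @return A data frame with columns `nupe` and `nute`.
#' @examples
#' compute_nue_components(3000, 60, 30) # nupe 2, nute 50
#' @export
compute_nue_components <- function(grain_yield, plant_n, n_supply) {
  if (any(!is.na(n_supply) & n_supply <= 0))
    stop("n_supply must be strictly positive (kg/ha of soil N)")
  nupe <- plant_n / n_supply
  nute <- ifelse(!is.na(plant_n) & plant_n == 0, NA_real_,
                 grain_yield / plant_n)
  data.frame(nupe = nupe, nute = nute)
}

#' @noRd
normalize_env <- function(env) {
  v <- toupper(trimws(as.character(env)))
  out <- ifelse(v %in% c("HN", "H", "HIGH", "HIGHN", "HIGH_N"), "HN",
                ifelse(v %in% c("LN", "L", "LOW", "LOWN", "LOW_N"), "LN",
                       NA_character_))
  bad <- unique(v[is.na(out) & !is.na(v)])
  if (length(bad))
    stop("unrecognized environment label(s): ", paste(bad, collapse = ", "),
         " (expected HN/LN)")
  out
}

#' @noRd
parse_numeric_column <- function(x, name) {
  v <- trimws(as.character(x))
  v[v %in% c("", "NA", "NaN", ".")] <- NA
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad))
    stop("column '", name, "' has unparseable numeric value(s) at row(s) ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  out
}

#' Read a plot-level phenotype table
#'
#' Reads CSV, TSV or whitespace-delimited TXT with a configurable column
#' mapping, types the columns, normalizes environment labels to HN/LN, and
#' constructs `nupe`/`nute` from the raw measurement columns when the trait
#' columns are absent.  Rows with a missing phenotype are flagged in the
#' logical column `missing_phenotype` (and counted in the `n_missing`
#' attribute), never silently dropped; the design builder later omits the
#' missing observations from the stacked response.
#'
#' @param path file to read.
#' @param col_map optional named list/vector mapping standard names
#'   (`genotype`, `env`, `replicate`, `block`, `grain_yield`, `plant_n`,
#'   `n_supply`, `nupe`, `nute`) to the file's column names.
#' @param sep field separator; `NULL` chooses by extension (`.csv` comma,
#'   `.tsv` tab, anything else whitespace).
#' @return A data frame of typed plot records with attribute `n_missing`.
#' @export
read_plot_table <- function(path, col_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
           else if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t"
           else ""
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = character(0),
                           colClasses = "character")
  std <- c("genotype", "env", "replicate", "block", "grain_yield",
           "plant_n", "n_supply", "nupe", "nute")
  map <- setNames(std, std)
  if (!is.null(col_map)) {
    col_map <- unlist(col_map)
    map[names(col_map)] <- col_map
  }
  pick <- function(name) {
    col <- map[[name]]
    if (col %in% names(raw)) raw[[col]] else NULL
  }
  required <- c("genotype", "env", "replicate", "block")
  for (name in required) {
    if (is.null(pick(name)))
      stop("schema error: required column '", map[[name]],
           "' (for '", name, "') is missing")
  }
  have_traits <- !is.null(pick("nupe")) && !is.null(pick("nute"))
  have_raw <- !is.null(pick("grain_yield")) && !is.null(pick("plant_n")) &&
    !is.null(pick("n_supply"))
  if (!have_traits && !have_raw)
    stop("schema error: need either trait columns ('", map[["nupe"]], "', '",
         map[["nute"]], "') or raw columns ('", map[["grain_yield"]], "', '",
         map[["plant_n"]], "', '", map[["n_supply"]], "')")

  out <- data.frame(genotype = as.character(pick("genotype")),
                    env = normalize_env(pick("env")),
                    replicate = as.integer(parse_numeric_column(pick("replicate"), "replicate")),
                    block = as.integer(parse_numeric_column(pick("block"), "block")),
                    stringsAsFactors = FALSE)
  for (name in c("grain_yield", "plant_n", "n_supply")) {
    v <- pick(name)
    out[[name]] <- if (is.null(v)) NA_real_ else parse_numeric_column(v, name)
  }
  if (have_traits) {
    out$nupe <- parse_numeric_column(pick("nupe"), "nupe")
    out$nute <- parse_numeric_column(pick("nute"), "nute")
  } else {
    nue <- compute_nue_components(out$grain_yield, out$plant_n, out$n_supply)
    out$nupe <- nue$nupe
    out$nute <- nue$nute
  }
  out$missing_phenotype <- is.na(out$nupe) | is.na(out$nute)
  attr(out, "n_missing") <- sum(out$missing_phenotype)
  out
}

#' Write plot records as tidy CSV
#'
#' @param records plot records data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(records, path) {
  keep <- intersect(c("genotype", "env", "replicate", "block", "grain_yield",
                      "plant_n", "n_supply", "nupe", "nute"),
                    names(records))
  utils::write.csv(records[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a plot-record table against the trial design contract
#'
#' Reports environment count, genotypes per environment-replicate,
#' duplicated plot keys, the block-size histogram and missing-phenotype
#' counts.  Only duplicated `(genotype, env, replicate)` keys are a hard
#' failure (`pass = FALSE`); unbalance such as a genotype absent from one
#' replicate is reported as a warning entry because the mixed model tolerates
#' it.
#'
#' @param records plot records data frame.
#' @return An object of class `trial_validation`.
#' @export
validate_trial <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("genotype", "env", "replicate", "block")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("schema error: required column '", missing_cols[1], "' is missing")
  key <- paste(records$genotype, records$env, records$replicate, sep = "|")
  dup <- unique(key[duplicated(key)])
  envs <- sort(unique(records$env))
  per_rep <- aggregate(genotype ~ env + replicate, data = records,
                       FUN = function(g) length(unique(g)))
  names(per_rep)[3] <- "n_genotypes"
  blk_key <- paste(records$env, records$replicate, records$block, sep = "|")
  block_sizes <- table(table(blk_key))
  warnings <- character(0)
  n_geno <- length(unique(records$genotype))
  incomplete <- per_rep[per_rep$n_genotypes < n_geno, , drop = FALSE]
  if (nrow(incomplete))
    warnings <- c(warnings, paste0(
      "unbalanced: ", nrow(incomplete),
      " environment-replicate(s) miss at least one genotype"))
  miss <- if ("missing_phenotype" %in% names(records))
    sum(records$missing_phenotype)
  else sum(is.na(records$nupe) | is.na(records$nute))
  structure(list(n_environments = length(envs), environments = envs,
                 genotypes_per_env_rep = per_rep,
                 duplicate_keys = dup,
                 block_size_histogram = block_sizes,
                 n_missing_phenotype = miss,
                 warnings = warnings,
                 pass = length(dup) == 0L),
            class = "trial_validation")
}

#' @export
print.trial_validation <- function(x, ...) {
  cat("Trial validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  environments:", paste(x$environments, collapse = ", "), "\n")
  cat("  genotypes per env x replicate:\n")
  print(x$genotypes_per_env_rep, row.names = FALSE)
  cat("  block-size histogram:\n"); print(x$block_size_histogram)
  cat("  missing phenotypes:", x$n_missing_phenotype, "\n")
  if (length(x$duplicate_keys))
    cat("  duplicated (genotype, env, replicate) keys:",
        paste(head(x$duplicate_keys, 5), collapse = "; "), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
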