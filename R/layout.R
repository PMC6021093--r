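#' Describe the layout of a lattice-square trial
#'
#' A resolvable incomplete-block layout: in every environment each replicate
#' contains all genotypes once, partitioned into incomplete blocks.  The
#' default is the 8 x 8 lattice square with two replications per N level that
#' is typical for maize inbred-line evaluation: 64 genotypes, blocks of 8
#' plots, two environments (low and high nitrogen) and the two NUE component
#' traits.
#'
#' @param n_genotypes number of genotypes; must equal
#'   `block_size * n_blocks_per_replicate`.
#' @param n_replicates replicates per environment.
#' @param block_size plots per incomplete block.
#' @param n_blocks_per_replicate incomplete blocks per replicate.
#' @param environments ordered environment labels (N levels).
#' @param traits ordered trait labels.
#' @return An object of class `trial_layout`.
#' @examples
#' trial_layout()
#' @export
trial_layout <- function(n_genotypes = 64L, n_replicates = 2L,
                         block_size = 8L, n_blocks_per_replicate = 8L,
                         environments = c("LN", "HN"),
                         traits = c("NUpE", "NUtE")) {
  n_genotypes <- as.integer(n_genotypes)
  n_replicates <- as.integer(n_replicates)
  block_size <- as.integer(block_size)
  n_blocks_per_replicate <- as.integer(n_blocks_per_replicate)
  if (n_genotypes != block_size * n_blocks_per_replicate) {
    stop("invalid layout sizing: n_genotypes (", n_genotypes,
         ") must equal block_size * n_blocks_per_replicate (",
         block_size * n_blocks_per_replicate, ")")
  }
  if (n_replicates < 1L || block_size < 1L || n_blocks_per_replicate < 1L)
    stop("layout counts must be positive")
  if (anyDuplicated(environments) || anyDuplicated(traits))
    stop("environment and trait labels must be unique")
  structure(list(n_genotypes = n_genotypes, n_replicates = n_replicates,
                 block_size = block_size,
                 n_blocks_per_replicate = n_blocks_per_replicate,
                 environments = as.character(environments),
                 traits = as.character(traits)),
            class = "trial_layout")
}

#' @export
print.trial_layout <- function(x, ...) {
  cat("Lattice trial layout:", x$n_genotypes, "genotypes,",
      x$n_blocks_per_replicate, "blocks of", x$block_size, "plots,",
      x$n_replicates, "replicate(s) per environment\n")
  cat("  environments:", paste(x$environments, collapse = ", "), "\n")
  cat("  traits:      ", paste(x$traits, collapse = ", "), "\n")
  invisible(x)
}

#' Genotype labels for a layout
#' @noRd
genotype_labels <- function(n) sprintf("G%03d", seq_len(n))

#' Randomly assign genotypes to lattice plots
#'
#' Within each environment and replicate, the genotypes are randomly
#' partitioned into `n_blocks_per_replicate` incomplete blocks of
#' `block_size` plots.  Every genotype appears exactly once per replicate per
#' environment.  The randomization is a fresh random partition per replicate
#' rather than a combinatorially resolvable lattice-square construction; the
#' mixed model does not require resolvability.
#'
#' @param layout a [trial_layout()].
#' @param seed integer seed making the assignment reproducible.
#' @return A data frame with one row per plot and columns `plot`, `env`,
#'   `replicate`, `block`, `genotype`.
#' @examples
#' head(assign_lattice_layout(trial_layout(), seed = 1))
#' @export
assign_lattice_layout <- function(layout, seed = NULL) {
  stopifnot(inherits(layout, "trial_layout"))
  if (!is.null(seed)) set.seed(seed)
  gl <- genotype_labels(layout$n_genotypes)
  rows <- list()
  i <- 1L
  for (env in layout$environments) {
    for (r in seq_len(layout$n_replicates)) {
      perm <- sample(gl)
      rows[[i]] <- data.frame(
        env = env, replicate = r,
        block = rep(seq_len(layout$n_blocks_per_replicate),
                    each = layout$block_size),
        genotype = perm, stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  out <- do.call(rbind, rows)
  out <- data.frame(plot = seq_len(nrow(out)), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
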