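#' Posterior breeding values per genotype
#'
#' Posterior mean and 95% HPD interval of each genotype's effect for every
#' trait-by-environment combination (full model) or trait (null model), plus
#' the within-column ranking by descending posterior mean.  Rank ties are
#' broken by genotype label, so the table is deterministic.
#'
#' @param fit an [run_chain()] fit with retained genotype-effect draws.
#' @param prob HPD mass.
#' @return A data frame of class `breeding_value_table` with columns
#'   `genotype`, `trait`, `env` (`NA` for null-model fits), `post_mean`,
#'   `hpd_lower`, `hpd_upper`, `rank`.
#' @export
breeding_value_table <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "mtme_fit"))
  if (is.null(fit$u))
    stop("fit has no retained genotype-effect draws (keep_u = FALSE?)")
  labs <- colnames(fit$u)
  parts <- strsplit(labs, ":", fixed = TRUE)
  out <- data.frame(
    genotype = vapply(parts, `[`, character(1), 1),
    trait = vapply(parts, `[`, character(1), 2),
    env = if (fit$model_kind == "full")
      vapply(parts, `[`, character(1), 3) else NA_character_,
    post_mean = colMeans(fit$u), stringsAsFactors = FALSE)
  hp <- t(apply(fit$u, 2, hpd_interval, prob = prob))
  out$hpd_lower <- hp[, "lower"]
  out$hpd_upper <- hp[, "upper"]
  grp <- paste(out$trait, out$env)
  out$rank <- NA_integer_
  for (g in unique(grp)) {
    i <- which(grp == g)
    o <- i[order(-out$post_mean[i], out$genotype[i])]
    out$rank[o] <- seq_along(o)
  }
  rownames(out) <- NULL
  class(out) <- c("breeding_value_table", "data.frame")
  out
}

#' Top-k genotypes for one trait and environment
#'
#' @param table a [breeding_value_table()].
#' @param trait trait label.
#' @param env environment label (omit/`NA` for null-model tables).
#' @param k list length (`0 <= k <=` number of genotypes).
#' @return Character vector of the k genotype labels, best first.
#' @export
rank_top_k <- function(table, trait, env = NA, k = 10) {
  stopifnot(inherits(table, "breeding_value_table") || is.data.frame(table))
  sel <- table$trait == trait &
    (if (is.na(env)) is.na(table$env) else !is.na(table$env) & table$env == env)
  sub <- table[sel, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no breeding values for trait '", trait, "' and env '", env, "'")
  if (k > nrow(sub)) stop("k (", k, ") exceeds the number of genotypes (",
                          nrow(sub), ")")
  if (k < 0) stop("k must be non-negative")
  sub$genotype[order(sub$rank)][seq_len(k)]
}

#' Coincidence percentage of two top-k lists
#'
#' `100 |A intersect B| / k`, ignoring order.  Symmetric, in `[0, 100]`, and
#' equal to 100 exactly when the two sets coincide.
#'
#' @param list_a,list_b equal-length character vectors of unique labels.
#' @return Percentage (scalar).
#' @examples
#' coincidence_percentage(c("a", "b"), c("b", "c")) # 50
#' @export
coincidence_percentage <- function(list_a, list_b) {
  if (length(list_a) != length(list_b))
    stop("lists must have equal length")
  if (anyDuplicated(list_a) || anyDuplicated(list_b))
    stop("lists must not contain duplicate labels")
  if (length(list_a) == 0) return(100)
  100 * length(intersect(list_a, list_b)) / length(list_a)
}

#' Compare full and null models by DIC
#'
#' `delta = DIC(null) - DIC(full)`; the full (interaction) model is
#' preferred when `delta > 0`, the null model otherwise (a tie prefers the
#' more parsimonious null model).  Both DIC values must come from the same
#' data and the same deviance convention.
#'
#' @param dic_full,dic_null results of [compute_dic()] (or bare numbers).
#' @return List with `delta` and `preferred` (`"full"` or `"null"`).
#' @export
compare_models <- function(dic_full, dic_null) {
  v <- function(x) if (is.list(x)) x$DIC else as.numeric(x)
  delta <- v(dic_null) - v(dic_full)
  list(delta = delta, preferred = if (delta > 0) "full" else "null")
}
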