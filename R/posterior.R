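#' Per-draw broad-sense heritability
#'
#' Plug-in per-plot heritability per retained draw,
#' `h2 = sigma_g2 / (sigma_g2 + sigma_r2 + sigma_b2 + sigma_e2)`, using each
#' draw's own variance components for the requested trait-by-environment
#' combination.  Draws lie in `[0, 1]` by construction and are invariant to
#' rescaling the trait.
#'
#' @param fit an [run_chain()] fit containing all four variance structures.
#' @param trait,env labels.
#' @return Numeric vector of h2 draws.
#' @export
heritability_draws <- function(fit, trait, env) {
  stopifnot(inherits(fit, "mtme_fit"))
  need <- c("genotype", "replicate", "block")
  if (!all(need %in% fit$terms))
    stop("heritability needs genotype, replicate and block variance draws")
  sg2 <- variance_component_draws(fit, "genetic", trait, env)
  sr2 <- variance_component_draws(fit, "replicate", trait, env)
  sb2 <- variance_component_draws(fit, "block", trait, env)
  se2 <- variance_component_draws(fit, "residual", trait, env)
  sg2 / (sg2 + sr2 + sb2 + se2)
}

#' Per-draw genetic correlation between the two traits in one environment
#'
#' `r = sigma_g(1,2) / sqrt(sigma_g2(1) sigma_g2(2))` using each draw's
#' cells of the genetic covariance matrix for the given environment (under
#' the null model the correlation is shared across environments).  Draws
#' with a zero variance yield `NA` and their count is reported via the
#' `n_dropped` attribute.
#'
#' @param fit a two-trait [run_chain()] fit.
#' @param env environment label.
#' @return Numeric vector of correlation draws (attribute `n_dropped`).
#' @export
genetic_correlation_draws <- function(fit, env) {
  stopifnot(inherits(fit, "mtme_fit"))
  if (length(fit$traits) != 2)
    stop("genetic correlations need a two-trait fit")
  if (is.null(fit$Sigma_u)) stop("fit has no genotype effects")
  e <- match(env, fit$environments)
  if (is.na(e)) stop("unknown environment label: ", env)
  E <- length(fit$environments)
  idx <- if (fit$model_kind == "full") c(e, E + e) else c(1L, 2L)
  v1 <- fit$Sigma_u[idx[1], idx[1], ]
  v2 <- fit$Sigma_u[idx[2], idx[2], ]
  cv <- fit$Sigma_u[idx[1], idx[2], ]
  ok <- v1 > 0 & v2 > 0
  r <- ifelse(ok, cv / sqrt(v1 * v2), NA_real_)
  attr(r, "n_dropped") <- sum(!ok)
  r
}

#' Highest posterior density interval
#'
#' Shortest empirical interval containing the requested posterior mass
#' (the Chen-Shao construction over the sorted draws, via
#' [coda::HPDinterval()]); assumes a unimodal posterior.  A degenerate
#' all-equal draw vector gives a zero-width interval.
#'
#' @param draws numeric vector of at least 2 finite draws.
#' @param prob interval mass.
#' @return Numeric `c(lower, upper)`.
#' @examples
#' hpd_interval(rnorm(1e5)) # about (-1.96, 1.96)
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 2) stop("need at least 2 finite draws")
  h <- coda::HPDinterval(coda::as.mcmc(as.numeric(draws)), prob = prob)
  c(lower = h[1, "lower"], upper = h[1, "upper"])
}

#' Posterior mode by kernel density estimation
#'
#' The mode of a Gaussian-kernel density estimate (bandwidth by the normal
#' reference rule, `bw.nrd`) evaluated on a fixed 512-point grid spanning
#' the draw range.  Because the KDE is nearly flat around its maximum, the
#' raw grid argmax is noisy; the estimate is refined by fitting a parabola
#' to the contiguous peak neighbourhood (grid points within 2% of the
#' maximum density) and taking its vertex.  With fewer than 30 draws the
#' median is returned with a warning.
#'
#' @param draws numeric vector.
#' @return The estimated mode (scalar).
#' @export
posterior_mode <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0) stop("no finite draws")
  if (length(unique(draws)) == 1) return(draws[1])
  if (length(draws) < 30) {
    warning("fewer than 30 draws; returning the median instead of a KDE mode")
    return(median(draws))
  }
  d <- density(draws, bw = "nrd", n = 512, from = min(draws),
               to = max(draws))
  i0 <- which.max(d$y)
  ym <- d$y[i0]
  lo <- i0; while (lo > 1 && d$y[lo - 1] >= 0.98 * ym) lo <- lo - 1
  hi <- i0; while (hi < 512 && d$y[hi + 1] >= 0.98 * ym) hi <- hi + 1
  idx <- lo:hi
  if (length(idx) < 5) return(d$x[i0])
  b <- coef(stats::lm(d$y[idx] ~ stats::poly(d$x[idx], 2, raw = TRUE)))
  if (!is.finite(b[3]) || b[3] >= 0) return(d$x[i0])
  m <- -b[2] / (2 * b[3])
  if (m < d$x[min(idx)] || m > d$x[max(idx)]) d$x[i0] else unname(m)
}

#' Coefficients of variation and the relative variation index
#'
#' `CVg = 100 sqrt(posterior-mean genetic variance) / mean` and
#' `CVe = 100 sqrt(posterior-mean residual variance) / mean`, scaled by the
#' observed phenotypic mean of the combination; the relative variation index
#' `CVg/CVe > 1` indicates that genetic signal dominates plot noise.
#'
#' @param fit an [run_chain()] fit.
#' @param trait,env labels.
#' @param observed_mean positive phenotypic mean used as the scale.
#' @return List with `cve`, `cvg` (both percent) and `index` (CVg/CVe).
#' @export
variation_coefficients <- function(fit, trait, env, observed_mean) {
  if (!is.finite(observed_mean) || observed_mean <= 0)
    stop("observed_mean must be positive")
  sg2 <- mean(variance_component_draws(fit, "genetic", trait, env))
  se2 <- mean(variance_component_draws(fit, "residual", trait, env))
  cvg <- 100 * sqrt(sg2) / observed_mean
  cve <- 100 * sqrt(se2) / observed_mean
  list(cve = cve, cvg = cvg, index = cvg / cve)
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of the first `frac_first` and last `frac_last`
#' portions of a chain, with variances estimated from the spectral density
#' at frequency zero (via [coda::geweke.diag()], the diagnostic of the CODA
#' package).  `|z| < 1.96` is read as consistent with convergence.
#'
#' @param draws numeric draw sequence.
#' @param frac_first,frac_last window fractions.
#' @return The z score (scalar).
#' @export
geweke_diagnostic <- function(draws, frac_first = 0.1, frac_last = 0.5) {
  draws <- as.numeric(draws)
  n1 <- floor(frac_first * length(draws))
  n2 <- floor(frac_last * length(draws))
  if (n1 < 50 || n2 < 50)
    stop("need at least 50 draws in each Geweke window")
  if (var(draws[seq_len(n1)]) == 0 ||
      var(draws[seq.int(length(draws) - n2 + 1, length(draws))]) == 0)
    stop("zero-variance Geweke window")
  z <- coda::geweke.diag(coda::as.mcmc(draws), frac1 = frac_first,
                         frac2 = frac_last)$z
  unname(z)
}

#' Posterior genetic-parameter summary
#'
#' Assembles, per trait-by-environment combination: the posterior mean of
#' the systematic mean, genetic variance summaries, heritability mode / mean
#' / median with 95% HPD, the CV indices, and (for two-trait fits) the
#' genetic correlation summaries per environment.  Convergence of every
#' variance-component draw sequence is screened with the Geweke diagnostic
#' and a warning is raised when any |z| exceeds 1.96.
#'
#' @param fit an [run_chain()] fit with all variance structures.
#' @param records optional plot records; when supplied the CV scale is the
#'   observed phenotypic mean per combination, otherwise the posterior mean
#'   of the systematic mean is used.
#' @param geweke_check screen variance components with the Geweke z score.
#' @return A list of class `genetic_summary` with data frames `trait_env`
#'   and (two-trait fits) `correlations`.
#' @export
summarize_genetics <- function(fit, records = NULL, geweke_check = TRUE) {
  stopifnot(inherits(fit, "mtme_fit"))
  combos <- expand.grid(env = fit$environments, trait = fit$traits,
                        stringsAsFactors = FALSE)[, c("trait", "env")]
  if (geweke_check) {
    zs <- unlist(lapply(seq_len(nrow(combos)), function(i) {
      vapply(c("genetic", "replicate", "block", "residual"), function(s)
        tryCatch(geweke_diagnostic(variance_component_draws(
          fit, s, combos$trait[i], combos$env[i])), error = function(e) NA_real_),
        numeric(1))
    }))
    if (any(abs(zs) > 1.96, na.rm = TRUE))
      warning(sum(abs(zs) > 1.96, na.rm = TRUE),
              " variance-component chain(s) fail the Geweke criterion ",
              "(|z| > 1.96); summaries may be unreliable")
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    tr <- combos$trait[i]; en <- combos$env[i]
    ci <- (match(tr, fit$traits) - 1L) * length(fit$environments) +
      match(en, fit$environments)
    beta_d <- fit$beta[, ci]
    sg2 <- variance_component_draws(fit, "genetic", tr, en)
    h2 <- heritability_draws(fit, tr, en)
    hh <- hpd_interval(h2)
    obs_mean <- if (!is.null(records)) {
      mean(records[[trait_column(tr)]][records$env == en], na.rm = TRUE)
    } else mean(beta_d)
    cv <- variation_coefficients(fit, tr, en, obs_mean)
    data.frame(trait = tr, env = en, mean = mean(beta_d),
               sigma_g2 = mean(sg2),
               h2_mode = posterior_mode(h2), h2_mean = mean(h2),
               h2_median = median(h2),
               h2_hpd_lower = hh["lower"], h2_hpd_upper = hh["upper"],
               cve = cv$cve, cvg = cv$cvg, cvg_cve = cv$index,
               stringsAsFactors = FALSE)
  })
  out <- list(trait_env = do.call(rbind, rows))
  rownames(out$trait_env) <- NULL
  if (length(fit$traits) == 2) {
    cors <- lapply(fit$environments, function(en) {
      r <- genetic_correlation_draws(fit, en)
      rr <- r[is.finite(r)]
      hh <- hpd_interval(rr)
      data.frame(pair = paste(fit$traits, collapse = "x"), env = en,
                 mode = posterior_mode(rr), mean = mean(rr),
                 median = median(rr),
                 hpd_lower = hh["lower"], hpd_upper = hh["upper"],
                 stringsAsFactors = FALSE)
    })
    out$correlations <- do.call(rbind, cors)
    rownames(out$correlations) <- NULL
  }
  structure(out, class = "genetic_summary")
}

#' @export
print.genetic_summary <- function(x, ...) {
  cat("Posterior genetic parameters per trait x environment:\n")
  df <- x$trait_env
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  if (!is.null(x$correlations)) {
    cat("Genetic correlations between traits:\n")
    dc <- x$correlations
    num <- vapply(dc, is.numeric, logical(1))
    dc[num] <- lapply(dc[num], round, 3)
    print(dc, row.names = FALSE)
  }
  invisible(x)
}
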