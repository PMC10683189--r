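## End-to-end sweeps (cohort -> association -> convergence) and the trend
## statistics relating the convergence signature to sample size,
## polygenicity and selection.

#' Effective sample size of a trait
#'
#' Quantitative traits: the sample size itself. Binary traits: the
#' power-equivalent harmonic-mean expression
#' `4 / (1/n_cases + 1/n_controls)`.
#'
#' @param type `"quantitative"` or `"binary"`.
#' @param n Total sample size (quantitative).
#' @param n_cases,n_controls Case/control counts (binary).
#' @return Effective sample size.
#' @examples
#' effective_sample_size("binary", n_cases = 500, n_controls = 1500)  # 1500
#' @export
effective_sample_size <- function(type = c("quantitative", "binary"),
                                  n = NULL, n_cases = NULL,
                                  n_controls = NULL) {
  type <- match.arg(type)
  if (type == "quantitative") {
    if (is.null(n) || n <= 0) stopf("`n` must be positive")
    return(as.numeric(n))
  }
  if (is.null(n_cases) || is.null(n_controls) ||
      n_cases <= 0 || n_controls <= 0)
    stopf("binary traits need positive n_cases and n_controls")
  4 / (1 / n_cases + 1 / n_controls)
}

## One replicate of the full pipeline; returns a one-row record.
run_replicate <- function(params, n_individuals, k, seed, decorrelate,
                          genome = list()) {
  rec <- data.frame(seed = seed, n_eff = n_individuals,
                    alpha = params$alpha, r = params$r, mode = params$mode,
                    prop_causal_genes = params$prop_causal_genes,
                    shared_causal_fraction = params$shared_causal_fraction,
                    h2 = params$h2_trait, decorrelated = decorrelate,
                    kappa = NA_real_, ac1 = NA_real_,
                    a = NA_integer_, n_clumped = NA_integer_,
                    failure = NA_character_, stringsAsFactors = FALSE)
  out <- tryCatch({
    co <- do.call(simulate_cohort,
                  c(list(params = params, n_individuals = n_individuals,
                         seed = seed, decorrelate = decorrelate), genome))
    genes <- gene_assoc_table(co$panel, co$phenotype)
    genes <- genes[!is.na(genes$p_common) & !is.na(genes$p_rare), ]
    fit <- corac(genes, k = k)
    rec$kappa <- fit$kappa
    rec$ac1 <- fit$ac1
    rec$a <- fit$table$a
    rec$n_clumped <- fit$n
    rec
  }, error = function(e) {
    rec$failure <- conditionMessage(e)
    rec
  })
  out
}

#' Sweep the convergence signature over effective sample size
#'
#' For every sample size in `n_grid` and every replicate, simulates a
#' cohort under `params`, runs the common- and rare-variant gene tests,
#' clumps, and records kappa and AC1. All stages are seeded
#' deterministically from `(seed, n_eff, replicate)`; per-replicate
#' failures are recorded in the `failure` column and the sweep continues.
#'
#' @param n_grid Vector of cohort sizes.
#' @param n_seeds Replicates per grid point.
#' @param params An [architecture_params()] object.
#' @param k Top-gene cutoff for the concordance table.
#' @param decorrelate Shuffle rare genotypes in every replicate.
#' @param genome Named list of genome settings passed to
#'   [simulate_cohort()] (`n_blocks`, `genes_per_block`, ...). A full-scale
#'   configuration is accepted; expect runtime to grow with
#'   `n * n_variants`.
#' @param seed Master seed.
#' @return A data frame with one record per (n, replicate).
#' @export
run_convergence_sweep <- function(n_grid = c(500, 1000, 2000, 4000),
                                  n_seeds = 20,
                                  params = architecture_params(),
                                  k = 15, decorrelate = FALSE,
                                  genome = list(), seed = 1) {
  n_seeds <- check_count(n_seeds, "n_seeds")
  if (prod(max(n_grid), n_seeds) > 4000 * 100)
    warnf("large sweep configuration; this may take a long time")
  rows <- list()
  for (nn in n_grid) {
    for (s in seq_len(n_seeds)) {
      rows[[length(rows) + 1L]] <-
        run_replicate(params, nn, k, child_seed(seed, nn, s), decorrelate,
                      genome)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the convergence signature over polygenicity
#'
#' As [run_convergence_sweep()] with the proportion of causal genes on a
#' grid at fixed cohort size.
#'
#' @param prop_grid Grid of causal-gene proportions.
#' @param n_individuals Fixed cohort size.
#' @inheritParams run_convergence_sweep
#' @return A data frame with one record per (proportion, replicate).
#' @export
run_polygenicity_sweep <- function(prop_grid = c(0.05, 0.10, 0.20),
                                   n_individuals = 4000, n_seeds = 20,
                                   params = architecture_params(),
                                   k = 15, genome = list(), seed = 1) {
  n_seeds <- check_count(n_seeds, "n_seeds")
  rows <- list()
  for (pp in prop_grid) {
    pars <- params
    pars$prop_causal_genes <- check_fraction(pp, "prop_causal_genes",
                                             open_lo = TRUE)
    for (s in seq_len(n_seeds)) {
      rows[[length(rows) + 1L]] <-
        run_replicate(pars, n_individuals, k,
                      child_seed(seed, round(1e4 * pp), s), FALSE, genome)
    }
  }
  do.call(rbind, rows)
}

#' Trend statistics between the convergence signature and a driver
#'
#' Spearman and Kendall rank correlations (with partial versions given a
#' covariate: partial Kendall through the standard tau identity, partial
#' Spearman through rank-residual correlation), and a generalized
#' least-squares fit of `y` on `x` with `Var(e_i) ~ x_i^(2 theta)`, the
#' variance exponent `theta` chosen on a grid by maximizing the Gaussian
#' profile likelihood (ties broken toward the smallest `|theta|`).
#'
#' @param x Driver values (positive where the GLS weights are used).
#' @param y Convergence estimates.
#' @param covariate Optional adjustment variable for the partial
#'   correlations.
#' @param theta_grid Grid for the GLS variance exponent.
#' @return An object of class `corac_trend`.
#' @export
trend_analysis <- function(x, y, covariate = NULL,
                           theta_grid = seq(-2, 2, by = 0.05)) {
  ok <- stats::complete.cases(x, y)
  if (!is.null(covariate)) ok <- ok & !is.na(covariate)
  x <- x[ok]; y <- y[ok]
  if (!is.null(covariate)) covariate <- covariate[ok]
  if (length(x) < 5L) stopf("need at least 5 paired observations")

  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  kd <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))

  partial_kendall <- partial_spearman <- NA_real_
  if (!is.null(covariate)) {
    txy <- kd$estimate
    txz <- suppressWarnings(stats::cor(x, covariate, method = "kendall"))
    tyz <- suppressWarnings(stats::cor(y, covariate, method = "kendall"))
    if (abs(txz) >= 1 || abs(tyz) >= 1)
      stopf("partial Kendall undefined: covariate is a monotone copy")
    partial_kendall <- (txy - txz * tyz) /
      sqrt((1 - txz^2) * (1 - tyz^2))
    rx <- stats::resid(stats::lm(rank(x) ~ rank(covariate)))
    ry <- stats::resid(stats::lm(rank(y) ~ rank(covariate)))
    partial_spearman <- stats::cor(rx, ry)
  }

  ## GLS with power-of-x variance; Gaussian profile likelihood over theta
  gls <- NULL
  if (all(x > 0)) {
    n <- length(x)
    prof <- vapply(theta_grid, function(th) {
      w <- x^(-2 * th)
      fit <- stats::lm.wfit(cbind(1, x), y, w)
      s2 <- sum(w * fit$residuals^2) / n
      -0.5 * (n * log(s2) + 2 * th * sum(log(x)) + n)
    }, numeric(1))
    best <- prof == max(prof)
    theta <- theta_grid[best][which.min(abs(theta_grid[best]))]
    w <- x^(-2 * theta)
    fit <- stats::lm(y ~ x, weights = w)
    sm <- summary(fit)
    gls <- list(theta = theta, slope = sm$coefficients["x", "Estimate"],
                se = sm$coefficients["x", "Std. Error"],
                p = sm$coefficients["x", "Pr(>|t|)"],
                profile = data.frame(theta = theta_grid, loglik = prof))
  }

  structure(list(spearman = list(rho = unname(sp$estimate), p = sp$p.value),
                 kendall = list(tau = unname(kd$estimate), p = kd$p.value),
                 partial_kendall = unname(partial_kendall),
                 partial_spearman = unname(partial_spearman),
                 gls = gls, n = length(x)),
            class = "corac_trend")
}

#' @export
print.corac_trend <- function(x, digits = 4, ...) {
  cat(sprintf("Trend over %d observations:\n", x$n))
  cat(sprintf("  Spearman rho = %.*f (p = %.3g)\n", digits,
              x$spearman$rho, x$spearman$p))
  cat(sprintf("  Kendall tau  = %.*f (p = %.3g)\n", digits,
              x$kendall$tau, x$kendall$p))
  if (!is.na(x$partial_kendall))
    cat(sprintf("  partial Kendall = %.*f, partial Spearman = %.*f\n",
                digits, x$partial_kendall, digits, x$partial_spearman))
  if (!is.null(x$gls))
    cat(sprintf("  GLS: slope = %.*g (p = %.3g), variance exponent theta = %.2f\n",
                digits, x$gls$slope, x$gls$p, x$gls$theta))
  invisible(x)
}
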