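## Profile-likelihood estimation of the selection exponent alpha from
## variant-level summary statistics: each marginal effect estimate (per
## genotype-SD) is modelled as Normal(0, C [p(1-p)]^(1+alpha) (1/(1+l))^r
## + se^2), variants treated as independent given their LD scores; C is
## profiled out by an inner one-dimensional maximization at each alpha.

#' Estimate the selection exponent from summary statistics
#'
#' @param stats Data frame with columns `beta_hat`, `se`, `maf` and (when
#'   `r = 1`) `ld_score`; one row per causal variant.
#' @param r LD exponent of the effect-size model, 0 or 1.
#' @param alpha_grid Grid of alpha values to profile over (default
#'   `seq(-1.5, 1, by = 0.01)`); the grid maximizer is refined by local
#'   continuous search.
#' @return An object of class `alpha_fit`: `alpha_hat`, `C_hat`, `logLik`,
#'   `converged`, and the profile curve (`alpha`, `loglik`, `C`).
#' @export
fit_alpha <- function(stats, r = 0, alpha_grid = seq(-1.5, 1, by = 0.01)) {
  if (!is.data.frame(stats) ||
      !all(c("beta_hat", "se", "maf") %in% names(stats)))
    stopf("`stats` needs columns beta_hat, se, maf")
  if (!r %in% c(0, 1)) stopf("`r` must be 0 or 1")
  b <- stats$beta_hat; se <- stats$se; p <- stats$maf
  if (any(se <= 0)) stopf("standard errors must be positive")
  if (any(p <= 0 | p > 0.5)) stopf("maf must lie in (0, 0.5]")
  m <- length(b)
  if (m < 100L) stopf("need at least 100 variants")
  het <- p * (1 - p)
  if (max(het) / min(het) < 2)
    stopf("non-identifiable: insufficient allele-frequency spread")
  ldfac <- if (r == 1) {
    if (!"ld_score" %in% names(stats) || anyNA(stats$ld_score))
      stopf("`ld_score` required when r = 1")
    1 / (1 + stats$ld_score)
  } else rep(1, m)

  b2 <- b^2; se2 <- se^2
  loglik_at <- function(alpha, want_C = FALSE) {
    v <- het^(1 + alpha) * ldfac
    ll_of_logC <- function(logC) {
      tot <- exp(logC) * v + se2
      -0.5 * sum(log(tot) + b2 / tot)
    }
    ## bracket C around the scale implied by the data
    c0 <- max(mean(pmax(b2 - se2, 0)) / mean(v), 1e-12)
    opt <- stats::optimize(ll_of_logC, log(c0) + c(-14, 8), maximum = TRUE,
                           tol = 1e-6)
    ## allow the boundary C -> 0 (pure-noise fit)
    ll0 <- -0.5 * sum(log(se2) + b2 / se2)
    if (ll0 > opt$objective) {
      if (want_C) c(ll0, 0) else ll0
    } else {
      if (want_C) c(opt$objective, exp(opt$maximum)) else opt$objective
    }
  }

  prof <- vapply(alpha_grid, loglik_at, numeric(1))
  if (max(prof) - min(prof) < 1e-6)
    stopf("non-identifiable: flat profile likelihood over the alpha grid")
  i <- which.max(prof)
  lo <- alpha_grid[max(1L, i - 1L)]
  hi <- alpha_grid[min(length(alpha_grid), i + 1L)]
  ref <- stats::optimize(function(a) loglik_at(a), c(lo, hi),
                         maximum = TRUE, tol = 1e-5)
  best <- if (ref$objective >= prof[i]) {
    list(alpha = ref$maximum, ll = ref$objective)
  } else list(alpha = alpha_grid[i], ll = prof[i])
  fin <- loglik_at(best$alpha, want_C = TRUE)
  structure(list(alpha_hat = best$alpha, C_hat = fin[2], logLik = fin[1],
                 converged = TRUE, r = r,
                 profile = data.frame(alpha = alpha_grid, loglik = prof),
                 n_variants = m),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Selection exponent fit (%d variants, r = %g):\n  alpha_hat = %.*f,  C_hat = %.*g,  logLik = %.2f\n",
    x$n_variants, x$r, digits, x$alpha_hat, digits, x$C_hat, x$logLik))
  invisible(x)
}

#' @export
coef.alpha_fit <- function(object, ...) {
  c(alpha = object$alpha_hat, C = object$C_hat)
}

#' @export
logLik.alpha_fit <- function(object, ...) {
  structure(object$logLik, df = 2, class = "logLik")
}

#' @export
plot.alpha_fit <- function(x, ...) {
  plot(x$profile$alpha, x$profile$loglik, type = "l", lwd = 2,
       xlab = expression(alpha), ylab = "profile log-likelihood",
       main = "Selection exponent profile", ...)
  abline(v = x$alpha_hat, lty = 2, col = "firebrick")
  invisible(x)
}

#' Simulate summary statistics from the selection effect-size model
#'
#' Generates causal-variant marginal summary statistics directly from the
#' model [fit_alpha()] assumes: true effects
#' `beta ~ N(0, C [p(1-p)]^(1+alpha) (1/(1+l))^r)` and estimates
#' `beta_hat ~ N(beta, 1/N)` (per-SD effects, so the sampling standard
#' error is `1/sqrt(N)`). The variance scale `C` is set so the mean
#' per-variant association noncentrality (`N * C * v`) equals `mean_ncp`,
#' which keeps the information content of the statistics at the level of the
#' large-biobank studies selection inference is run on even when `n` is
#' scaled down to desk size.
#'
#' @param m Number of causal variants.
#' @param n Sample size behind each estimate.
#' @param alpha True selection exponent.
#' @param r LD exponent (0 or 1).
#' @param mean_ncp Mean per-variant noncentrality of the true effects
#'   (mean chi-square minus 1); 20 emulates well-powered biobank input.
#' @param maf_range Range the MAFs are drawn uniformly from.
#' @param seed Integer seed.
#' @return A data frame usable as [fit_alpha()] input, with attributes
#'   `alpha`, `C`.
#' @export
simulate_summary_stats <- function(m = 5000, n = 5000, alpha = -0.37, r = 0,
                                   mean_ncp = 20, maf_range = c(0.001, 0.5),
                                   seed = 1) {
  m <- check_count(m, "m"); n <- check_count(n, "n")
  with_seed(seed, {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    ld <- 1 + stats::rexp(m, 1 / 9)       # LD scores >= 1, mean 10
    shape <- (maf * (1 - maf))^(1 + alpha) *
      if (r == 1) (1 / (1 + ld))^r else 1
    C <- mean_ncp / (n * mean(shape))
    v <- C * shape
    beta <- stats::rnorm(m, 0, sqrt(v))
    se <- rep(1 / sqrt(n), m)
    bh <- stats::rnorm(m, beta, se)
    structure(data.frame(variant_id = sprintf("s%06d", seq_len(m)),
                         beta_hat = bh, se = se, maf = maf, ld_score = ld,
                         n = n, stringsAsFactors = FALSE),
              alpha = alpha, C = C)
  })
}
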