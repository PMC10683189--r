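## Bayesian inference for the concordance probabilities. The 2x2 counts are
## multinomial in (p11, p10, p01, p00); the model is parameterized by the two
## margins p1. (top-ranked under the common signal), p.1 (top-ranked under the
## rare signal) and the joint probability p11, so the likelihood is
##   L ~ p11^a (p1.-p11)^b (p.1-p11)^c (1-p1.-p.1+p11)^d.
## Beta priors on the margins; p11 uniform on its feasible (Frechet) range
## [max(0, p1.+p.1-1), min(p1., p.1)] conditional on the margins.

#' Prior for the Bayesian agreement model
#'
#' Beta priors on the two margin probabilities (`p1. ~ Beta(u s, u (1-s))`,
#' `p.1 ~ Beta(v t, v (1-t))`, so `s` and `t` are the prior means and `u`,
#' `v` the concentrations) and a conditional uniform prior on `p11` over its
#' feasible range given the margins.
#'
#' @param s,t Prior means of the margins, in (0, 1).
#' @param u,v Prior concentrations, > 0.
#' @return An object of class `corac_prior`.
#' @export
corac_prior <- function(s = 0.1, t = 0.1, u = 2, v = 2) {
  s <- check_fraction(s, "s", open_lo = TRUE, open_hi = TRUE)
  t <- check_fraction(t, "t", open_lo = TRUE, open_hi = TRUE)
  if (u <= 0 || v <= 0) stopf("prior concentrations u, v must be > 0")
  structure(list(s = s, t = t, u = u, v = v), class = "corac_prior")
}

## kappa as a function of the three model probabilities
kappa_from_probs <- function(p1, p2, p11) {
  p_alpha <- 1 - p1 - p2 + 2 * p11
  p_eps <- p1 * p2 + (1 - p1) * (1 - p2)
  (p_alpha - p_eps) / (1 - p_eps)
}

#' Grid posterior for the agreement probabilities and kappa
#'
#' Evaluates the posterior of `(p1., p.1, p11)` on a three-dimensional grid
#' restricted to the feasible region of `p11`, in log space with a global
#' max-shift against underflow, normalized by the trapezoid rule, and reports
#' posterior means and equal-tailed credible intervals for `p11` and for
#' kappa (computed pointwise from the three probabilities).
#'
#' With no data (`a = b = c = d = 0`) the posterior equals the prior, so the
#' posterior mean of each margin reproduces the prior mean up to grid error.
#' For large tables the posterior mean of kappa approaches the plug-in
#' estimate from [cohen_kappa()].
#'
#' @param table A [concordance_table()] or numeric `c(a, b, c, d)`; all-zero
#'   counts are allowed and return the prior.
#' @param prior A [corac_prior()]. Default: margins centred at the observed
#'   margin proportions with weak concentration 2.
#' @param grid Number of grid points per dimension (default 101).
#' @param conf_level Credible level.
#' @return An object of class `corac_posterior` with posterior means and
#'   credible intervals for `p11` and kappa, and posterior margin means.
#' @export
posterior_corac <- function(table, prior = NULL, grid = 101,
                            conf_level = 0.95) {
  if (is.numeric(table) && length(table) == 4L && sum(table) == 0) {
    tab <- list(a = 0L, b = 0L, c = 0L, d = 0L, n = 0L)
  } else {
    tab <- as_concordance_table(table)
  }
  grid <- check_count(grid, "grid", min = 11L)
  if (is.null(prior)) {
    if (tab$n > 0) {
      s0 <- min(max((tab$a + tab$b) / tab$n, 1 / (tab$n + 2)), 1 - 1e-6)
      t0 <- min(max((tab$a + tab$c) / tab$n, 1 / (tab$n + 2)), 1 - 1e-6)
    } else s0 <- t0 <- 0.5
    prior <- corac_prior(s = s0, t = t0)
  }
  if (!inherits(prior, "corac_prior")) stopf("`prior` must be a corac_prior")

  g <- grid
  ## open grid on (0,1) for the margins; unit grid along the p11 segment
  pg <- seq(1 / (g + 1), g / (g + 1), length.out = g)
  u11 <- seq(0, 1, length.out = g)
  trap <- function(x) c(diff(x) / 2, 0) + c(0, diff(x) / 2)
  wg <- trap(pg)
  wu <- trap(u11)

  lbeta1 <- stats::dbeta(pg, prior$u * prior$s, prior$u * (1 - prior$s),
                         log = TRUE)
  lbeta2 <- stats::dbeta(pg, prior$v * prior$t, prior$v * (1 - prior$t),
                         log = TRUE)

  ## margin planes, replicated into the 3rd (p11) dimension
  P1 <- array(rep(pg, times = g * g), c(g, g, g))
  P2 <- array(rep(rep(pg, each = g), times = g), c(g, g, g))
  LO <- pmax(0, P1 + P2 - 1)
  HI <- pmin(P1, P2)
  LEN <- HI - LO
  U <- array(rep(u11, each = g * g), c(g, g, g))
  P11 <- LO + LEN * U

  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  P10 <- P1 - P11
  P01 <- P2 - P11
  P00 <- 1 - P1 - P2 + P11
  xlog <- function(cnt, p) if (cnt == 0) 0 else cnt * log(pmax(p, 0))
  ll <- xlog(a, P11) + xlog(b, P10) + xlog(cc, P01) + xlog(d, P00)

  LP <- array(rep(lbeta1, times = g * g), c(g, g, g)) +
    array(rep(rep(lbeta2, each = g), times = g), c(g, g, g)) -
    log(LEN)  # conditional-uniform density 1/len on the segment
  lw <- ll + LP

  ## trapezoid volume element: dp1 dp2 dp11 with dp11 = len * du
  W <- array(rep(wg, times = g * g), c(g, g, g)) *
    array(rep(rep(wg, each = g), times = g), c(g, g, g)) *
    array(rep(wu, each = g * g), c(g, g, g)) * LEN

  feas <- is.finite(lw) & LEN > 0 & W > 0
  if (!any(feas)) stopf("posterior has no feasible support on the grid")
  m <- max(lw[feas])
  mass <- numeric(length(lw))
  mass[feas] <- exp(lw[feas] - m) * W[feas]
  Z <- sum(mass)
  if (!is.finite(Z) || Z <= 0)
    stopf("posterior normalization failed (zero or non-finite mass)")
  w <- mass / Z

  kap <- kappa_from_probs(P1, P2, P11)
  keep <- w > 0
  wk <- w[keep]
  wquant <- function(x, probs) {
    ord <- order(x)
    cw <- cumsum(wk[ord])
    stats::approx(cw, x[ord], xout = probs, rule = 2, ties = "ordered")$y
  }
  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  p11k <- P11[keep]
  kapk <- kap[keep]

  structure(list(
    mean_p11 = sum(p11k * wk),
    ci_p11 = wquant(p11k, qs),
    mean_kappa = sum(kapk * wk),
    ci_kappa = wquant(kapk, qs),
    mean_p1 = sum(P1[keep] * wk),
    mean_p2 = sum(P2[keep] * wk),
    table = tab, prior = prior, grid = g, conf_level = conf_level),
    class = "corac_posterior")
}

#' @export
print.corac_posterior <- function(x, digits = 4, ...) {
  cat("Posterior for the concordance probabilities\n")
  cat(sprintf("  E[p11 | data]   = %.*f  CI [%.*f, %.*f]\n", digits, x$mean_p11,
              digits, x$ci_p11[1], digits, x$ci_p11[2]))
  cat(sprintf("  E[kappa | data] = %.*f  CI [%.*f, %.*f]\n", digits,
              x$mean_kappa, digits, x$ci_kappa[1], digits, x$ci_kappa[2]))
  cat(sprintf("  E[p1. | data] = %.*f   E[p.1 | data] = %.*f\n", digits,
              x$mean_p1, digits, x$mean_p2))
  invisible(x)
}
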