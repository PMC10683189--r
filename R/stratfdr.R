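## Conditional (stratified) FDR: the posterior null probability of one
## variant class's gene p-value given that the paired class's p-value is at
## least as extreme as a conditioning threshold, plus stratified Q-Q
## summaries of the same conditioning.

#' Conditional FDR of one signal given the other
#'
#' For genes whose conditioning p-value is below `threshold`,
#' `FDR(p | .) = pi0 * p / F(p | .)`, where `F` is the empirical conditional
#' CDF of the target p-values in the subset (floored at `1/|S|`) and `pi0`
#' is Storey's null-proportion estimate at `lambda` on the subset, clamped
#' to [0, 1]; the FDR itself is clamped at 1. `direction` names which class
#' is the target: `"rare_given_common"` conditions the rare p-values on the
#' common ones, `"common_given_rare"` the reverse.
#'
#' @param pairs Data frame with columns `p_rare` and `p_common` (a gene
#'   table works), or a two-column matrix `(p_R, p_C)`.
#' @param threshold Conditioning p-value threshold.
#' @param direction `"rare_given_common"` or `"common_given_rare"`.
#' @param lambda Storey tuning parameter for the pi0 estimate.
#' @param pi0 Optional fixed pi0 overriding the estimate.
#' @return An object of class `stratified_fdr`: per-gene data frame
#'   (`p_target`, `p_cond`, `in_subset`, `F_hat`, `fdr`) plus `pi0_hat`,
#'   `threshold`, `direction`, `subset_size`.
#' @export
conditional_fdr <- function(pairs, threshold = 1,
                            direction = c("rare_given_common",
                                          "common_given_rare"),
                            lambda = 0.5, pi0 = NULL) {
  direction <- match.arg(direction)
  pr <- extract_pairs(pairs)
  target <- if (direction == "rare_given_common") pr$p_rare else pr$p_common
  cond <- if (direction == "rare_given_common") pr$p_common else pr$p_rare
  threshold <- check_fraction(threshold, "threshold", open_lo = TRUE)
  sel <- which(cond <= threshold)
  if (length(sel) == 0L)
    stopf("no genes with conditioning p <= %g", threshold)
  if (length(sel) < 20L)
    warnf("conditioning subset has only %d genes", length(sel))
  ts <- target[sel]
  ns <- length(ts)
  if (is.null(pi0)) {
    pi0 <- sum(ts > lambda) / ((1 - lambda) * ns)
    pi0 <- min(max(pi0, 0), 1)
  }
  ## empirical conditional CDF with a 1/|S| floor
  Fh <- pmax(vapply(ts, function(p) mean(ts <= p), numeric(1)), 1 / ns)
  fdr <- pmin(pi0 * ts / Fh, 1)
  per_gene <- data.frame(p_target = target, p_cond = cond,
                         in_subset = seq_along(target) %in% sel,
                         F_hat = NA_real_, fdr = NA_real_)
  per_gene$F_hat[sel] <- Fh
  per_gene$fdr[sel] <- fdr
  structure(list(genes = per_gene, pi0_hat = pi0, threshold = threshold,
                 direction = direction, subset_size = ns, lambda = lambda),
            class = "stratified_fdr")
}

extract_pairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    if (!all(c("p_rare", "p_common") %in% names(pairs)))
      stopf("`pairs` needs columns p_rare and p_common")
    out <- list(p_rare = pairs$p_rare, p_common = pairs$p_common)
  } else if (is.matrix(pairs) && ncol(pairs) == 2L) {
    out <- list(p_rare = pairs[, 1L], p_common = pairs[, 2L])
  } else stopf("`pairs` must be a data frame or two-column matrix")
  ok <- stats::complete.cases(out$p_rare, out$p_common)
  out$p_rare <- out$p_rare[ok]; out$p_common <- out$p_common[ok]
  if (any(out$p_rare <= 0 | out$p_rare > 1 |
          out$p_common <= 0 | out$p_common > 1))
    stopf("p-values must lie in (0, 1]")
  out
}

#' @export
print.stratified_fdr <- function(x, ...) {
  cat(sprintf(
    "Conditional FDR (%s), threshold %g: %d genes in subset, pi0_hat = %.3f\n",
    x$direction, x$threshold, x$subset_size, x$pi0_hat))
  invisible(x)
}

#' Stratified Q-Q summary
#'
#' For each conditioning threshold (a descending list; 1 reproduces the
#' unconditional Q-Q), the expected versus observed `-log10` quantiles of
#' the target p-values among genes whose conditioning p-value passes the
#' threshold. Strata are nested by construction; strata smaller than
#' `min_size` are dropped with a warning.
#'
#' @inheritParams conditional_fdr
#' @param thresholds Descending vector of conditioning thresholds.
#' @param min_size Minimum stratum size retained.
#' @return An object of class `stratified_qq`: data frame with
#'   `stratum_threshold`, `expected_neglog10`, `observed_neglog10`,
#'   `stratum_size`.
#' @export
stratified_qq <- function(pairs, thresholds = c(1, 0.1, 0.01, 0.001),
                          direction = c("rare_given_common",
                                        "common_given_rare"),
                          min_size = 20L) {
  direction <- match.arg(direction)
  pr <- extract_pairs(pairs)
  target <- if (direction == "rare_given_common") pr$p_rare else pr$p_common
  cond <- if (direction == "rare_given_common") pr$p_common else pr$p_rare
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  rows <- list()
  for (th in thresholds) {
    ts <- sort(target[cond <= th])
    ns <- length(ts)
    if (ns < min_size) {
      warnf("stratum at threshold %g has %d genes (< %d); dropped",
            th, ns, min_size)
      next
    }
    expected <- -log10((seq_len(ns) - 0.5) / ns)
    rows[[length(rows) + 1L]] <-
      data.frame(stratum_threshold = th, expected_neglog10 = expected,
                 observed_neglog10 = -log10(ts), stratum_size = ns)
  }
  if (!length(rows)) stopf("no stratum met the minimum size")
  structure(do.call(rbind, rows), class = c("stratified_qq", "data.frame"))
}

#' @export
plot.stratified_qq <- function(x, ...) {
  ths <- unique(x$stratum_threshold)
  cols <- grDevices::hcl.colors(length(ths), "Dark 3")
  lim <- range(0, x$expected_neglog10, x$observed_neglog10, finite = TRUE)
  plot(NA, xlim = lim, ylim = lim,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)),
       main = "Stratified Q-Q", ...)
  abline(0, 1, lty = 2, col = "grey50")
  for (i in seq_along(ths)) {
    s <- x[x$stratum_threshold == ths[i], ]
    lines(sort(s$expected_neglog10), sort(s$observed_neglog10),
          col = cols[i], lwd = 2)
  }
  legend("topleft", legend = sprintf("p_cond <= %g", ths), col = cols,
         lwd = 2, cex = 0.8)
  invisible(x)
}
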