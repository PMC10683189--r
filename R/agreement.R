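## Chance-corrected agreement between two gene rankings: the convergence
## signature (Cohen's kappa) and its margin-robust companion (Gwet's AC1),
## computed from the 2x2 top-ranked / not-top-ranked gene counts.

#' Build a 2x2 concordance table from gene counts
#'
#' The table cross-classifies genes by whether they are top-ranked under the
#' common-variant signal and under the rare-variant signal: `a` genes ranked
#' top by both, `b` by the common signal only, `c` by the rare signal only,
#' and `d` by neither.
#'
#' @param a,b,c,d Non-negative gene counts.
#' @return An object of class `concordance_table` with fields `a`, `b`, `c`,
#'   `d` and `n = a + b + c + d`.
#' @examples
#' concordance_table(30, 20, 10, 40)
#' @export
concordance_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stopf("cell counts must be non-negative integers")
  counts <- as.integer(round(counts))
  n <- sum(counts)
  if (n < 1L) stopf("concordance table must contain at least one gene")
  structure(list(a = counts[[1L]], b = counts[[2L]], c = counts[[3L]],
                 d = counts[[4L]], n = n),
            class = "concordance_table")
}

as_concordance_table <- function(x) {
  if (inherits(x, "concordance_table")) return(x)
  if (is.numeric(x) && length(x) == 4L)
    return(concordance_table(x[[1]], x[[2]], x[[3]], x[[4]]))
  stopf("expected a `concordance_table` or a numeric vector (a, b, c, d)")
}

#' @export
print.concordance_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(rare = c("top", "other"),
                              common = c("top", "other")))
  cat("2x2 gene concordance table (n =", x$n, "genes)\n")
  print(m)
  invisible(x)
}

## Marginal and agreement probabilities shared by kappa and AC1.
table_probs <- function(tab) {
  n <- tab$n
  p_row1 <- (tab$a + tab$b) / n   # top-ranked under the common signal
  p_col1 <- (tab$a + tab$c) / n   # top-ranked under the rare signal
  p_alpha <- (tab$a + tab$d) / n  # observed proportionate agreement
  p_beta <- p_row1 * p_col1
  p_delta <- ((tab$c + tab$d) / n) * ((tab$b + tab$d) / n)
  list(p_alpha_hat = p_alpha, p_beta_hat = p_beta, p_delta_hat = p_delta,
       p_epsilon_hat = p_beta + p_delta, p_row1 = p_row1, p_col1 = p_col1)
}

#' Cohen's kappa from a concordance table
#'
#' The convergence signature: observed agreement corrected for the agreement
#' expected when the two rankings are independent with the observed margins,
#' `kappa = (p_alpha - p_epsilon) / (1 - p_epsilon)` where `p_epsilon` is the
#' sum of the chance probabilities of joint top-ranking and joint
#' non-top-ranking.
#'
#' @param table A [concordance_table()] or numeric vector `c(a, b, c, d)`.
#' @return A list with `kappa` and the intermediate probability estimates.
#' @examples
#' cohen_kappa(concordance_table(30, 20, 10, 40))$kappa  # 0.4
#' @export
cohen_kappa <- function(table) {
  tab <- as_concordance_table(table)
  pr <- table_probs(tab)
  if (pr$p_epsilon_hat >= 1)
    stopf("kappa is undefined: chance agreement p_epsilon = 1 (all mass in one margin cell)")
  kappa <- (pr$p_alpha_hat - pr$p_epsilon_hat) / (1 - pr$p_epsilon_hat)
  c(list(kappa = kappa), pr)
}

#' Gwet's AC1 from a concordance table
#'
#' A chance-corrected agreement coefficient less sensitive than kappa to the
#' prevalence of top-ranked genes: `ac1 = (p_alpha - p_gamma) / (1 - p_gamma)`
#' with `p_gamma = 2 * pi * (1 - pi)` and `pi` the mean of the two margin
#' probabilities.
#'
#' @inheritParams cohen_kappa
#' @return A list with `ac1`, `pi_hat`, `p_gamma_hat` and `p_alpha_hat`.
#' @examples
#' gwet_ac1(concordance_table(50, 0, 0, 50))$ac1  # 1
#' @export
gwet_ac1 <- function(table) {
  tab <- as_concordance_table(table)
  pr <- table_probs(tab)
  pi_hat <- (pr$p_row1 + pr$p_col1) / 2
  p_gamma <- 2 * pi_hat * (1 - pi_hat)
  if (p_gamma >= 1)
    stopf("AC1 is undefined: chance agreement p_gamma = 1")
  list(ac1 = (pr$p_alpha_hat - p_gamma) / (1 - p_gamma),
       pi_hat = pi_hat, p_gamma_hat = p_gamma, p_alpha_hat = pr$p_alpha_hat)
}

#' Odds ratio of joint top-ranking
#'
#' `(a d) / (b c)`; when any cell is zero the Haldane--Anscombe correction
#' (+0.5 to every cell) is applied and flagged. The odds ratio is reported for
#' comparison only: it equals 1 at chance and diverges as disagreement
#' vanishes, which makes its scale hard to compare across traits.
#'
#' @inheritParams cohen_kappa
#' @return A list with `odds_ratio` and logical `corrected`.
#' @examples
#' odds_ratio(concordance_table(30, 20, 10, 40))$odds_ratio  # 6
#' @export
odds_ratio <- function(table) {
  tab <- as_concordance_table(table)
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       corrected = corrected)
}
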