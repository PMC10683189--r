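## Gene-based rare-variant tests: weighted burden regression, the SKAT
## variance-component score test with Liu-type moment-matched quadratic-form
## p-values, and the SKAT-O optimal linear combination over a rho grid with
## Lee-style one-dimensional integration.

#' Default rare-variant weights
#'
#' The SKAT convention: the Beta(1, 25) density evaluated at the
#' minor-allele frequency, upweighting the rarest variants.
#'
#' @param maf Minor-allele frequencies.
#' @param shape1,shape2 Beta density parameters.
#' @return Numeric weights.
#' @export
rare_weights <- function(maf, shape1 = 1, shape2 = 25) {
  stats::dbeta(maf, shape1, shape2)
}

## Null-model residual machinery shared by the rare tests: intercept-only
## Gaussian model; residuals standardized by the residual SD.
null_residuals <- function(y, n) {
  res <- y - mean(y)
  sigma2 <- sum(res^2) / (n - 1)
  list(res = res, sigma2 = sigma2, rs = res / sqrt(sigma2))
}

## Liu et al. moment-matching p-value for Q ~ sum(lambda_j chi^2_1).
liu_pvalue <- function(Q, lambda) {
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
    a <- sqrt(l)
  }
  tstar <- (Q - c1) / sqrt(2 * c2)
  muX <- l + delta
  sigmaX <- sqrt(2) * a
  p <- stats::pchisq(tstar * sigmaX + muX, df = l, ncp = delta,
                     lower.tail = FALSE)
  max(p, .Machine$double.xmin)
}

## Liu quantile: value q with P(Q > q) = p under the matched distribution.
liu_quantile <- function(p, lambda) {
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
    a <- sqrt(l)
  }
  q <- stats::qchisq(p, df = l, ncp = delta, lower.tail = FALSE)
  (q - (l + delta)) / (sqrt(2) * a) * sqrt(2 * c2) + c1
}

## Extract the weighted, column-centered rare-dosage matrix of one
## gene/category; NULL when no polymorphic variant is available.
gene_category_matrix <- function(panel, gene, category, weights) {
  v <- panel$map$variants
  idx <- which(v$gene_id == gene & v$class == "rare" & !panel$monomorphic)
  if (!is.null(category) && !is.na(category))
    idx <- idx[v$category[idx] == category]
  if (length(idx) == 0L) return(NULL)
  w <- if (is.null(weights)) rare_weights(panel$maf[idx])
  else rep_len(weights, length(idx))
  A <- sweep(panel$G[, idx, drop = FALSE], 2L, w, `*`)
  sweep(A, 2L, colMeans(A))
}

## Internal workers on a prebuilt weighted centered matrix A and shared null
## model; the exported per-gene functions and gene_assoc_table both use them.

burden_p_from_A <- function(A, y) {
  score <- rowSums(A)
  sxx <- sum(score^2)
  if (sxx <= 0)
    return(structure(NA_real_, reason = "zero-variance burden score"))
  n <- length(y)
  yc <- y - mean(y)
  b <- sum(score * yc) / sxx
  rss <- max(sum(yc^2) - b^2 * sxx, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  max(2 * stats::pt(-abs(b / se), n - 2), .Machine$double.xmin)
}

skat_p_from_parts <- function(S, K) {
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (max(lambda) <= 0)
    return(structure(NA_real_, reason = "all-zero genotype matrix"))
  quadform_pvalue(sum(S^2), lambda)
}

## Ruben's chi-square series for P(Q > q), Q ~ sum(lambda_j chi^2_1):
## with beta <= min(lambda) the series P(Q <= q) = sum_k a_k F_{m+2k}(q/beta)
## has non-negative coefficients summing to 1, giving a rigorous truncation
## bound. Falls back to the saddlepoint when convergence is too slow.
ruben_pvalue <- function(Q, lambda, max_terms = 4000L, tol = 1e-7) {
  m <- length(lambda)
  beta <- 0.90625 * min(lambda)
  r1 <- 1 - beta / lambda
  a <- numeric(max_terms)
  a[1] <- exp(0.5 * sum(log(beta / lambda)))
  b <- numeric(max_terms)
  rp <- rep(1, m)
  cum <- a[1]
  for (k in seq_len(max_terms - 1L)) {
    rp <- rp * r1
    b[k] <- sum(rp)
    a[k + 1L] <- sum(b[k:1] * a[1:k]) / (2 * k)
    cum <- cum + a[k + 1L]
    if (1 - cum < tol) {
      kk <- 0:k
      cdf <- sum(a[1:(k + 1L)] *
                   stats::pchisq(Q / beta, df = m + 2 * kk))
      return(min(max(1 - cdf + (1 - cum), .Machine$double.xmin), 1))
    }
  }
  NA_real_
}

## Kuonen saddlepoint (Lugannani-Rice) tail probability for
## Q ~ sum(lambda_j chi^2_1); far more accurate than moment matching across
## the whole distribution. Single eigenvalue is exact chi-square.
quadform_pvalue <- function(Q, lambda) {
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  if (length(lambda) == 1L)
    return(max(stats::pchisq(Q / lambda, 1, lower.tail = FALSE),
               .Machine$double.xmin))
  if (Q <= 0) return(1)
  p <- ruben_pvalue(Q, lambda)
  if (!is.na(p)) return(p)
  kpr <- function(t) sum(lambda / (1 - 2 * t * lambda))
  tmax <- 1 / (2 * max(lambda))
  ## solve K'(t) = Q for the saddlepoint
  f <- function(t) kpr(t) - Q
  lo <- -1e3 / max(lambda)
  hi <- tmax * (1 - 1e-10)
  that <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root,
                   error = function(e) NA_real_)
  if (is.na(that)) return(liu_pvalue(Q, lambda))
  k2 <- sum(2 * lambda^2 / (1 - 2 * that * lambda)^2)
  if (abs(that) < 1e-7) {
    ## at the mean: Lugannani-Rice limit 1/2 - k3 / (6 sqrt(2 pi) k2^{3/2})
    k3 <- sum(8 * lambda^3)
    return(min(max(0.5 - k3 / (6 * sqrt(2 * pi) * sum(2 * lambda^2)^1.5),
                   .Machine$double.xmin), 1))
  }
  K <- -0.5 * sum(log1p(-2 * that * lambda))
  w <- sign(that) * sqrt(2 * (that * Q - K))
  v <- that * sqrt(k2)
  p <- stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Burden test for one gene and annotation category
#'
#' Regresses the phenotype on the weighted sum of minor-allele dosages over
#' the gene's rare variants of the category (default weights
#' [rare_weights()]); two-sided t-test p-value.
#'
#' @param panel A [simulate_genotypes()] panel.
#' @param phenotype Phenotype vector or [simulate_phenotype()] result.
#' @param gene Gene id.
#' @param category Annotation category (`"pLoF"`, `"missense_LC"`,
#'   `"synonymous"`) or `NA` to pool all rare variants of the gene.
#' @param weights Optional fixed weights (recycled); default Beta(1,25)
#'   density of the MAF.
#' @return A two-sided p-value, or `NA` when no testable variant exists or
#'   the burden score is constant (flagged via attribute `reason`).
#' @export
burden_test <- function(panel, phenotype, gene, category = NA,
                        weights = NULL) {
  y <- if (is.list(phenotype)) phenotype$y else phenotype
  A <- gene_category_matrix(panel, gene, category, weights)
  if (is.null(A))
    return(structure(NA_real_, reason = "no polymorphic variant"))
  burden_p_from_A(A, y)
}

#' SKAT variance-component test for one gene and annotation category
#'
#' Score statistic `Q = res' G W^2 G' res` (residuals from the intercept-only
#' null model, standardized by the residual SD), referred to its matching
#' mixture of chi-squares via Liu-type moment matching on the eigenvalues of
#' the weighted, centered genotype cross-product.
#'
#' @inheritParams burden_test
#' @return A p-value, or flagged `NA`.
#' @export
skat_test <- function(panel, phenotype, gene, category = NA, weights = NULL) {
  y <- if (is.list(phenotype)) phenotype$y else phenotype
  A <- gene_category_matrix(panel, gene, category, weights)
  if (is.null(A))
    return(structure(NA_real_, reason = "no polymorphic variant"))
  nm <- null_residuals(y, length(y))
  skat_p_from_parts(drop(crossprod(A, nm$rs)), crossprod(A))
}

## Symmetric square root of R_rho = (1-rho) I + rho 1 1'.
rho_sqrt <- function(m, rho) {
  e1 <- sqrt(1 - rho + rho * m)
  e2 <- sqrt(1 - rho)
  J <- matrix(1 / m, m, m)
  e2 * (diag(m) - J) + e1 * J
}

#' SKAT-O: optimal burden/SKAT combination for one gene and category
#'
#' For each `rho` on the grid the combined statistic
#' `Q_rho = (1 - rho) Q_SKAT + rho Q_burden` is referred to its
#' moment-matched mixture distribution; the minimum p-value over the grid is
#' then corrected by a one-dimensional integration over the shared
#' chi-square(1) factor. When the integration degenerates a Bonferroni
#' correction over the grid is used and flagged (attribute `fallback`).
#'
#' @inheritParams burden_test
#' @param rho_grid Grid of burden/SKAT mixing weights in [0, 1].
#' @return A p-value, or flagged `NA`.
#' @export
skato_test <- function(panel, phenotype, gene, category = NA,
                       weights = NULL,
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)) {
  y <- if (is.list(phenotype)) phenotype$y else phenotype
  A <- gene_category_matrix(panel, gene, category, weights)
  if (is.null(A))
    return(structure(NA_real_, reason = "no polymorphic variant"))
  if (any(rho_grid < 0 | rho_grid > 1)) stopf("rho_grid must lie in [0, 1]")
  nm <- null_residuals(y, length(y))
  skato_p_from_parts(A, drop(crossprod(A, nm$rs)), crossprod(A), rho_grid)
}

skato_p_from_parts <- function(A, S, K, rho_grid) {
  rho_grid <- sort(unique(rho_grid))
  m <- ncol(A)
  if (max(diag(K)) <= 0)
    return(structure(NA_real_, reason = "all-zero genotype matrix"))

  q_skat <- sum(S^2)
  q_burden <- sum(S)^2
  ## a single-point grid is a pure SKAT (rho = 0) or burden (rho = 1) test:
  ## use the exact quadratic-form distribution, no omnibus correction
  if (length(rho_grid) == 1L) {
    rho <- rho_grid
    Qr <- (1 - rho) * q_skat + rho * q_burden
    if (rho == 1 || m == 1L)
      return(stats::pchisq(Qr / sum(K), 1, lower.tail = FALSE))
    Rs <- rho_sqrt(m, rho)
    lam <- eigen(Rs %*% K %*% Rs, symmetric = TRUE, only.values = TRUE)$values
    return(quadform_pvalue(Qr, lam))
  }
  p_rho <- numeric(length(rho_grid))
  lambdas <- vector("list", length(rho_grid))
  for (i in seq_along(rho_grid)) {
    rho <- rho_grid[i]
    Qr <- (1 - rho) * q_skat + rho * q_burden
    if (rho == 1 || m == 1L) {
      lam <- sum(K)
      p_rho[i] <- stats::pchisq(Qr / lam, 1, lower.tail = FALSE)
      lambdas[[i]] <- lam
    } else {
      Rs <- rho_sqrt(m, rho)
      lam <- eigen(Rs %*% K %*% Rs, symmetric = TRUE,
                   only.values = TRUE)$values
      p_rho[i] <- liu_pvalue(Qr, lam)
      lambdas[[i]] <- lam
    }
  }
  if (length(rho_grid) == 1L || m == 1L) return(min(p_rho))
  minp <- min(p_rho)

  ## Lee-style omnibus: decompose along the column-mean direction.
  zbar <- rowMeans(A)
  zbar_sq <- sum(zbar^2)
  if (zbar_sq <= 0)
    return(structure(min(minp * length(rho_grid), 1), fallback = TRUE))
  ztA <- drop(crossprod(zbar, A))
  Z1 <- A - outer(zbar, ztA / zbar_sq)
  lam_k <- eigen(crossprod(Z1), symmetric = TRUE, only.values = TRUE)$values
  lam_k <- lam_k[lam_k > max(lam_k, 1e-12) * 1e-10]
  if (length(lam_k) == 0L)
    return(structure(min(minp * length(rho_grid), 1), fallback = TRUE))
  MuQ <- sum(lam_k)
  VarZeta <- 4 * sum((crossprod(A - Z1, Z1))^2)
  VarQ <- 2 * sum(lam_k^2) + VarZeta
  Df <- 12 / (12 * sum(lam_k^4) / sum(lam_k^2)^2)
  rho_c <- pmin(rho_grid, 0.999)  # keep the kappa-term weight positive
  tau <- m^2 * rho_c * zbar_sq + (1 - rho_c) * sum(ztA^2) / zbar_sq
  qmin <- vapply(seq_along(rho_grid), function(i) {
    if (rho_grid[i] == 1) {
      stats::qchisq(minp, 1, lower.tail = FALSE) * sum(K)
    } else liu_quantile(minp, lambdas[[i]])
  }, numeric(1))

  ## Integrate over the shared chi-square(1) factor with the substitution
  ## x = u^2 (removes the density singularity at 0).
  ug <- seq(0, 6.5, length.out = 651)
  xg <- ug^2
  ## minimum over rho of the kappa-part budget at chi1 = x
  tmin <- (qmin[1] - tau[1] * xg) / (1 - rho_c[1])
  for (i in seq_along(rho_c)[-1])
    tmin <- pmin(tmin, (qmin[i] - tau[i] * xg) / (1 - rho_c[i]))
  tq <- (tmin - MuQ) / sqrt(VarQ) * sqrt(2 * Df) + Df
  Fk <- ifelse(tq <= 0, 0, stats::pchisq(tq, Df))
  integrand <- Fk * 2 * stats::dnorm(ug)
  surv <- 1 - sum((integrand[-1] + integrand[-length(ug)]) / 2 * diff(ug))
  p <- min(max(surv, .Machine$double.xmin), 1)
  if (!is.finite(p))
    return(structure(min(minp * length(rho_grid), 1), fallback = TRUE))
  min(p, minp * length(rho_grid))
}

#' Combine rare-variant test p-values into P_rare
#'
#' The minimum over the available per-test, per-category p-values (no
#' multiplicity adjustment, mirroring the min-p convention); the number of
#' contributing tests and ties at the minimum are recorded. A
#' Bonferroni-style adjusted variant (`adjust = TRUE`, multiply by the count)
#' is available for sensitivity analysis.
#'
#' @param p Named (or unnamed) numeric vector of p-values, `NA` allowed.
#' @param adjust Multiply the minimum by the number of contributing tests.
#' @return A list with `p_rare`, `n_tests`, `tie`, and the source name
#'   `which` of the minimum.
#' @export
combine_rare <- function(p, adjust = FALSE) {
  ok <- !is.na(p)
  if (!any(ok)) return(list(p_rare = NA_real_, n_tests = 0L, tie = FALSE,
                            which = NA_character_))
  pv <- p[ok]
  mn <- min(pv)
  tie <- sum(pv == mn) > 1L
  out <- if (adjust) min(mn * length(pv), 1) else mn
  nm <- names(pv)[which.min(pv)]
  list(p_rare = out, n_tests = sum(ok), tie = tie,
       which = if (is.null(nm)) NA_character_ else nm)
}
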