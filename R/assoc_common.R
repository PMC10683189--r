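## Common-variant association: per-SNP ordinary least squares and gene-level
## aggregation of correlated p-values (Brown's-method style scaled
## chi-square, standing in for a full SNP-wise gene model).

#' Per-variant association scan (OLS)
#'
#' Ordinary least-squares slope, standard error and two-sided t-test p-value
#' of the phenotype on each polymorphic common variant. When covariates are
#' supplied they are residualized out of both the phenotype and the
#' genotypes (with an intercept) before the per-variant fits.
#'
#' @param panel A [simulate_genotypes()] panel.
#' @param phenotype A [simulate_phenotype()] result or numeric vector.
#' @param covariates Optional numeric matrix (individuals x covariates).
#' @return A data frame (`variant_id`, `beta_hat`, `se`, `p`, `n`, `maf`),
#'   one row per polymorphic common variant.
#' @export
gwas_scan <- function(panel, phenotype, covariates = NULL) {
  if (!inherits(panel, "cohort_panel")) stopf("`panel` must be a cohort_panel")
  y <- if (is.list(phenotype)) phenotype$y else phenotype
  n <- panel$n
  if (length(y) != n) stopf("phenotype length does not match the panel")
  v <- panel$map$variants
  keep <- which(v$class == "common" & !panel$monomorphic)
  if (length(keep) == 0L) stopf("no polymorphic common variants")
  q <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    q <- ncol(covariates)
    if (n < q + 2L) stopf("need at least covariates + 2 individuals")
    fit <- stats::lm.fit(cbind(1, covariates), y)
    y <- fit$residuals
    X <- stats::lm.fit(cbind(1, covariates),
                       panel$G[, keep, drop = FALSE])$residuals
  } else {
    if (n < 2L) stopf("need at least 2 individuals")
    X <- panel$G[, keep, drop = FALSE]
  }
  yc <- y - mean(y)
  Xc <- sweep(X, 2L, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- drop(crossprod(Xc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  df <- n - 2L - q
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  p <- pmax(p, .Machine$double.xmin)
  data.frame(variant_id = v$variant_id[keep], beta_hat = beta, se = se,
             p = p, n = n, maf = panel$maf[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

## Polynomial approximation to cov(-2 ln p_i, -2 ln p_j) for TWO-SIDED
## p-values of jointly normal statistics with correlation r: an even
## function of r (fitted by large-scale Monte Carlo, constrained to the
## exact value 4 at |r| = 1 so duplicated variants collapse exactly).
brown_cov <- function(r) {
  r2 <- r^2
  3.9364 * r2 - 0.0407 * r2^2 + 0.1043 * r2^3
}

#' Gene-level common-variant p-values from correlated SNP p-values
#'
#' Projects SNP-level signal to genes by summing `-2 ln p` over a gene's
#' common variants and referring the sum to a scaled chi-square whose mean
#' and variance match a sum of correlated chi-square(2) terms; the
#' covariance between terms is approximated by a cubic polynomial in the
#' absolute genotype correlation (Brown's method). Single-variant genes
#' return the SNP p-value unchanged. Genes whose common variants are all
#' monomorphic (absent from the scan) get `NA`.
#'
#' @param snp_table A [gwas_scan()] table.
#' @param map The [build_genome_map()] result.
#' @param panel The panel (needed for the genotype correlations).
#' @return Data frame with `gene_id`, `block_id`, `p_common`, `n_snps`.
#' @export
gene_test_common <- function(snp_table, map, panel) {
  if (!inherits(map, "genome_map")) stopf("`map` must be a genome_map")
  v <- map$variants
  pv <- snp_table$p[match(v$variant_id, snp_table$variant_id)]
  genes <- map$genes
  out_p <- rep(NA_real_, nrow(genes))
  out_m <- integer(nrow(genes))
  idx_by_gene <- split(seq_len(nrow(v)), v$gene_id)
  for (i in seq_len(nrow(genes))) {
    idx <- idx_by_gene[[genes$gene_id[i]]]
    idx <- idx[v$class[idx] == "common" & !is.na(pv[idx])]
    m <- length(idx)
    out_m[i] <- m
    if (m == 0L) next
    if (m == 1L) {
      out_p[i] <- pv[idx]
      next
    }
    T <- sum(-2 * log(pv[idx]))
    R <- stats::cor(panel$G[, idx, drop = FALSE])
    off <- brown_cov(R[upper.tri(R)])
    mu <- 2 * m
    vr <- 4 * m + 2 * sum(off)
    cc <- vr / (2 * mu)
    df <- 2 * mu^2 / vr
    out_p[i] <- stats::pchisq(T / cc, df, lower.tail = FALSE)
  }
  data.frame(gene_id = genes$gene_id, block_id = genes$block_id,
             p_common = pmax(out_p, .Machine$double.xmin),
             n_snps = out_m, stringsAsFactors = FALSE)
}
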