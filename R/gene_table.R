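## Assemble the per-gene association table: P_common from the correlated-p
## aggregation, P_rare as the minimum over (test x annotation category).

#' Gene-level association table for a simulated cohort
#'
#' Runs the common-variant scan and gene aggregation plus the rare-variant
#' tests (by default burden and SKAT-O in each annotation category, the six
#' tests whose minimum defines `P_rare`) and returns one row per gene with
#' the per-test p-values retained for audit.
#'
#' @param panel A [simulate_genotypes()] panel.
#' @param phenotype A [simulate_phenotype()] result or numeric vector.
#' @param tests Rare-variant tests entering `P_rare`: subset of
#'   `c("burden", "skat", "skato")`.
#' @param covariates Optional covariate matrix for the common scan.
#' @param adjust_rare Bonferroni-adjust the rare minimum (sensitivity
#'   analysis; default `FALSE`, the literal minimum).
#' @return Data frame with `gene_id`, `block_id`, `p_common`, `p_rare`,
#'   `rare_n_tests`, `rare_tie`, and `p_<test>_<category>` audit columns.
#' @export
gene_assoc_table <- function(panel, phenotype, tests = c("burden", "skato"),
                             covariates = NULL, adjust_rare = FALSE) {
  tests <- match.arg(tests, c("burden", "skat", "skato"), several.ok = TRUE)
  snp <- gwas_scan(panel, phenotype, covariates)
  common <- gene_test_common(snp, panel$map, panel)
  y <- if (is.list(phenotype)) phenotype$y else phenotype
  v <- panel$map$variants
  cats <- c("pLoF", "missense_LC", "synonymous")
  nm <- null_residuals(y, length(y))
  audit <- matrix(NA_real_, nrow(common), length(tests) * length(cats),
                  dimnames = list(NULL, paste0(
                    "p_", rep(tests, each = length(cats)), "_",
                    rep(cats, length(tests)))))
  p_rare <- rep(NA_real_, nrow(common))
  n_tests <- integer(nrow(common))
  tie <- logical(nrow(common))
  rare_poly <- which(v$class == "rare" & !panel$monomorphic)
  by_gene <- split(rare_poly, v$gene_id[rare_poly])
  for (i in seq_len(nrow(common))) {
    idx_gene <- by_gene[[common$gene_id[i]]]
    pvec <- numeric(0)
    for (ct in cats) {
      idx <- idx_gene[v$category[idx_gene] == ct]
      if (length(idx) == 0L) {
        pvec <- c(pvec, stats::setNames(rep(NA_real_, length(tests)),
                                        paste0(tests, "_", ct)))
        next
      }
      w <- rare_weights(panel$maf[idx])
      nn <- nrow(panel$G)
      A <- panel$G[, idx, drop = FALSE] * rep(w, each = nn)
      A <- A - rep(colMeans(A), each = nn)
      S <- drop(crossprod(A, nm$rs))
      K <- crossprod(A)
      for (te in tests) {
        p <- switch(te,
                    burden = burden_p_from_A(A, y),
                    skat = skat_p_from_parts(S, K),
                    skato = skato_p_from_parts(A, S, K,
                      c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)))
        nmcol <- paste0(te, "_", ct)
        audit[i, paste0("p_", nmcol)] <- as.numeric(p)
        pvec <- c(pvec, stats::setNames(as.numeric(p), nmcol))
      }
    }
    cmb <- combine_rare(pvec, adjust = adjust_rare)
    p_rare[i] <- cmb$p_rare
    n_tests[i] <- cmb$n_tests
    tie[i] <- cmb$tie
  }
  cbind(data.frame(gene_id = common$gene_id, block_id = common$block_id,
                   p_common = common$p_common, p_rare = p_rare,
                   rare_n_tests = n_tests, rare_tie = tie,
                   stringsAsFactors = FALSE),
        as.data.frame(audit))
}
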