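## The convergence estimator: clump genes within LD blocks, select the top-k
## genes under each variant class, and measure chance-corrected agreement.

validate_gene_table <- function(genes, require_p = TRUE) {
  if (!is.data.frame(genes))
    stopf("`genes` must be a data frame (gene_id, block_id, p_common, p_rare)")
  need <- c("gene_id", "block_id", "p_common", "p_rare")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stopf("`genes` is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stopf("duplicated gene_id in gene table")
  if (require_p) {
    for (cl in c("p_common", "p_rare")) {
      p <- genes[[cl]]
      if (any(is.na(p)))
        stopf("`%s` contains missing values; drop or impute before clumping", cl)
      if (any(p <= 0 | p > 1)) stopf("`%s` must lie in (0, 1]", cl)
    }
  }
  genes
}

#' Clump genes to one representative per LD block
#'
#' Within each linkage-disequilibrium block the gene with the strongest
#' combined signal -- the smallest product of its common-variant and
#' rare-variant p-values, computed as a sum of logs for underflow safety --
#' is retained. Ties are broken deterministically by lexicographic gene id
#' and flagged in the `tie` column.
#'
#' @param genes Data frame with columns `gene_id`, `block_id`, `p_common`,
#'   `p_rare` (all p-values present and in (0, 1]).
#' @return The clumped data frame, one row per block, with an added logical
#'   `tie` column.
#' @export
clump <- function(genes) {
  genes <- validate_gene_table(genes)
  score <- log(genes$p_common) + log(genes$p_rare)
  ## order by block, then score, then gene id for the deterministic tie-break
  ord <- order(genes$block_id, score, as.character(genes$gene_id))
  g <- genes[ord, , drop = FALSE]
  sc <- score[ord]
  first <- !duplicated(g$block_id)
  ## a tie: the runner-up in the same block has an identical score
  nxt <- c(first[-1], TRUE)                # TRUE where next row starts a block
  tie <- first & !nxt & c(sc[-1] == sc[-length(sc)], FALSE)
  out <- g[first, , drop = FALSE]
  out$tie <- tie[first]
  rownames(out) <- NULL
  out
}

#' Cross-classify top-k genes from two rankings
#'
#' Genes are ranked by `p_common` ascending and, independently, by `p_rare`
#' ascending; the top `k` of each list are the "significant" genes. The
#' counts of genes top-ranked by both, one, or neither list form the
#' concordance table (so `a + b = a + c = k` and `d = n - 2k + a`). Ties at
#' the k-th rank are broken by lexicographic gene id and flagged.
#'
#' @param clumped A clumped gene table (one gene per block).
#' @param k Number of top genes to select from each ranking.
#' @return A [concordance_table()] with attributes `k`, `tie_common`,
#'   `tie_rare`.
#' @export
build_table <- function(clumped, k) {
  clumped <- validate_gene_table(clumped)
  k <- check_count(k, "k")
  n <- nrow(clumped)
  if (k > n) stopf("k (%d) exceeds the number of clumped genes (%d)", k, n)
  id <- as.character(clumped$gene_id)
  top_set <- function(p) {
    ord <- order(p, id)
    sel <- ord[seq_len(k)]
    ## flag a tie straddling the k-th rank
    tie <- k < n && p[ord[k]] == p[ord[k + 1L]]
    list(top = id[sel], tie = tie)
  }
  tc <- top_set(clumped$p_common)
  tr <- top_set(clumped$p_rare)
  a <- length(intersect(tc$top, tr$top))
  tab <- concordance_table(a, k - a, k - a, n - 2L * k + a)
  attr(tab, "k") <- k
  attr(tab, "tie_common") <- tc$tie
  attr(tab, "tie_rare") <- tr$tie
  tab
}

#' Estimate the convergence of common- and rare-variant gene signals
#'
#' The main fitting function: clumps the gene table to one gene per LD block,
#' selects the top `k` genes under each variant class, and computes the
#' chance-corrected agreement between the two selections -- Cohen's kappa
#' (the convergence signature), Gwet's AC1 (its margin-robust variant) and
#' the odds ratio -- optionally with a bootstrap uncertainty summary.
#'
#' @param genes Gene association table: `gene_id`, `block_id`, `p_common`,
#'   `p_rare`. May contain several genes per block; clumping is applied.
#' @param k Number of top-ranked genes treated as significant in each list.
#' @param bootstrap Number of bootstrap replicates (0 to skip).
#' @param seed Integer seed for the bootstrap resampling.
#' @param conf_level Confidence level for percentile intervals.
#' @return An object of class `corac`: the concordance table, `kappa`, `ac1`,
#'   `odds_ratio`, intermediate probabilities, and (if requested) a
#'   `bootstrap` summary from [bootstrap_agreement()].
#' @examples
#' genes <- data.frame(gene_id = paste0("g", 1:200),
#'                     block_id = rep(1:100, each = 2),
#'                     p_common = runif(200), p_rare = runif(200))
#' fit <- corac(genes, k = 10)
#' coef(fit)
#' @export
corac <- function(genes, k = 100, bootstrap = 0, seed = 1,
                  conf_level = 0.95) {
  clumped <- clump(genes)
  tab <- build_table(clumped, k)
  kap <- cohen_kappa(tab)
  ac1 <- gwet_ac1(tab)
  orr <- odds_ratio(tab)
  boot <- NULL
  if (bootstrap > 0)
    boot <- bootstrap_agreement(clumped, k = k, B = bootstrap, seed = seed,
                                conf_level = conf_level)
  structure(list(table = tab, k = attr(tab, "k"), n = tab$n,
                 kappa = kap$kappa, ac1 = ac1$ac1,
                 odds_ratio = orr$odds_ratio, or_corrected = orr$corrected,
                 probs = kap[setdiff(names(kap), "kappa")],
                 pi_hat = ac1$pi_hat, p_gamma_hat = ac1$p_gamma_hat,
                 tie_common = attr(tab, "tie_common"),
                 tie_rare = attr(tab, "tie_rare"),
                 bootstrap = boot, clumped = clumped,
                 conf_level = conf_level),
            class = "corac")
}

#' @export
print.corac <- function(x, digits = 4, ...) {
  cat("Convergence of common- and rare-variant gene signals\n")
  cat(sprintf("  %d clumped genes, top k = %d per ranking\n", x$n, x$k))
  cat(sprintf("  kappa       = %.*f   (convergence signature)\n", digits, x$kappa))
  cat(sprintf("  AC1         = %.*f   (margin-robust variant)\n", digits, x$ac1))
  cat(sprintf("  odds ratio  = %.*g%s\n", digits, x$odds_ratio,
              if (x$or_corrected) "   [Haldane-Anscombe corrected]" else ""))
  if (!is.null(x$bootstrap)) {
    ci <- x$bootstrap$kappa$ci
    cat(sprintf("  bootstrap SE(kappa) = %.*f, %d%% CI [%.*f, %.*f] (B = %d)\n",
                digits, x$bootstrap$kappa$se, round(100 * x$conf_level),
                digits, ci[1], digits, ci[2], x$bootstrap$B))
  }
  invisible(x)
}

#' @export
coef.corac <- function(object, ...) {
  c(kappa = object$kappa, ac1 = object$ac1, odds_ratio = object$odds_ratio)
}

#' @export
summary.corac <- function(object, ...) {
  out <- list(estimates = coef(object), table = object$table,
              probs = object$probs, bootstrap = object$bootstrap,
              k = object$k, n = object$n)
  class(out) <- "summary.corac"
  out
}

#' @export
print.summary.corac <- function(x, ...) {
  print(x$table)
  cat("\nEstimates:\n")
  print(x$estimates)
  cat("\nIntermediate probabilities:\n")
  print(unlist(x$probs))
  if (!is.null(x$bootstrap)) {
    cat("\nBootstrap (B =", x$bootstrap$B, "):\n")
    cat(sprintf("  kappa SE %.4f  CI [%.4f, %.4f]\n", x$bootstrap$kappa$se,
                x$bootstrap$kappa$ci[1], x$bootstrap$kappa$ci[2]))
    cat(sprintf("  ac1   SE %.4f  CI [%.4f, %.4f]\n", x$bootstrap$ac1$se,
                x$bootstrap$ac1$ci[1], x$bootstrap$ac1$ci[2]))
  }
  invisible(x)
}

#' @export
confint.corac <- function(object, parm = c("kappa", "ac1"), level = 0.95, ...) {
  if (is.null(object$bootstrap))
    stopf("no bootstrap stored; refit with `bootstrap > 0`")
  parm <- match.arg(parm, several.ok = TRUE)
  reps <- object$bootstrap$replicates
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- t(vapply(parm, function(p)
    stats::quantile(reps[[p]], probs, na.rm = TRUE, names = FALSE),
    numeric(2)))
  colnames(out) <- paste0(format(100 * probs, trim = TRUE), " %")
  out
}

#' @export
plot.corac <- function(x, ...) {
  cl <- x$clumped
  lx <- -log10(cl$p_common)
  ly <- -log10(cl$p_rare)
  ord_c <- order(cl$p_common, as.character(cl$gene_id))[seq_len(x$k)]
  ord_r <- order(cl$p_rare, as.character(cl$gene_id))[seq_len(x$k)]
  both <- intersect(ord_c, ord_r)
  col <- rep("grey60", nrow(cl))
  col[ord_c] <- "steelblue"; col[ord_r] <- "orange"; col[both] <- "firebrick"
  plot(lx, ly, col = col, pch = 16, cex = 0.6,
       xlab = expression(-log[10] ~ p[common]),
       ylab = expression(-log[10] ~ p[rare]),
       main = sprintf("Gene-signal convergence (kappa = %.3f)", x$kappa), ...)
  legend("topright", pch = 16, cex = 0.8,
         col = c("firebrick", "steelblue", "orange", "grey60"),
         legend = c("top in both", "top common only", "top rare only",
                    "neither"))
  invisible(x)
}

#' Bootstrap uncertainty for the agreement statistics
#'
#' Resamples the clumped genes (the exchangeable unit after clumping) with
#' replacement, re-ranks the two p-value columns within each resample,
#' rebuilds the top-k concordance table and recomputes kappa and AC1.
#' Replicates on which kappa is undefined are dropped and counted; a warning
#' is issued when more than 10% are dropped.
#'
#' @param clumped Clumped gene table (one gene per block).
#' @param k Top-gene count, as in [build_table()].
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level Confidence level for the percentile interval.
#' @return A list with `kappa` and `ac1` summaries (point estimate, `se`,
#'   percentile `ci`), the replicate draws, `B` and the dropped count.
#' @export
bootstrap_agreement <- function(clumped, k, B = 1000, seed = 1,
                                conf_level = 0.95) {
  clumped <- validate_gene_table(clumped)
  k <- check_count(k, "k")
  B <- check_count(B, "B")
  n <- nrow(clumped)
  if (k > n) stopf("k exceeds the number of clumped genes")
  point_tab <- build_table(clumped, k)
  point <- list(kappa = cohen_kappa(point_tab)$kappa,
                ac1 = gwet_ac1(point_tab)$ac1)
  lpc <- log(clumped$p_common)
  lpr <- log(clumped$p_rare)
  reps <- with_seed(seed, {
    kap <- ac1 <- rep(NA_real_, B)
    for (bb in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      ## re-rank within the resample; duplicate genes keep distinct rank slots
      rc <- order(lpc[idx], idx)[seq_len(k)]
      rr <- order(lpr[idx], idx)[seq_len(k)]
      ## multiset intersection: a duplicated gene in both top lists counts
      ## once per matched instance, keeping the resampled a unbiased
      a <- sum(pmin(tabulate(idx[rc], nbins = n),
                    tabulate(idx[rr], nbins = n)))
      tab <- concordance_table(a, k - a, k - a, n - 2L * k + a)
      pr <- table_probs(tab)
      if (pr$p_epsilon_hat < 1)
        kap[bb] <- (pr$p_alpha_hat - pr$p_epsilon_hat) / (1 - pr$p_epsilon_hat)
      g <- gwet_ac1(tab)
      ac1[bb] <- g$ac1
    }
    list(kappa = kap, ac1 = ac1)
  })
  dropped <- sum(is.na(reps$kappa))
  if (dropped > 0.1 * B)
    warnf("%d of %d bootstrap replicates had undefined kappa", dropped, B)
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  summarise <- function(v, pt) {
    v <- v[!is.na(v)]
    list(estimate = pt, se = stats::sd(v),
         ci = stats::quantile(v, probs, names = FALSE))
  }
  list(kappa = summarise(reps$kappa, point$kappa),
       ac1 = summarise(reps$ac1, point$ac1),
       replicates = reps, B = B, dropped = dropped,
       conf_level = conf_level)
}

#' Read / write a gene-level association table
#'
#' Tab-separated text with columns `gene_id`, `block_id`, `p_common`,
#' `p_rare` (extra audit columns such as per-test rare p-values are kept).
#' This is also the entry point for externally produced (empirical) gene
#' tables.
#'
#' @param path File path.
#' @param genes Gene table to write.
#' @return `read_gene_table` returns the validated data frame.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_gene_table(g, require_p = FALSE)
}

#' @rdname read_gene_table
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
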