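## Genome scaffold for the synthetic cohorts: approximately independent LD
## blocks, genes nested in blocks, and common/rare variants nested in genes.

#' Build a synthetic genome map
#'
#' Lays out `n_blocks` approximately independent LD blocks, each holding
#' `genes_per_block` genes; every gene carries `n_common_per_gene` common
#' variants and `n_rare_per_gene` rare variants. Rare variants are assigned
#' an annotation category (pLoF, missense_LC or synonymous) with the given
#' proportions. Common variants receive a target minor-allele frequency drawn
#' uniformly from `[maf_split, 0.5]`; rare-variant target frequencies depend
#' on the cohort size and are resolved by [simulate_genotypes()].
#'
#' @param n_blocks,genes_per_block,n_common_per_gene,n_rare_per_gene Counts
#'   (all >= 1, except the variant counts which may be 0 for one class).
#' @param maf_split Common/rare frequency boundary, in (0, 0.5).
#' @param category_props Length-3 proportions for the rare-variant categories
#'   (pLoF, missense_LC, synonymous).
#' @param seed Integer seed; the map is a pure function of its arguments.
#' @return An object of class `genome_map`: a list with `variants` (data
#'   frame: `variant_id`, `gene_id`, `block_id`, `class`, `category`,
#'   `target_maf`), `genes` (gene -> block), `blocks`, and the settings.
#' @examples
#' m <- build_genome_map(2, 3, 4, 6, seed = 1)
#' table(m$variants$class)
#' @export
build_genome_map <- function(n_blocks, genes_per_block, n_common_per_gene,
                             n_rare_per_gene, maf_split = 0.01,
                             category_props = c(pLoF = 0.2, missense_LC = 0.5,
                                                synonymous = 0.3),
                             seed = 1) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  genes_per_block <- check_count(genes_per_block, "genes_per_block")
  n_common_per_gene <- check_count(n_common_per_gene, "n_common_per_gene",
                                   min = 0L)
  n_rare_per_gene <- check_count(n_rare_per_gene, "n_rare_per_gene", min = 0L)
  if (n_common_per_gene + n_rare_per_gene < 1L)
    stopf("each gene needs at least one variant")
  maf_split <- check_fraction(maf_split, "maf_split", 0, 0.5,
                              open_lo = TRUE, open_hi = TRUE)
  if (length(category_props) != 3L || any(category_props < 0) ||
      sum(category_props) <= 0)
    stopf("`category_props` must be 3 non-negative proportions")
  category_props <- category_props / sum(category_props)
  cats <- c("pLoF", "missense_LC", "synonymous")

  n_genes <- n_blocks * genes_per_block
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  gene_block <- rep(seq_len(n_blocks), each = genes_per_block)
  m_per_gene <- n_common_per_gene + n_rare_per_gene

  cls <- rep(rep(c("common", "rare"),
                 c(n_common_per_gene, n_rare_per_gene)), n_genes)
  v_gene <- rep(gene_id, each = m_per_gene)
  v_block <- rep(gene_block, each = m_per_gene)
  n_var <- n_genes * m_per_gene
  variant_id <- sprintf("v%06d", seq_len(n_var))

  rare_idx <- which(cls == "rare")
  category <- rep(NA_character_, n_var)
  target_maf <- rep(NA_real_, n_var)
  with_seed(seed, {
    if (length(rare_idx))
      category[rare_idx] <- sample(cats, length(rare_idx), replace = TRUE,
                                   prob = category_props)
    common_idx <- which(cls == "common")
    if (length(common_idx))
      target_maf[common_idx] <- stats::runif(length(common_idx),
                                             maf_split, 0.5)
  })

  variants <- data.frame(variant_id = variant_id, gene_id = v_gene,
                         block_id = v_block, class = cls,
                         category = category, target_maf = target_maf,
                         stringsAsFactors = FALSE)
  structure(list(variants = variants,
                 genes = data.frame(gene_id = gene_id, block_id = gene_block,
                                    stringsAsFactors = FALSE),
                 blocks = seq_len(n_blocks),
                 maf_split = maf_split,
                 category_props = category_props,
                 seed = check_seed(seed)),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  v <- x$variants
  cat("Synthetic genome map:",
      length(x$blocks), "LD blocks,",
      nrow(x$genes), "genes,",
      sum(v$class == "common"), "common +",
      sum(v$class == "rare"), "rare variants",
      sprintf("(MAF split %.3g)\n", x$maf_split))
  invisible(x)
}
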