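## Synthetic genotype panels: within-block LD from a single-factor latent
## Gaussian threshold model, dosages as two thresholded haplotype draws.

#' Simulate a genotype panel over a genome map
#'
#' Within each LD block a shared latent Gaussian factor induces exchangeable
#' correlation: every common variant loads `sqrt(rho_common)` on the block
#' factor (pairwise latent correlation `rho_common`), and every rare variant
#' loads `rho_rare / sqrt(rho_common)` (latent correlation `rho_rare` with
#' any common variant in the block). Two independent latent draws per
#' individual are thresholded at the MAF-matched normal quantile and summed
#' into an allele dosage in {0, 1, 2} (Hardy-Weinberg at the target
#' frequency). Variants in different blocks are independent.
#'
#' Common-variant target frequencies come from the genome map; rare-variant
#' targets are drawn uniformly on `[1/(2 n), maf_split)` because the lower
#' bound depends on the cohort size. Monomorphic columns (realized frequency
#' 0 or 1) are retained but flagged so indices stay aligned with the map.
#'
#' @param map A [build_genome_map()] result.
#' @param n_individuals Cohort size (>= 2).
#' @param seed Integer seed.
#' @param rho_common Latent correlation between common variants in a block.
#' @param rho_rare Latent correlation between a rare variant and any other
#'   variant in its block (must satisfy `rho_rare <= sqrt(rho_common)`).
#' @param maf_rare Optional function `(k, n)` returning `k` rare target
#'   frequencies for a cohort of size `n`; default uniform on
#'   `[1/(2n), maf_split)`.
#' @return An object of class `cohort_panel`: dosage matrix `G`
#'   (individuals x variants), realized allele frequency `freq`, minor-allele
#'   frequency `maf`, `monomorphic` flags, the `map`, and `n`.
#' @export
simulate_genotypes <- function(map, n_individuals, seed = 1,
                               rho_common = 0.3, rho_rare = 0.05,
                               maf_rare = NULL) {
  if (!inherits(map, "genome_map")) stopf("`map` must be a genome_map")
  n <- check_count(n_individuals, "n_individuals", min = 2L)
  rho_common <- check_fraction(rho_common, "rho_common", 0, 1, open_hi = TRUE)
  rho_rare <- check_fraction(rho_rare, "rho_rare", 0, 1, open_hi = TRUE)
  if (rho_common > 0 && rho_rare > sqrt(rho_common))
    stopf("rho_rare must not exceed sqrt(rho_common)")

  v <- map$variants
  M <- nrow(v)
  target <- v$target_maf
  with_seed(seed, {
    rare <- which(v$class == "rare")
    if (length(rare)) {
      lo <- 1 / (2 * n)
      if (lo >= map$maf_split)
        stopf("cohort too small: 1/(2n) >= maf_split")
      target[rare] <- if (is.null(maf_rare))
        stats::runif(length(rare), lo, map$maf_split)
      else maf_rare(length(rare), n)
    }

    load <- numeric(M)
    if (rho_common > 0) {
      load[v$class == "common"] <- sqrt(rho_common)
      load[v$class == "rare"] <- rho_rare / sqrt(rho_common)
    }
    thr <- stats::qnorm(1 - target)

    G <- matrix(0L, n, M)
    n2 <- 2L * n
    for (b in unique(v$block_id)) {
      idx <- which(v$block_id == b)
      m <- length(idx)
      lam <- load[idx]
      ## two haplotype draws per individual
      L <- matrix(stats::rnorm(n2 * m) * rep(sqrt(1 - lam^2), each = n2),
                  n2, m)
      if (any(lam != 0))
        L <- L + tcrossprod(stats::rnorm(n2), lam)
      H <- L > rep(thr[idx], each = n2)
      G[, idx] <- H[seq_len(n), , drop = FALSE] +
        H[n + seq_len(n), , drop = FALSE]
    }
    colnames(G) <- v$variant_id
    freq <- colMeans(G) / 2
    maf <- pmin(freq, 1 - freq)
    structure(list(G = G, freq = freq, maf = maf, target_maf = target,
                   monomorphic = maf == 0, map = map, n = n,
                   rho_common = rho_common, rho_rare = rho_rare,
                   ld_scores = NULL, decorrelated = FALSE),
              class = "cohort_panel")
  })
}

#' @export
print.cohort_panel <- function(x, ...) {
  v <- x$map$variants
  cat("Synthetic cohort panel:", x$n, "individuals x", ncol(x$G), "variants",
      sprintf("(%d common, %d rare; %d monomorphic%s)\n",
              sum(v$class == "common"), sum(v$class == "rare"),
              sum(x$monomorphic),
              if (x$decorrelated) "; rare decorrelated" else ""))
  invisible(x)
}

#' LD scores within blocks
#'
#' For each polymorphic variant, the sum of squared Pearson correlations with
#' every variant in the same block (including itself, so scores are >= 1 up
#' to floating point). Monomorphic variants get `NA`.
#'
#' @param panel A [simulate_genotypes()] panel.
#' @param window Correlation window; only `"block"` (the within-block sum the
#'   block-diagonal model implies) is meaningful here.
#' @return Numeric vector of per-variant LD scores.
#' @export
compute_ld_scores <- function(panel, window = "block") {
  if (!inherits(panel, "cohort_panel")) stopf("`panel` must be a cohort_panel")
  window <- match.arg(window, "block")
  v <- panel$map$variants
  l <- rep(NA_real_, nrow(v))
  for (b in unique(v$block_id)) {
    idx <- which(v$block_id == b)
    poly <- idx[!panel$monomorphic[idx]]
    if (length(poly) == 0L) next
    if (length(poly) == 1L) {
      l[poly] <- 1
      next
    }
    r <- stats::cor(panel$G[, poly, drop = FALSE])
    l[poly] <- rowSums(r^2)
  }
  l
}

## Fetch (and cache in the caller's object) LD scores.
panel_ld_scores <- function(panel) {
  if (is.null(panel$ld_scores)) compute_ld_scores(panel) else panel$ld_scores
}

#' Break rare/common correlation by permuting rare genotypes
#'
#' Each rare-variant column is independently permuted across individuals;
#' common-variant columns are untouched. Marginal allele counts (and hence
#' frequencies) are preserved exactly, while any correlation between rare
#' variants and the rest of the panel is destroyed.
#'
#' @param panel A [simulate_genotypes()] panel.
#' @param seed Integer seed.
#' @return The panel with shuffled rare columns and `decorrelated = TRUE`.
#' @export
decorrelate_rare <- function(panel, seed = 1) {
  if (!inherits(panel, "cohort_panel")) stopf("`panel` must be a cohort_panel")
  rare <- which(panel$map$variants$class == "rare")
  with_seed(seed, {
    for (j in rare) panel$G[, j] <- panel$G[sample.int(panel$n), j]
  })
  panel$ld_scores <- NULL
  panel$decorrelated <- TRUE
  panel
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper chaining [build_genome_map()] (unless a map is given),
#' [simulate_genotypes()], [assign_causal_genes()], [draw_effects()] and
#' [simulate_phenotype()], with per-stage seeds derived deterministically
#' from `seed`.
#'
#' @param params An [architecture_params()] object.
#' @param n_individuals Cohort size.
#' @param map Optional pre-built [build_genome_map()] result.
#' @param n_blocks,genes_per_block,n_common_per_gene,n_rare_per_gene,maf_split
#'   Map settings used when `map` is not supplied.
#' @param seed Master integer seed.
#' @param decorrelate Permute rare-variant genotypes after simulation.
#' @param ... Passed to [simulate_genotypes()].
#' @return A list with `panel`, `causal`, `effects`, `phenotype`, `map` and
#'   the seeds used per stage.
#' @export
simulate_cohort <- function(params, n_individuals, map = NULL,
                            n_blocks = 150, genes_per_block = 2,
                            n_common_per_gene = 4, n_rare_per_gene = 12,
                            maf_split = 0.01, seed = 1,
                            decorrelate = FALSE, ...) {
  if (is.null(map))
    map <- build_genome_map(n_blocks, genes_per_block, n_common_per_gene,
                            n_rare_per_gene, maf_split = maf_split,
                            seed = child_seed(seed, 1))
  panel <- simulate_genotypes(map, n_individuals,
                              seed = child_seed(seed, 2), ...)
  causal <- assign_causal_genes(map, params, seed = child_seed(seed, 3))
  effects <- draw_effects(panel, causal, params, seed = child_seed(seed, 4))
  if (decorrelate) panel <- decorrelate_rare(panel, seed = child_seed(seed, 6))
  phenotype <- simulate_phenotype(panel, effects, params,
                                  seed = child_seed(seed, 5))
  list(panel = panel, causal = causal, effects = effects,
       phenotype = phenotype, map = map, seed = check_seed(seed))
}

#' Write a cohort to plain-text files
#'
#' `variants.tsv` (variant metadata with realized frequencies and LD scores),
#' `genotypes.tsv` (dense dosage matrix with a versioned header line) and
#' `phenotype.tsv` (individual id and trait value).
#'
#' @param cohort A [simulate_cohort()] result (or a bare panel).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  panel <- if (inherits(cohort, "cohort_panel")) cohort else cohort$panel
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- panel$map$variants
  v$maf <- panel$maf
  v$ld_score <- panel_ld_scores(panel)
  utils::write.table(v, file.path(dir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "genotypes.tsv"), "w")
  writeLines("#corac-genotypes v1: individuals x variants, dosage 0/1/2", con)
  utils::write.table(panel$G, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (!inherits(cohort, "cohort_panel") && !is.null(cohort$phenotype)) {
    utils::write.table(
      data.frame(individual_id = seq_len(panel$n), y = cohort$phenotype$y),
      file.path(dir, "phenotype.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(dir)
}

#' Read simulation settings from a YAML config
#'
#' All generator and architecture parameters may be stored in one YAML file;
#' unknown keys are rejected to catch typos.
#'
#' @param path YAML file path.
#' @return A named list of settings.
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the `yaml` package is required to read config files")
  cfg <- yaml::read_yaml(path)
  known <- c("n_blocks", "genes_per_block", "n_common_per_gene",
             "n_rare_per_gene", "maf_split", "n_individuals", "seed",
             "h2_trait", "prop_causal_genes", "shared_causal_fraction",
             "alpha", "r", "mode", "rho_common", "rho_rare",
             "prop_causal_variants", "k", "decorrelate")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg
}
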