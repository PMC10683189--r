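## Genetic architectures: causal-gene assignment, frequency-dependent
## (selection-aware) effect sizes, and phenotype construction at fixed
## heritability.

#' Genetic architecture parameters
#'
#' Bundles the simulation architecture: trait heritability, the fraction of
#' genes that are causal, the fraction of causal genes shared between the
#' common-variant and rare-variant paths, the selection exponent `alpha`
#' linking allele frequency to causal-effect variance, the LD exponent `r`
#' (0: frequency-dependent only; 1: frequency- and LD-dependent) and the
#' effect-size `mode` (`"selection"`: variance proportional to
#' `[p(1-p)]^(1+alpha) * (1/(1+l))^r`; `"baseline"`: frequency-independent
#' variance `h2/N_causal`).
#'
#' @param h2_trait Heritability in [0, 1].
#' @param prop_causal_genes Fraction of genes causal, in (0, 1].
#' @param shared_causal_fraction Fraction of each path's causal genes shared
#'   with the other path, in [0, 1].
#' @param alpha Selection exponent (negative values concentrate per-variant
#'   heritability at low frequencies; -0.37 is a typical biobank estimate).
#' @param r LD exponent, 0 or 1.
#' @param mode `"selection"` or `"baseline"`.
#' @param prop_causal_variants Fraction of a causal gene's variants (per
#'   class) that carry effects.
#' @return An object of class `architecture_params`.
#' @export
architecture_params <- function(h2_trait = 0.3, prop_causal_genes = 0.1,
                                shared_causal_fraction = 0.5, alpha = -0.37,
                                r = 0, mode = c("selection", "baseline"),
                                prop_causal_variants = 0.5) {
  mode <- match.arg(mode)
  if (!r %in% c(0, 1)) stopf("`r` must be 0 or 1")
  structure(list(
    h2_trait = check_fraction(h2_trait, "h2_trait"),
    prop_causal_genes = check_fraction(prop_causal_genes,
                                       "prop_causal_genes", open_lo = TRUE),
    shared_causal_fraction = check_fraction(shared_causal_fraction,
                                            "shared_causal_fraction"),
    alpha = as.numeric(alpha), r = as.numeric(r), mode = mode,
    prop_causal_variants = check_fraction(prop_causal_variants,
                                          "prop_causal_variants",
                                          open_lo = TRUE)),
    class = "architecture_params")
}

#' @export
print.architecture_params <- function(x, ...) {
  cat(sprintf(
    "Architecture: h2 = %.3g, %.0f%% causal genes (%.0f%% shared), %s mode",
    x$h2_trait, 100 * x$prop_causal_genes, 100 * x$shared_causal_fraction,
    x$mode))
  if (x$mode == "selection")
    cat(sprintf(" (alpha = %.3g, r = %g)", x$alpha, x$r))
  cat("\n")
  invisible(x)
}

#' Assign causal genes to the common and rare paths
#'
#' Each path receives `round(prop_causal_genes * n_genes)` causal genes,
#' constructed as a shared core of `round(shared_causal_fraction * size)`
#' genes plus disjoint path-specific remainders, so the realized overlap
#' fraction equals the requested one exactly.
#'
#' @param map A [build_genome_map()] result.
#' @param params An [architecture_params()] object.
#' @param seed Integer seed.
#' @return A list with character vectors `common` and `rare` (gene ids) and
#'   `shared` (their intersection).
#' @export
assign_causal_genes <- function(map, params, seed = 1) {
  if (!inherits(map, "genome_map")) stopf("`map` must be a genome_map")
  if (!inherits(params, "architecture_params"))
    stopf("`params` must be architecture_params")
  genes <- map$genes$gene_id
  n_genes <- length(genes)
  size <- round(params$prop_causal_genes * n_genes)
  if (size < 1) stopf("prop_causal_genes * n_genes must be >= 1")
  n_shared <- round(params$shared_causal_fraction * size)
  need <- n_shared + 2L * (size - n_shared)
  if (need > n_genes)
    stopf("not enough genes (%d) for two causal sets of %d sharing %d",
          n_genes, size, n_shared)
  with_seed(seed, {
    picked <- sample(genes, need)
    shared <- picked[seq_len(n_shared)]
    rest <- picked[seq_len(need - n_shared) + n_shared]
    common_only <- rest[seq_len(size - n_shared)]
    rare_only <- rest[seq_len(size - n_shared) + (size - n_shared)]
    list(common = sort(c(shared, common_only)),
         rare = sort(c(shared, rare_only)),
         shared = sort(shared))
  })
}

## variance profile of Eq.-style effect model on SD-scaled genotypes
selection_variance <- function(maf, ld, C, alpha, r) {
  v <- C * (maf * (1 - maf))^(1 + alpha)
  if (r != 0) v <- v * (1 / (1 + ld))^r
  v
}

#' Draw causal effect sizes
#'
#' Common-path causal genes receive effects on a fraction of their common
#' variants, rare-path causal genes on a fraction of their rare variants
#' (at least one variant per class). Effects are per genotype-SD. Under
#' `mode = "selection"` the variance is
#' `C * [p(1-p)]^(1+alpha) * (1/(1+l))^r` with `C = h2 / N_causal` and `p`
#' the realized minor-allele frequency; under `mode = "baseline"` the
#' variance is `h2 / N_causal` for every causal variant. Monomorphic
#' variants are never selected as causal.
#'
#' @param panel A [simulate_genotypes()] panel.
#' @param causal An [assign_causal_genes()] result.
#' @param params An [architecture_params()] object.
#' @param seed Integer seed.
#' @return A list with `beta` (per-variant effect, 0 for non-causal),
#'   `causal` (logical), `n_causal` and the scale `C`.
#' @export
draw_effects <- function(panel, causal, params, seed = 1) {
  if (!inherits(panel, "cohort_panel")) stopf("`panel` must be a cohort_panel")
  if (!inherits(params, "architecture_params"))
    stopf("`params` must be architecture_params")
  v <- panel$map$variants
  M <- nrow(v)
  pick <- logical(M)
  with_seed(seed, {
    for (path in c("common", "rare")) {
      for (g in causal[[path]]) {
        idx <- which(v$gene_id == g & v$class == path & !panel$monomorphic)
        if (length(idx) == 0L) next
        k <- max(1L, round(params$prop_causal_variants * length(idx)))
        pick[sample(idx, k)] <- TRUE
      }
    }
    n_causal <- sum(pick)
    if (n_causal == 0L) stopf("no polymorphic causal variants available")
    C <- params$h2_trait / n_causal
    beta <- numeric(M)
    if (params$h2_trait > 0) {
      vari <- if (params$mode == "baseline") rep(C, n_causal) else {
        ld <- if (params$r != 0) panel_ld_scores(panel)[pick] else
          rep(0, n_causal)
        if (params$r != 0 && anyNA(ld))
          stopf("LD scores unavailable for some causal variants (r = 1)")
        selection_variance(panel$maf[pick], ld, C, params$alpha, params$r)
      }
      beta[pick] <- stats::rnorm(n_causal, 0, sqrt(vari))
    }
    list(beta = beta, causal = pick, n_causal = n_causal, C = C)
  })
}

#' Simulate a quantitative phenotype at fixed heritability
#'
#' `y = G_s beta + e` on column-scaled genotypes, with the noise drawn,
#' orthogonalized against the genetic component, and both parts rescaled so
#' the realized genetic variance share equals `h2_trait` exactly; the output
#' is standardized to mean 0, variance 1.
#'
#' @param panel A [simulate_genotypes()] panel.
#' @param effects A [draw_effects()] result.
#' @param params An [architecture_params()] object.
#' @param seed Integer seed.
#' @return A list with `y`, `genetic` (the scaled genetic component), `n`
#'   and the realized `h2`.
#' @export
simulate_phenotype <- function(panel, effects, params, seed = 1) {
  if (!inherits(panel, "cohort_panel")) stopf("`panel` must be a cohort_panel")
  n <- panel$n
  h2 <- params$h2_trait
  idx <- which(effects$beta != 0)
  g <- if (length(idx)) {
    Gs <- scale(panel$G[, idx, drop = FALSE])
    drop(Gs %*% effects$beta[idx])
  } else numeric(n)
  vg <- stats::var(g)
  if (h2 > 0 && vg <= 0)
    stopf("h2_trait > 0 requires a non-degenerate genetic component")
  with_seed(seed, {
    e <- stats::rnorm(n)
    if (h2 > 0) {
      ## orthogonalize the noise so the variance split is exact
      e <- e - mean(e)
      gc <- g - mean(g)
      e <- e - gc * sum(e * gc) / sum(gc^2)
      y <- sqrt(h2) * gc / stats::sd(gc) + sqrt(1 - h2) * e / stats::sd(e)
      gen <- sqrt(h2) * gc / stats::sd(gc)
    } else {
      y <- e
      gen <- numeric(n)
    }
    y <- (y - mean(y)) / stats::sd(y)
    list(y = y, genetic = gen, n = n,
         h2 = if (h2 > 0) stats::var(gen) / stats::var(y) * 1 else 0)
  })
}
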