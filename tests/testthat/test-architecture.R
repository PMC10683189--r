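test_that("causal gene sets have the requested sizes and overlap", {
  m <- build_genome_map(200, 3, 2, 2, seed = 1)   # 600 genes
  ar <- architecture_params(prop_causal_genes = 0.10,
                            shared_causal_fraction = 0.50)
  cs <- assign_causal_genes(m, ar, seed = 2)
  expect_length(cs$common, 60)
  expect_length(cs$rare, 60)
  expect_length(intersect(cs$common, cs$rare), 30)
  ## extremes
  cs1 <- assign_causal_genes(m, architecture_params(shared_causal_fraction = 1),
                             seed = 3)
  expect_identical(cs1$common, cs1$rare)
  cs0 <- assign_causal_genes(m, architecture_params(shared_causal_fraction = 0),
                             seed = 4)
  expect_length(intersect(cs0$common, cs0$rare), 0)
  ## infeasible request
  big <- architecture_params(prop_causal_genes = 0.9,
                             shared_causal_fraction = 0)
  expect_error(assign_causal_genes(m, big, seed = 5), "not enough genes")
})

test_that("zero heritability yields all-zero effects", {
  co <- tiny_cohort()
  ar <- architecture_params(h2_trait = 0)
  cs <- assign_causal_genes(co$map, ar, seed = 1)
  ef <- draw_effects(co$panel, cs, ar, seed = 2)
  expect_true(all(ef$beta == 0))
  expect_gt(ef$n_causal, 0)
})

test_that("baseline effects have variance h2 / N_causal", {
  ## every gene causal, every variant causal: N_causal fixed across seeds
  m <- build_genome_map(50, 1, 4, 0, seed = 7)
  p <- simulate_genotypes(m, 500, seed = 8)
  ar <- architecture_params(h2_trait = 0.3, prop_causal_genes = 1,
                            shared_causal_fraction = 1, mode = "baseline",
                            prop_causal_variants = 1)
  cs <- assign_causal_genes(m, ar, seed = 1)
  betas <- unlist(lapply(1:60, function(s) {
    ef <- draw_effects(p, cs, ar, seed = s)
    ef$beta[ef$causal]
  }))
  expect_gte(length(betas), 10000)
  expect_equal(var(betas), 0.3 / 200, tolerance = 0.1)
})

test_that("selection mode reproduces the frequency scaling of effect variance", {
  ## alpha = -1, r = 0: variance independent of p(1-p)
  m <- build_genome_map(400, 1, 6, 0, seed = 17)
  p <- simulate_genotypes(m, 800, seed = 18)
  ar1 <- architecture_params(alpha = -1, r = 0, prop_causal_genes = 1,
                             shared_causal_fraction = 1,
                             prop_causal_variants = 1)
  betas <- numeric(0); hets <- numeric(0)
  for (s in 1:5) {
    ef <- draw_effects(p, assign_causal_genes(m, ar1, seed = 1), ar1, seed = s)
    betas <- c(betas, ef$beta[ef$causal])
    hets <- c(hets, p$maf[ef$causal] * (1 - p$maf[ef$causal]))
  }
  fit <- lm(betas^2 ~ hets)
  expect_lt(abs(coef(fit)[2]) * mean(hets) / mean(betas^2), 0.15)

  ## general alpha: log variance binned by p(1-p) has slope 1 + alpha
  for (alpha in c(-0.37, 0)) {
    ar <- architecture_params(alpha = alpha, r = 0, prop_causal_genes = 1,
                              shared_causal_fraction = 1,
                              prop_causal_variants = 1)
    betas <- numeric(0); hets <- numeric(0)
    for (s in 1:5) {
      ef <- draw_effects(p, assign_causal_genes(m, ar, seed = 1), ar, seed = s)
      betas <- c(betas, ef$beta[ef$causal])
      hets <- c(hets, p$maf[ef$causal] * (1 - p$maf[ef$causal]))
    }
    bins <- cut(log(hets), breaks = 8)
    lv <- tapply(betas^2, bins, function(x) log(mean(x)))
    lh <- tapply(log(hets), bins, mean)
    slope <- coef(lm(lv ~ lh))[2]
    expect_equal(unname(slope), 1 + alpha, tolerance = 0.15)
  }
})

test_that("LD-dependent mode (r = 1) downweights high-LD variants", {
  m <- build_genome_map(100, 1, 5, 0, seed = 27)
  p <- simulate_genotypes(m, 600, seed = 28)
  ar <- architecture_params(alpha = -1, r = 1, prop_causal_genes = 1,
                            shared_causal_fraction = 1,
                            prop_causal_variants = 1)
  cs <- assign_causal_genes(m, ar, seed = 1)
  betas <- numeric(0); lds <- numeric(0)
  for (s in 1:12) {
    ef <- draw_effects(p, cs, ar, seed = s)
    betas <- c(betas, ef$beta[ef$causal])
    lds <- c(lds, compute_ld_scores(p)[ef$causal])
  }
  ## with alpha = -1 the only variance driver is (1/(1+l))^1
  ratio <- betas^2 * (1 + lds)
  gp <- lds > median(lds)
  expect_equal(mean(ratio[gp]) / mean(ratio[!gp]), 1, tolerance = 0.25)
})

test_that("phenotypes hit the target heritability exactly and are standardized", {
  ar <- architecture_params(h2_trait = 0.3, prop_causal_genes = 0.2)
  co <- simulate_cohort(ar, 4000, n_blocks = 30, genes_per_block = 2,
                        n_common_per_gene = 3, n_rare_per_gene = 4, seed = 5)
  y <- co$phenotype$y
  expect_equal(mean(y), 0, tolerance = 1e-10)
  expect_equal(var(y), 1, tolerance = 1e-10)
  ## realized genetic variance share
  expect_equal(var(co$phenotype$genetic) / var(y), 0.3, tolerance = 0.02)
  ## determinism
  co2 <- simulate_cohort(ar, 4000, n_blocks = 30, genes_per_block = 2,
                         n_common_per_gene = 3, n_rare_per_gene = 4, seed = 5)
  expect_identical(co$phenotype$y, co2$phenotype$y)
})

test_that("null phenotypes are uncorrelated with the genotypes", {
  co <- tiny_cohort(n = 900)
  ar0 <- architecture_params(h2_trait = 0)
  cs <- assign_causal_genes(co$map, ar0, seed = 1)
  ef <- draw_effects(co$panel, cs, ar0, seed = 2)
  ph <- simulate_phenotype(co$panel, ef, ar0, seed = 3)
  poly <- which(!co$panel$monomorphic)
  cors <- cor(ph$y, co$panel$G[, poly])
  expect_lt(max(abs(cors)), 4 / sqrt(900))
})
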