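test_that("dosages are 0/1/2 with frequencies near their targets", {
  m <- build_genome_map(10, 2, 4, 6, seed = 21)
  p <- simulate_genotypes(m, 2000, seed = 22)
  expect_true(all(p$G %in% 0:2))
  expect_equal(dim(p$G), c(2000, nrow(m$variants)))
  cm <- m$variants$class == "common"
  ## realized common frequencies track targets within binomial error
  se <- sqrt(p$target_maf * (1 - p$target_maf) / (2 * 2000))
  expect_gt(mean(abs(p$freq[cm] - p$target_maf[cm]) < 4 * se[cm]), 0.95)
  ## spectrum split: common at or above split minus sampling error, rare below
  expect_true(all(p$maf[cm] >= m$maf_split - 2 * se[cm]))
  rr <- !cm
  expect_true(all(p$maf[rr] < m$maf_split + 2 * se[rr]))
  ## monomorphic flag matches the matrix
  expect_equal(unname(p$monomorphic), unname(apply(p$G, 2, var) == 0))
})

test_that("two individuals and one variant give a 2x1 dosage matrix", {
  m <- build_genome_map(1, 1, 1, 0, seed = 1)
  p <- simulate_genotypes(m, 2, seed = 2)
  expect_equal(dim(p$G), c(2, 1))
  expect_true(all(p$G %in% 0:2))
})

test_that("same seed reproduces the panel exactly", {
  m <- build_genome_map(5, 2, 3, 4, seed = 31)
  p1 <- simulate_genotypes(m, 300, seed = 7)
  p2 <- simulate_genotypes(m, 300, seed = 7)
  expect_identical(p1$G, p2$G)
  expect_identical(p1$target_maf, p2$target_maf)
})

test_that("within-block common variants correlate; across blocks they do not", {
  m <- build_genome_map(50, 1, 2, 0, seed = 41)
  p <- simulate_genotypes(m, 5000, seed = 42)
  v <- m$variants
  ## 50 within-block pairs: all correlations should be clearly positive
  within <- vapply(seq_len(50), function(b) {
    idx <- which(v$block_id == b)
    cor(p$G[, idx[1]], p$G[, idx[2]])
  }, numeric(1))
  expect_gt(mean(within), 0.1)
  expect_gt(quantile(within, 0.01), 0)
  ## 100 across-block pairs: mean |cor| within sampling error of zero
  set.seed(1)
  across <- replicate(100, {
    b <- sample(50, 2)
    cor(p$G[, which(v$block_id == b[1])[1]], p$G[, which(v$block_id == b[2])[1]])
  })
  expect_lte(mean(abs(across)), 0.05)
})

test_that("LD scores equal the brute-force sum of squared correlations", {
  m <- build_genome_map(3, 1, 5, 0, seed = 51)
  p <- simulate_genotypes(m, 400, seed = 52)
  l <- compute_ld_scores(p)
  v <- m$variants
  for (b in 1:3) {
    idx <- which(v$block_id == b)
    R <- cor(p$G[, idx])
    expect_equal(l[idx], unname(rowSums(R^2)), tolerance = 1e-10)
  }
  expect_true(all(l >= 1 - 1e-8, na.rm = TRUE))
})

test_that("LD score limiting cases: singleton block and duplicated variant", {
  m <- build_genome_map(2, 1, 1, 0, seed = 61)
  p <- simulate_genotypes(m, 200, seed = 62)
  expect_equal(compute_ld_scores(p), c(1, 1))
  ## duplicate one column inside a two-variant block
  m2 <- build_genome_map(1, 1, 2, 0, seed = 63)
  p2 <- simulate_genotypes(m2, 200, seed = 64)
  p2$G[, 2] <- p2$G[, 1]
  expect_equal(compute_ld_scores(p2), c(2, 2))
  ## monomorphic variants carry NA
  p2$G[, 2] <- 0L
  p2$monomorphic[2] <- TRUE
  l <- compute_ld_scores(p2)
  expect_true(is.na(l[2]))
  expect_equal(l[1], 1)
})

test_that("decorrelation permutes rare columns only, preserving margins", {
  m <- build_genome_map(8, 2, 3, 5, seed = 71)
  p <- simulate_genotypes(m, 1500, seed = 72)
  d <- decorrelate_rare(p, seed = 73)
  cm <- which(m$variants$class == "common")
  rr <- which(m$variants$class == "rare")
  expect_identical(p$G[, cm], d$G[, cm])
  ## columnwise multisets preserved
  expect_equal(colSums(p$G[, rr]), colSums(d$G[, rr]))
  expect_identical(p$freq, d$freq)
  expect_true(d$decorrelated)
  ## at least some rare columns actually moved
  expect_gt(sum(p$G[, rr] != d$G[, rr]), 0)
})

test_that("after shuffling, rare variants are uncorrelated with same-gene common ones", {
  m <- build_genome_map(50, 1, 2, 2, seed = 81)
  p <- simulate_genotypes(m, 5000, seed = 82)
  d <- decorrelate_rare(p, seed = 83)
  v <- m$variants
  pairs <- do.call(rbind, lapply(unique(v$gene_id), function(g) {
    idx <- which(v$gene_id == g)
    expand.grid(c = idx[v$class[idx] == "common"],
                r = idx[v$class[idx] == "rare"])
  }))
  keep <- !p$monomorphic[pairs$c] & !p$monomorphic[pairs$r]
  pairs <- pairs[keep, ][seq_len(min(100, sum(keep))), ]
  cors <- mapply(function(i, j) cor(d$G[, i], d$G[, j]), pairs$c, pairs$r)
  expect_lte(mean(abs(cors)), 0.03)
})

test_that("cohort wrapper is seed-deterministic end to end", {
  ar <- architecture_params()
  co1 <- simulate_cohort(ar, 250, n_blocks = 6, genes_per_block = 2,
                         n_common_per_gene = 3, n_rare_per_gene = 4, seed = 9)
  co2 <- simulate_cohort(ar, 250, n_blocks = 6, genes_per_block = 2,
                         n_common_per_gene = 3, n_rare_per_gene = 4, seed = 9)
  expect_identical(co1$panel$G, co2$panel$G)
  expect_identical(co1$phenotype$y, co2$phenotype$y)
  expect_identical(co1$effects$beta, co2$effects$beta)
})

test_that("cohorts write out as plain-text artifacts", {
  ar <- architecture_params(prop_causal_genes = 0.5)
  co <- simulate_cohort(ar, 120, n_blocks = 4, genes_per_block = 1,
                        n_common_per_gene = 2, n_rare_per_gene = 3, seed = 3)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "variants.tsv")))
  v <- read.delim(file.path(d, "variants.tsv"))
  expect_equal(nrow(v), 20)
  g <- read.delim(file.path(d, "genotypes.tsv"), comment.char = "#")
  expect_equal(dim(g), c(120, 20))
  ph <- read.delim(file.path(d, "phenotype.tsv"))
  expect_equal(ph$y, co$phenotype$y, tolerance = 1e-6)
})
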