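## A compact cohort with a known gene/category layout for the rare tests.
rare_fixture <- function(n = 900, seed = 201) {
  map <- build_genome_map(12, 1, 1, 8, seed = seed)
  panel <- simulate_genotypes(map, n, seed = seed + 1)
  list(map = map, panel = panel)
}

test_that("single-variant gene: SKAT equals the squared-score test", {
  fx <- rare_fixture()
  v <- fx$map$variants
  set.seed(7); y <- rnorm(fx$panel$n)
  done <- 0
  for (g in fx$map$genes$gene_id) {
    for (ct in c("pLoF", "missense_LC", "synonymous")) {
      idx <- which(v$gene_id == g & v$class == "rare" & v$category == ct &
                     !fx$panel$monomorphic)
      if (length(idx) != 1L) next
      p_skat <- skat_test(fx$panel, y, g, ct, weights = 1)
      ## independent oracle: score test U^2 / (sigma2 * Sxx) ~ chisq(1)
      x <- fx$panel$G[, idx]; xc <- x - mean(x)
      res <- y - mean(y)
      s2 <- sum(res^2) / (length(y) - 1)
      stat <- sum(xc * res)^2 / (s2 * sum(xc^2))
      expect_equal(as.numeric(p_skat), pchisq(stat, 1, lower.tail = FALSE),
                   tolerance = 1e-6)
      ## burden with unit weight equals the plain regression p
      p_b <- burden_test(fx$panel, y, g, ct, weights = 1)
      oracle <- summary(lm(y ~ x))$coefficients[2, 4]
      expect_equal(as.numeric(p_b), oracle, tolerance = 1e-9)
      done <- done + 1
    }
  }
  expect_gte(done, 3)
})

test_that("a phenotype equal to the burden score drives p to the floor", {
  fx <- rare_fixture()
  g <- fx$map$genes$gene_id[1]
  v <- fx$map$variants
  idx <- which(v$gene_id == g & v$class == "rare" & !fx$panel$monomorphic)
  ct <- v$category[idx[1]]
  idx <- idx[v$category[idx] == ct]
  w <- rare_weights(fx$panel$maf[idx])
  y <- drop(fx$panel$G[, idx, drop = FALSE] %*% w)
  expect_lt(as.numeric(burden_test(fx$panel, y, g, ct)), 1e-200)
})

test_that("SKAT-O limiting cases match SKAT and the squared burden", {
  fx <- rare_fixture()
  set.seed(9); y <- rnorm(fx$panel$n)
  v <- fx$map$variants
  checked <- 0
  for (g in fx$map$genes$gene_id) {
    for (ct in c("missense_LC", "synonymous")) {
      idx <- which(v$gene_id == g & v$class == "rare" & v$category == ct &
                     !fx$panel$monomorphic)
      if (length(idx) < 2L) next
      p0 <- skato_test(fx$panel, y, g, ct, rho_grid = 0)
      expect_equal(as.numeric(p0), as.numeric(skat_test(fx$panel, y, g, ct)),
                   tolerance = 1e-10)
      ## rho = 1: squared burden score with the Beta weights
      p1 <- skato_test(fx$panel, y, g, ct, rho_grid = 1)
      w <- rare_weights(fx$panel$maf[idx])
      sc <- drop(fx$panel$G[, idx, drop = FALSE] %*% w)
      sc <- sc - mean(sc)
      res <- y - mean(y)
      s2 <- sum(res^2) / (length(y) - 1)
      stat <- sum(sc * res)^2 / (s2 * sum(sc^2))
      expect_equal(as.numeric(p1), pchisq(stat, 1, lower.tail = FALSE),
                   tolerance = 1e-6)
      ## the omnibus p is never much smaller than the best single rho
      pfull <- skato_test(fx$panel, y, g, ct)
      expect_gt(as.numeric(pfull), 0)
      expect_lte(as.numeric(pfull),
                 min(as.numeric(p0), as.numeric(p1)) * 8 + 1e-12)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 4)
})

test_that("duplicating a variant column doubles the SKAT quadratic form", {
  fx <- rare_fixture()
  set.seed(11); y <- rnorm(fx$panel$n)
  res <- y - mean(y); rs <- res / sqrt(sum(res^2) / (length(y) - 1))
  v <- fx$map$variants
  idx <- which(v$gene_id == fx$map$genes$gene_id[2] & v$class == "rare" &
                 !fx$panel$monomorphic)[1:2]
  A1 <- scale(fx$panel$G[, idx, drop = FALSE], scale = FALSE)
  Q1 <- sum(drop(crossprod(A1, rs))^2)
  A2 <- cbind(A1, A1)
  Q2 <- sum(drop(crossprod(A2, rs))^2)
  expect_equal(Q2, 2 * Q1, tolerance = 1e-12)
})

test_that("degenerate inputs give flagged missing p-values", {
  fx <- rare_fixture()
  set.seed(13); y <- rnorm(fx$panel$n)
  ## a category with no variants in the gene
  v <- fx$map$variants
  g <- fx$map$genes$gene_id[3]
  cats <- unique(v$category[v$gene_id == g & v$class == "rare"])
  missing_cat <- setdiff(c("pLoF", "missense_LC", "synonymous"), cats)
  if (length(missing_cat)) {
    p <- burden_test(fx$panel, y, g, missing_cat[1])
    expect_true(is.na(p))
    expect_match(attr(p, "reason"), "no polymorphic")
  }
  ## zero-variance burden: make a monomorphic-only gene
  panel <- fx$panel
  idx <- which(v$gene_id == g & v$class == "rare")
  panel$G[, idx] <- 0L
  panel$monomorphic[idx] <- TRUE
  expect_true(is.na(burden_test(panel, y, g, NA)))
})

test_that("P_rare is the minimum over available tests, ties flagged", {
  cm <- combine_rare(c(a = 0.2, b = 0.03, c = 0.5, d = 0.7, e = 0.04,
                       f = 0.9))
  expect_equal(cm$p_rare, 0.03)
  expect_equal(cm$n_tests, 6L)
  expect_false(cm$tie)
  expect_equal(cm$which, "b")
  expect_equal(combine_rare(c(NA, 0.4, NA))$p_rare, 0.4)
  expect_equal(combine_rare(c(NA, 0.4, NA))$n_tests, 1L)
  tied <- combine_rare(c(0.1, 0.1, 0.5))
  expect_true(tied$tie)
  expect_equal(tied$p_rare, 0.1)
  allna <- combine_rare(c(NA_real_, NA_real_))
  expect_true(is.na(allna$p_rare))
  ## Bonferroni-style sensitivity variant
  expect_equal(combine_rare(c(0.02, 0.5, 0.9), adjust = TRUE)$p_rare, 0.06)
})

test_that("the assembled gene table is consistent with its audit columns", {
  ar <- architecture_params(prop_causal_genes = 0.3)
  co <- simulate_cohort(ar, 500, n_blocks = 10, genes_per_block = 2,
                        n_common_per_gene = 3, n_rare_per_gene = 6, seed = 33)
  g <- gene_assoc_table(co$panel, co$phenotype)
  expect_equal(nrow(g), 20)
  audit <- as.matrix(g[, grep("^p_(burden|skato)_", names(g))])
  for (i in seq_len(nrow(g))) {
    avail <- audit[i, !is.na(audit[i, ])]
    if (length(avail)) expect_equal(g$p_rare[i], min(avail))
    else expect_true(is.na(g$p_rare[i]))
  }
  expect_true(all(g$p_common > 0 & g$p_common <= 1, na.rm = TRUE))
})
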