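test_that("clumping keeps the smallest p-product per block, tie-broken by id", {
  genes <- data.frame(
    gene_id = c("g2", "g1", "g3", "g4", "g6", "g5"),
    block_id = c(1, 1, 2, 2, 3, 3),
    p_common = c(1e-8, 1e-4, 0.2, 0.1, 0.5, 0.5),
    p_rare   = c(0.5,  1e-4, 0.3, 0.6, 0.2, 0.2))
  cl <- clump(genes)
  ## block 1: product 5e-9 (g2) beats 1e-8 (g1)
  expect_equal(cl$gene_id[cl$block_id == 1], "g2")
  ## block 2: 0.2*0.3 == 0.1*0.6, tie -> lexicographically smaller g3
  expect_equal(cl$gene_id[cl$block_id == 2], "g3")
  expect_true(cl$tie[cl$block_id == 2])
  ## block 3: tie again -> g5
  expect_equal(cl$gene_id[cl$block_id == 3], "g5")
  expect_equal(nrow(cl), 3)
})

test_that("clump handles ties deterministically and flags them", {
  genes <- data.frame(gene_id = c("gB", "gA"), block_id = c(1, 1),
                      p_common = c(0.2, 0.1), p_rare = c(0.3, 0.6))
  cl <- clump(genes)   # identical products 0.06
  expect_equal(cl$gene_id, "gA")
  expect_true(cl$tie)
  ## already one gene per block: identity apart from the tie column
  one <- data.frame(gene_id = c("g1", "g2"), block_id = c(1, 2),
                    p_common = c(0.5, 0.1), p_rare = c(0.2, 0.9))
  cl1 <- clump(one)
  expect_equal(cl1[order(cl1$block_id), c("gene_id", "p_common", "p_rare")],
               one[, c("gene_id", "p_common", "p_rare")],
               ignore_attr = TRUE)
  expect_false(any(cl1$tie))
})

test_that("clumping uses log-space products so extreme p-values cannot underflow", {
  genes <- data.frame(gene_id = c("g1", "g2"), block_id = c(1, 1),
                      p_common = c(1e-250, 1e-250), p_rare = c(1e-100, 1e-90))
  expect_equal(clump(genes)$gene_id, "g1")  # product underflows to 0 either way
})

test_that("build_table counts obey a + b = a + c = k and d = n - 2k + a", {
  tab <- build_table(gene_table_with_overlap(1000, 100, 26), k = 100)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(26, 74, 74, 826))
  tab2 <- build_table(gene_table_with_overlap(200, 50, 50), k = 50)
  expect_equal(c(tab2$a, tab2$b, tab2$c, tab2$d), c(50, 0, 0, 150))
  expect_equal(cohen_kappa(tab2)$kappa, 1)
  set.seed(2)
  for (i in 1:20) {
    n <- sample(30:300, 1); k <- sample(5:(n %/% 3), 1)
    tab <- build_table(null_gene_table(n), k)
    expect_equal(tab$a + tab$b, k)
    expect_equal(tab$a + tab$c, k)
    expect_equal(tab$d, n - 2 * k + tab$a)
  }
  expect_error(build_table(null_gene_table(10), 11), "exceeds")
})

test_that("build_table flags ties straddling the k-th rank", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      block_id = 1:4,
                      p_common = c(0.1, 0.2, 0.2, 0.9),
                      p_rare = c(0.1, 0.3, 0.5, 0.9))
  tab <- build_table(genes, 2)
  expect_true(attr(tab, "tie_common"))
  expect_false(attr(tab, "tie_rare"))
})

test_that("the corac fit exposes estimates, table and methods coherently", {
  set.seed(7)
  genes <- null_gene_table(200)
  genes$block_id <- rep(1:100, each = 2)
  fit <- corac(genes, k = 10, bootstrap = 50, seed = 3)
  expect_s3_class(fit, "corac")
  expect_equal(fit$n, 100)
  expect_equal(unname(coef(fit)["kappa"]), fit$kappa)
  expect_equal(fit$kappa, cohen_kappa(fit$table)$kappa)
  expect_equal(fit$ac1, gwet_ac1(fit$table)$ac1)
  expect_output(print(fit), "kappa")
  expect_output(print(summary(fit)), "Estimates")
  ci <- confint(fit, "kappa")
  expect_equal(dim(ci), c(1L, 2L))
  expect_lte(ci[1, 1], ci[1, 2])
})

test_that("bootstrap is deterministic in the seed and covers its point estimate", {
  set.seed(11)
  genes <- gene_table_with_overlap(300, 30, 12)
  ## jitter so resampled rankings vary
  genes$p_common <- genes$p_common * runif(300, 0.5, 1)
  genes$p_rare <- genes$p_rare * runif(300, 0.5, 1)
  b1 <- bootstrap_agreement(genes, k = 30, B = 200, seed = 5)
  b2 <- bootstrap_agreement(genes, k = 30, B = 200, seed = 5)
  expect_identical(b1$kappa$ci, b2$kappa$ci)
  expect_identical(b1$replicates$kappa, b2$replicates$kappa)
  expect_gte(b1$kappa$estimate, b1$kappa$ci[1])
  expect_lte(b1$kappa$estimate, b1$kappa$ci[2])
})

test_that("bootstrap of a degenerate two-gene table has zero CI width", {
  genes <- data.frame(gene_id = c("g1", "g2"), block_id = 1:2,
                      p_common = c(0.01, 0.9), p_rare = c(0.02, 0.8))
  b <- bootstrap_agreement(genes, k = 1, B = 100, seed = 2)
  expect_equal(diff(b$kappa$ci), 0)
})

test_that("bootstrap standard error shrinks roughly like 1/sqrt(n)", {
  make <- function(n) {
    set.seed(n)
    g <- null_gene_table(n)
    ## induce mild dependence so kappa is non-degenerate
    g$p_rare <- pmin(1, pmax(1e-9, g$p_common * exp(rnorm(n, 0, 2))))
    g
  }
  se200 <- bootstrap_agreement(make(200), k = 20, B = 300, seed = 9)$kappa$se
  se800 <- bootstrap_agreement(make(800), k = 80, B = 300, seed = 9)$kappa$se
  expect_lt(se800, se200)
  expect_lt(se800, se200 / 1.3)  # about halving expected at 4x n
})

test_that("gene tables round-trip through TSV and validate on read", {
  g <- gene_table_with_overlap(20, 5, 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(g, f)
  g2 <- read_gene_table(f)
  expect_equal(g2$gene_id, g$gene_id)
  expect_equal(g2$p_common, g$p_common, tolerance = 1e-12)
  bad <- g; bad$p_common[1] <- 2
  expect_error(clump(bad), "0, 1")
})
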