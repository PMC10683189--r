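## Shared fixtures, built in code. Heavy sweep results are memoized within a
## session so several tests can share one computation.

## A gene table with prescribed top-k overlap between the two rankings:
## genes 1..k are top-common; of those the first `overlap` are also
## top-rare, the rare list being completed by genes k+1, ..., 2k-overlap.
gene_table_with_overlap <- function(n, k, overlap) {
  stopifnot(overlap <= k, 2 * k - overlap <= n)
  p_common <- seq_len(n) / (n + 1)
  rare_rank <- rep(NA_integer_, n)
  rare_top <- c(seq_len(overlap), k + seq_len(k - overlap))
  rare_rank[rare_top] <- seq_len(k)
  rare_rank[is.na(rare_rank)] <- k + seq_len(n - k)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             block_id = seq_len(n),
             p_common = p_common,
             p_rare = rare_rank / (n + 1),
             stringsAsFactors = FALSE)
}

## Random-ranking gene table (independent p-value columns).
null_gene_table <- function(n) {
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             block_id = seq_len(n),
             p_common = stats::runif(n),
             p_rare = stats::runif(n),
             stringsAsFactors = FALSE)
}

## Small cohort reused by several association tests.
tiny_cohort <- function(n = 600, n_blocks = 20, genes_per_block = 2,
                        n_common = 3, n_rare = 6, seed = 101) {
  map <- build_genome_map(n_blocks, genes_per_block, n_common, n_rare,
                          seed = seed)
  panel <- simulate_genotypes(map, n, seed = seed + 1)
  list(map = map, panel = panel)
}

## Memoized sweep runs for the acceptance tests; key -> data frame.
.sweep_cache <- new.env(parent = emptyenv())

cached_sweep <- function(key, expr) {
  if (!exists(key, envir = .sweep_cache))
    assign(key, expr, envir = .sweep_cache)
  get(key, envir = .sweep_cache)
}

## The suite's standard master seed for stochastic checks.
SUITE_SEED <- 20260921L
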