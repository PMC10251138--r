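test_that("a perfect diagonal of hits chains into one same-orientation block", {
  ga <- toy_genome("a", genes_per_chrom = 10)
  gb <- toy_genome("b", genes_per_chrom = 10)
  h <- toy_hits(ga$genes$id[1:5], gb$genes$id[1:5])
  bl <- chain_collinear_blocks(h, ga, gb, max_gap = 50, min_anchors = 5)
  expect_length(bl, 1L)
  expect_equal(nrow(bl[[1]]$anchors), 5L)
  expect_equal(bl[[1]]$orientation, "same")
})

test_that("a gap of 51 genes splits a chain at the max_gap=50 boundary", {
  ga <- toy_genome("a", genes_per_chrom = 120)
  gb <- toy_genome("b", genes_per_chrom = 120)
  idx <- c(1:5, 57:61)  # gap of 51 intervening genes between 5 and 57
  h <- toy_hits(ga$genes$id[idx], gb$genes$id[idx])
  bl <- chain_collinear_blocks(h, ga, gb, max_gap = 50, min_anchors = 5)
  expect_length(bl, 2L)
  expect_equal(sort(vapply(bl, function(b) nrow(b$anchors), integer(1))),
               c(5L, 5L))
  # with the gap allowed, one block
  bl2 <- chain_collinear_blocks(h, ga, gb, max_gap = 51, min_anchors = 5)
  expect_length(bl2, 1L)
})

test_that("each extracted block is a longest chain on the remaining hits", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 60
    ga <- toy_genome("a", genes_per_chrom = n)
    gb <- toy_genome("b", genes_per_chrom = n)
    perm <- sample(n)
    h <- toy_hits(ga$genes$id, gb$genes$id[perm])
    max_gap <- 10; min_anchors <- 3
    bl <- chain_collinear_blocks(h, ga, gb, max_gap = max_gap,
                                 min_anchors = min_anchors)
    # replay the greedy extraction against the brute-force oracle: every
    # block must be a longest valid chain on the hits left at its turn
    remaining <- data.frame(qi = seq_len(n) - 1L, si = perm - 1L)
    for (b in bl) {
      expect_equal(nrow(b$anchors),
                   oracle_longest_chain(remaining$qi, remaining$si, max_gap))
      expect_block_invariants(b, max_gap, min_anchors)
      drop <- paste(b$anchors$order_a, b$anchors$order_b)
      remaining <- remaining[!paste(remaining$qi, remaining$si) %in% drop, ,
                             drop = FALSE]
    }
    # nothing chainable above the reporting threshold is left behind
    expect_lt(oracle_longest_chain(remaining$qi, remaining$si, max_gap),
              min_anchors)
  }
})

test_that("every returned block satisfies the monotone-chain invariants", {
  cfg <- sim_config(seed = 3, n_chrom = 2, genes_per_chrom = 80,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0.1, b = 0.25, c = 0.4),
                                      p = 0.29))
  sim <- simulate_paleogenomes(cfg)
  h <- filter_hits(sim$hits)
  bl <- chain_collinear_blocks(h, sim$genomes$ref, sim$genomes$hexa)
  expect_gt(length(bl), 0L)
  for (b in bl) expect_block_invariants(b, 50, 5)
})

test_that("chaining is symmetric: B-vs-A returns transposed anchor lists", {
  ga <- toy_genome("a", genes_per_chrom = 30)
  gb <- toy_genome("b", genes_per_chrom = 30)
  set.seed(9)
  idx <- sort(sample(30, 12))
  h <- toy_hits(ga$genes$id[idx], gb$genes$id[idx])
  ab <- chain_collinear_blocks(h, ga, gb, min_anchors = 5)
  ba <- chain_collinear_blocks(h, gb, ga, min_anchors = 5)
  expect_equal(length(ab), length(ba))
  expect_equal(ab[[1]]$anchors$gene_a, ba[[1]]$anchors$gene_b)
  expect_equal(ab[[1]]$anchors$gene_b, ba[[1]]$anchors$gene_a)
})

test_that("zero-loss triplication gives one all-gene block per descended pair", {
  cfg <- sim_config(seed = 5, n_chrom = 2, genes_per_chrom = 50,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0, b = 0, c = 0), p = 0.29),
                    noise_hit_rate = 0)
  sim <- simulate_paleogenomes(cfg)
  bl <- chain_collinear_blocks(sim$hits, sim$genomes$ref, sim$genomes$hexa)
  # 2 ancestral chromosomes x 3 copies, each fully covered
  expect_length(bl, 6L)
  expect_true(all(vapply(bl, function(b) nrow(b$anchors), integer(1)) == 50L))
})

test_that("orthology depth ratios reflect ploidy (1:3 triplication, 1:2 WGD)", {
  cfg <- sim_config(seed = 5, n_chrom = 2, genes_per_chrom = 50,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0, b = 0, c = 0), p = 0.29),
                    noise_hit_rate = 0)
  sim <- simulate_paleogenomes(cfg)
  bl <- chain_collinear_blocks(sim$hits, sim$genomes$ref, sim$genomes$hexa)
  dr <- block_depth_ratio(bl, sim$genomes$ref, sim$genomes$hexa)
  expect_equal(dr$ratio, "1:3")
  # direct brute-force coverage count on the reference side
  ref <- sim$genomes$ref$genes
  cov <- integer(nrow(ref))
  for (b in bl) {
    sel <- ref$chrom == b$chrom_a &
      ref$order_index >= min(b$anchors$order_a) &
      ref$order_index <= max(b$anchors$order_a)
    cov[sel] <- cov[sel] + 1L
  }
  expect_equal(dr$d_query, as.integer(names(which.max(table(cov[cov > 0])))))

  expect_equal(block_depth_ratio(list(), sim$genomes$ref,
                                 sim$genomes$hexa)$flag, "no_blocks")
})

test_that("unknown gene ids in hits are reported by id", {
  ga <- toy_genome("a"); gb <- toy_genome("b")
  h <- toy_hits("nonexistent_gene", gb$genes$id[1])
  expect_error(chain_collinear_blocks(h, ga, gb), "nonexistent_gene")
})
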