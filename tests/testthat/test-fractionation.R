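test_that("retention windows count non-dot cells per slot", {
  cells <- cbind(s1 = rep("g", 100),
                 s2 = rep(c("g", "."), 50))
  chrom <- rep("c1", 100)
  prof <- retention_profile(cells, chrom, window = 50, step = 25)
  expect_true(all(prof$s1 == 50))
  expect_true(all(prof$s2 == 25))
  expect_true(all(is.na(prof$flag)))
  # short chromosome: one truncated, flagged window
  short <- retention_profile(cells[1:20, , drop = FALSE], chrom[1:20],
                             window = 50)
  expect_equal(nrow(short), 1L)
  expect_equal(short$flag, "truncated_window")
  expect_equal(short$end_index, 20L)
})

test_that("mean retention ordering follows configured slot loss rates", {
  set.seed(3)
  n <- 600
  cells <- cbind(s1 = ifelse(runif(n) < 0.2, ".", "g"),
                 s2 = ifelse(runif(n) < 0.4, ".", "g"),
                 s3 = ifelse(runif(n) < 0.6, ".", "g"))
  prof <- retention_profile(cells, rep(c("c1", "c2"), each = n / 2))
  expect_true(mean(prof$s1) > mean(prof$s2))
  expect_true(mean(prof$s2) > mean(prof$s3))
})

test_that("loss runs are maximal dot runs broken at chromosome ends", {
  col <- c("g", ".", "g", "g", ".", ".", ".", "g", ".")
  expect_equal(sort(loss_runs(col)), c(1L, 1L, 3L))
  expect_equal(loss_runs(rep("g", 5)), integer(0))
  expect_equal(loss_runs(rep(".", 7)), 7L)
  # a run spanning a chromosome boundary is split
  col2 <- rep(".", 6)
  expect_equal(loss_runs(col2, chrom = rep(c("a", "b"), each = 3)),
               c(3L, 3L))
  # lengths sum to the dot count
  set.seed(1)
  col3 <- ifelse(runif(200) < 0.3, ".", "g")
  expect_equal(sum(loss_runs(col3)), sum(col3 == "."))
})

test_that("geometric fit recovers p exactly from exact frequencies", {
  freq <- 0.5^(1:12)
  names(freq) <- 1:12
  fit <- fit_geometric(freq = freq)
  expect_equal(fit$p, 0.5, tolerance = 1e-6)

  fit1 <- fit_geometric(rep(1L, 30))
  expect_equal(fit1$p, 1)
  expect_equal(fit1$flag, "degenerate")
})

test_that("geometric fit recovers p = 0.29 within 0.02 and matches the MLE", {
  set.seed(5)
  runs <- rgeom(10000, 0.29) + 1L
  fit <- fit_geometric(runs)
  expect_lt(abs(fit$p - 0.29), 0.02)
  expect_lt(abs(fit$p_mle - 1 / mean(runs)), 1e-12)
  expect_lt(abs(fit$p - fit$p_mle), 0.02)
  expect_gt(fit$r_squared, 0.95)
  expect_lt(fit$f_test_p, 0.01)
})

test_that("geometric recovery error shrinks with sample size", {
  errs <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n)
    median(vapply(1:5, function(i)
      abs(fit_geometric(rgeom(n, 0.29) + 1L)$p - 0.29), numeric(1)))
  }, numeric(1))
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("subgenome labels rank copies by retention with stable ties", {
  ret <- data.frame(region = "r1", copy = c("A", "B", "C"),
                    retained = c(216, 169, 106))
  lab <- assign_subgenomes(ret)$regions
  expect_equal(lab$label[match(c("A", "B", "C"), lab$copy)],
               c("LF", "MF1", "MF2"))
  # ties resolved deterministically (chromosome totals then lexicographic)
  tie <- data.frame(region = "r1", copy = c("A", "B", "C"),
                    retained = c(10, 10, 10),
                    chrom = c("c1", "c2", "c3"))
  l1 <- assign_subgenomes(tie)$regions
  l2 <- assign_subgenomes(tie[c(3, 1, 2), ])$regions
  expect_true(all(l1$tie))
  expect_equal(l1$label[match(l2$copy, l1$copy)], l2$label)
  # labels are always a permutation of LF/MF1/MF2
  set.seed(2)
  for (i in 1:20) {
    r <- data.frame(region = "r", copy = c("x", "y", "z"),
                    retained = sample(0:50, 3, replace = TRUE))
    expect_setequal(assign_subgenomes(r)$regions$label,
                    c("LF", "MF1", "MF2"))
  }
})

test_that("retention divergence test matches the chi-square oracle", {
  t1 <- retention_divergence_test(c(100, 100, 100))
  expect_equal(t1$p_value, 1)
  t2 <- retention_divergence_test(c(106, 216, 169))
  expect_equal(t2$statistic, 37.23, tolerance = 1e-3)
  expect_equal(t2$df, 2L)
  expect_equal(t2$p_value, 8.25e-9, tolerance = 1e-2)
  t3 <- retention_divergence_test(c(0, 300))
  expect_lt(t3$p_value, 1e-60)
  # small counts fall back to the exact multinomial
  t4 <- retention_divergence_test(c(1, 7))
  expect_equal(t4$method, "exact_multinomial")
  expect_equal(t4$p_value, 2 * (dbinom(0, 8, 0.5) + dbinom(1, 8, 0.5)),
               tolerance = 1e-9)
})

test_that("percentage-lost arithmetic reproduces printed worked examples", {
  expect_equal(round(percent_lost(738, 1399), 1), 52.8)
  expect_equal(round(percent_lost(2471, 3868), 1), 63.9)
  expect_equal(round(percent_lost(7779, 23647), 1), 32.9)
})

test_that("P-index is 0 under ties, 1 under total one-sided bias", {
  chrom <- rep(1:4, each = 10)
  A <- rep(20, 40)
  expect_equal(p_index(cbind(A, A), chrom), 0)
  B <- A - 1
  expect_equal(p_index(cbind(A, B), chrom), 1)
})

test_that("P-index is label- and chromosome-order-invariant and in [0,1]", {
  set.seed(6)
  chrom <- rep(1:6, each = 30)
  A <- rbinom(180, 50, 0.7); B <- rbinom(180, 50, 0.5)
  v <- p_index(cbind(A, B), chrom)
  expect_gte(v, 0); expect_lte(v, 1)
  expect_equal(p_index(cbind(B, A), chrom), v)
  o <- order(rep(c(4, 2, 6, 1, 3, 5), each = 30))
  expect_equal(p_index(cbind(A, B)[o, ], chrom[o]), v)
})

test_that("P-index separates biased from balanced loss regimes", {
  set.seed(8)
  chrom <- rep(1:10, each = 50)
  A <- rbinom(500, 50, 1 - 0.15); B <- rbinom(500, 50, 1 - 0.45)
  expect_gt(p_index(cbind(A, B), chrom), 0.3)
  A2 <- rbinom(500, 50, 0.7); B2 <- rbinom(500, 50, 0.7)
  expect_lt(p_index(cbind(A2, B2), chrom), 0.3)
})
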