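kar4 <- function() new_karyotype(list(c("A1", "A2"), c("B1", "B2"),
                                      c("C1", "C2"), c("D1", "D2")))

test_that("fusion, translocation and fission events act on segment lists", {
  k <- kar4()
  eej <- apply_event(k, rearrangement_event("EEJ", a = 1, b = 2))
  expect_length(eej$chromosomes, 3L)
  expect_equal(eej$chromosomes[[3]], c("A1", "A2", "B1", "B2"))

  ncf <- apply_event(k, rearrangement_event("NCF", a = 1, b = 2, pos_a = 1))
  expect_length(ncf$chromosomes, 3L)
  expect_equal(ncf$chromosomes[[3]], c("A1", "B1", "B2", "A2"))
  expect_error(apply_event(k, rearrangement_event("NCF", a = 1, b = 2,
                                                  pos_a = 2)), "EEJ")

  rct <- apply_event(k, rearrangement_event("RCT", a = 1, b = 2,
                                            pos_a = 1, pos_b = 1))
  expect_length(rct$chromosomes, 4L)
  expect_equal(rct$chromosomes[[1]], c("A1", "B2"))
  expect_equal(rct$chromosomes[[2]], c("B1", "A2"))

  nct <- apply_event(k, rearrangement_event("NCT", a = 1, b = 2,
                                            from = 2, to = 2, pos_b = 2))
  expect_equal(nct$chromosomes[[1]], "A1")
  expect_equal(nct$chromosomes[[2]], c("B1", "B2", "A2"))
  expect_error(apply_event(k, rearrangement_event("NCT", a = 1, b = 2,
                                                  from = 1, to = 2,
                                                  pos_b = 0)),
               "whole chromosome")

  fis <- apply_event(k, rearrangement_event("FISSION", a = 1, pos_a = 1))
  expect_length(fis$chromosomes, 5L)
})

test_that("segment multisets are conserved under non-polyploidy events", {
  k <- kar4()
  segs <- sort(paleohexkit:::seg_id(unlist(k$chromosomes)))
  for (ev in list(rearrangement_event("EEJ", a = 1, b = 3, flip = TRUE),
                  rearrangement_event("RCT", a = 2, b = 4, pos_a = 1,
                                      pos_b = 1),
                  rearrangement_event("NCT", a = 1, b = 2, from = 1, to = 1,
                                      pos_b = 1),
                  rearrangement_event("FISSION", a = 3, pos_a = 1))) {
    k2 <- apply_event(k, ev)
    expect_equal(sort(paleohexkit:::seg_id(unlist(k2$chromosomes))), segs)
  }
  wgt <- apply_event(k, rearrangement_event("WGT"))
  expect_length(unlist(wgt$chromosomes), 3L * length(segs))
  wgd <- apply_event(k, rearrangement_event("WGD"))
  expect_length(wgd$chromosomes, 8L)
})

test_that("triplication of a 7-chromosome karyotype gives 21 chromosomes", {
  k7 <- new_karyotype(lapply(1:7, function(i) paste0("G", i)))
  expect_length(apply_event(k7, rearrangement_event("WGT"))$chromosomes, 21L)
})

test_that("chromosome-count arithmetic reproduces known trajectories", {
  expect_equal(chromosome_count_after(21, c(rep("EEJ", 11), "NCF",
                                            rep("RCT", 2), rep("NCT", 3))), 9L)
  expect_equal(chromosome_count_after(27, c(rep("EEJ", 10), rep("NCF", 2),
                                            rep("RCT", 2), rep("NCT", 2))), 15L)
  expect_equal(chromosome_count_after(15, c(rep("EEJ", 5), "NCF", "RCT",
                                            rep("NCT", 4))), 9L)
  expect_equal(chromosome_count_after(15, c("WGD", rep("EEJ", 8),
                                            rep("NCF", 5), rep("RCT", 2),
                                            rep("NCT", 27))), 17L)
  expect_equal(expected_chromosomes(7, c(3, 3)), 63L)
  expect_equal(expected_chromosomes(9, 3), 27L)
  expect_error(chromosome_count_after(2, c("EEJ", "EEJ")), "below 1")
})

test_that("count arithmetic agrees with stepwise event application", {
  set.seed(10)
  for (rep in 1:200) {
    k <- new_karyotype(lapply(1:6, function(i) paste0("S", i, ".", 1:3)))
    kinds <- sample(c("EEJ", "RCT", "NCT", "FISSION", "NCF"), 4,
                    replace = TRUE)
    counts <- table(factor(kinds, levels = c("EEJ", "NCF", "RCT", "NCT",
                                             "FISSION")))
    res <- tryCatch(paleohexkit:::random_events(k, as.list(counts)),
                    error = function(e) NULL)
    if (is.null(res)) next
    applied <- vapply(res$events, `[[`, character(1), "kind")
    expect_length(res$karyotype$chromosomes,
                  chromosome_count_after(6, applied))
  }
})

test_that("junctions shared by all descendants and absent outgroup are ancestral", {
  anc <- kar4()
  fused <- apply_event(anc, rearrangement_event("EEJ", a = 1, b = 2))
  d1 <- fused
  d2 <- apply_event(fused, rearrangement_event("EEJ", a = 1, b = 2))
  shared <- infer_shared_fusions(list(d1 = d1, d2 = d2), anc)
  expect_length(shared, 1L)
  expect_true(grepl("A2", shared) && grepl("B1", shared))
  # a junction in only one descendant is lineage-specific
  only_d2 <- setdiff(paleohexkit:::karyotype_junctions(d2),
                     paleohexkit:::karyotype_junctions(d1))
  expect_false(any(only_d2 %in% shared))
})

test_that("the ancestral karyotype is rebuilt from shared junctions", {
  anc <- kar4()
  shared <- apply_event(apply_event(anc,
                                    rearrangement_event("EEJ", a = 1, b = 2)),
                        rearrangement_event("EEJ", a = 1, b = 2))
  # lineage-specific translocation placed away from the shared junctions
  d1 <- apply_event(shared, rearrangement_event("RCT", a = 1, b = 2,
                                                pos_a = 1, pos_b = 1))
  d2 <- shared
  rec <- reconstruct_ancestral_karyotype(list(d1 = d1, d2 = d2), anc)
  expect_length(rec$karyotype$chromosomes, 2L)
  expect_equal(nrow(rec$events), 2L)
  expect_true(all(rec$events$kind == "EEJ"))
  # no shared junctions: ancestor equals the outgroup state
  e1 <- apply_event(anc, rearrangement_event("EEJ", a = 1, b = 2))
  e2 <- apply_event(anc, rearrangement_event("EEJ", a = 3, b = 4))
  rec2 <- reconstruct_ancestral_karyotype(list(d1 = e1, d2 = e2), anc)
  expect_length(rec2$karyotype$chromosomes, 4L)
  expect_equal(nrow(rec2$events), 0L)
})

test_that("a planted 21-to-9 fusion history is recovered from descendants", {
  set.seed(12)
  k7 <- new_karyotype(lapply(1:7, function(i) paste0("G", i, ".", 1:3)))
  post <- apply_event(k7, rearrangement_event("WGT",
                                              copy_labels = c("a", "b", "c")))
  res <- paleohexkit:::random_events(
    post, list(EEJ = 11, NCF = 1, RCT = 2, NCT = 3))
  stem <- res$karyotype
  expect_length(stem$chromosomes, 9L)
  # descendants acquire lineage-specific fusions that keep old junctions
  d1 <- apply_event(stem, rearrangement_event("EEJ", a = 1, b = 2))
  d2 <- apply_event(stem, rearrangement_event("EEJ", a = 5, b = 7))
  rec <- reconstruct_ancestral_karyotype(list(d1 = d1, d2 = d2), post)
  expect_length(rec$karyotype$chromosomes, 9L)
})

test_that("connection patterns classify inversion, colinearity, separation", {
  cp <- connection_patterns(data.frame(
    copy = c("o", "x", "y", "z"),
    chrom_a = c("c0", "c1", "c2", "c3"),
    chrom_b = c("c0", "c1", "c2", "c9"),
    orient_a = c("+", "+", "-", "+"),
    orient_b = c("+", "-", "-", "+")))
  expect_equal(unname(cp), c("(A)-(B)", "(A)-(-B)", "(A)-(B)", "unlinked"))
})

test_that("two-step order follows the pair sharing the derived pattern", {
  cps <- c(LF = "(A)-(-B)", MF1 = "(A)-(-B)", MF2 = "(A)-(B)")
  res <- two_step_inference(cps, "(A)-(B)")
  expect_equal(res$status, "ok")
  expect_equal(res$first_step, c("LF", "MF1"))
  expect_equal(res$second_step, "MF2")
  # all derived or one derived: uninformative
  allder <- c(LF = "(A)-(-B)", MF1 = "(A)-(-B)", MF2 = "(A)-(-B)")
  expect_equal(two_step_inference(allder, "(A)-(B)")$status, "uninformative")
  oneder <- c(LF = "(A)-(B)", MF1 = "(A)-(B)", MF2 = "(A)-(-B)")
  expect_equal(two_step_inference(oneder, "(A)-(B)")$status, "uninformative")
  expect_equal(two_step_inference(cps, "unlinked")$status,
               "uninformative(outgroup)")
})

test_that("karyotypes round-trip through structured text", {
  k <- new_karyotype(list(c("A1", "-B2", "C3"), c("D4")), name = "t")
  f <- tempfile()
  write_karyotype(k, f)
  k2 <- read_karyotype(f, name = "t")
  expect_equal(k2$chromosomes, k$chromosomes)
})
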