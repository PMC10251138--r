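mk_block <- function(genome_a, genome_b, chrom_a, chrom_b, gene_a, gene_b,
                     order_a, order_b, ks_median = NA_real_) {
  b <- paleohexkit:::new_synteny_block(
    genome_a, genome_b, chrom_a, chrom_b,
    data.frame(gene_a = gene_a, gene_b = gene_b, order_a = order_a,
               order_b = order_b, ks = NA_real_, stringsAsFactors = FALSE),
    "same")
  b$ks_median <- ks_median
  b
}

test_that("blocks classify to the nearest event peak within tolerance", {
  peaks <- data.frame(event = c("ACH", "lsa-han"), mu = c(0.95, 0.56),
                      tol = c(0.3, 0.3))
  b <- mk_block("l", "l", "c1", "c2", "x1", "y1", 0, 0, ks_median = 0.95)
  expect_equal(classify_block_event(b, peaks)$event, "ACH")

  b$ks_median <- (0.95 + 0.56) / 2
  expect_equal(classify_block_event(b, peaks)$event, "unclassified(tie)")

  b$ks_median <- 2.9
  expect_equal(classify_block_event(b, peaks)$event, "unclassified")
})

test_that("event homolog counts pool anchors and deduplicate genes", {
  b1 <- mk_block("l", "l", "c1", "c2", c("a1", "a2", "a3"),
                 c("b1", "b2", "b3"), 0:2, 0:2, 0.95)
  b2 <- mk_block("l", "l", "c1", "c3", c("a1", "a4", "a5"),
                 c("c1", "c2", "c3"), 0:2, 0:2, 0.95)
  b1$event <- b2$event <- "ACH"
  cnt <- count_event_homologs(list(b1, b2), "ACH")
  expect_equal(cnt$n_pairs, 6L)
  expect_equal(cnt$n_genes, 11L)  # a1 shared between the blocks
  expect_equal(count_event_homologs(list(), "ACH"),
               list(n_pairs = 0L, n_genes = 0L))
})

test_that("table layout column counts follow 3 * (1 + sum(3 * 2^N))", {
  g2 <- data.frame(genome = c("lsa", "han"),
                   shared_hexaploidy = TRUE, n_tetraploidies = c(0L, 1L))
  expect_equal(attr(plan_table_layout("vvi", g2), "n_columns"), 30L)
  expect_equal(attr(plan_table_layout("vvi"), "n_columns"), 3L)
  g1 <- data.frame(genome = "lsa", shared_hexaploidy = TRUE,
                   n_tetraploidies = 0L)
  expect_equal(attr(plan_table_layout("vvi", g1), "n_columns"), 12L)
  # property: arbitrary N_g configurations
  for (i in 1:10) {
    ns <- sample(0:3, sample(1:4, 1), replace = TRUE)
    g <- data.frame(genome = paste0("g", seq_along(ns)),
                    shared_hexaploidy = TRUE, n_tetraploidies = ns)
    expect_equal(attr(plan_table_layout("r", g), "n_columns"),
                 3L * (1L + sum(3L * 2L^ns)))
  }
  bad <- data.frame(genome = "x", shared_hexaploidy = FALSE,
                    n_tetraploidies = 0L)
  expect_error(plan_table_layout("r", bad), "hexaploidy")
})

test_that("a reference gene with orthologs in 2 of 3 slots gets one dot", {
  ref <- toy_genome("ref", genes_per_chrom = 10)
  qry <- toy_genome("qry", n_chrom = 3, genes_per_chrom = 10)
  ids <- ref$genes$id
  q <- function(ci) qry$genes$id[qry$genes$chrom == paste0("qry_chr", ci)]
  bl <- list(
    mk_block("ref", "qry", "ref_chr1", "qry_chr1", ids, q(1), 0:9, 0:9, 0.5),
    mk_block("ref", "qry", "ref_chr1", "qry_chr2", ids[1:6], q(2)[1:6],
             0:5, 0:5, 0.5))
  layout <- plan_table_layout("ref", data.frame(
    genome = "qry", shared_hexaploidy = TRUE, n_tetraploidies = 0L))
  tab <- fill_table(layout, ref, bl)
  r8 <- tab[tab$ref_gene == ids[8], ]
  expect_false(r8$qry_p1_s1 == ".")
  expect_equal(r8$qry_p1_s2, ".")
  expect_equal(r8$qry_p1_s3, ".")
  # a gene with no blocks at all is all dots
  expect_true(all(tab[tab$ref_gene == ids[8],
                      c("qry_p1_s2", "qry_p1_s3")] == "."))
})

test_that("table cells reproduce the simulated retention truth", {
  cfg <- sim_config(seed = 11, n_chrom = 2, genes_per_chrom = 100,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0.2, b = 0.35, c = 0.5),
                                      p = 0.29),
                    noise_hit_rate = 0)
  sim <- simulate_paleogenomes(cfg)
  bl <- chain_collinear_blocks(filter_hits(sim$hits), sim$genomes$ref,
                               sim$genomes$hexa)
  kt <- sim$pairs; names(kt)[names(kt) == "ks"] <- "Ks"
  bl <- lapply(bl, annotate_block_ks, cds = kt)
  bl <- classify_blocks(bl, data.frame(event = "DIV", mu = 1.52, tol = 0.4))
  layout <- plan_table_layout("ref", data.frame(
    genome = "hexa", shared_hexaploidy = TRUE, n_tetraploidies = 0L))
  tab <- fill_table(layout, sim$genomes$ref, bl)
  cols <- paste0("hexa_p1_s", 1:3)
  # every filled cell is supported by an anchor of a block
  anchors <- unlist(lapply(bl, function(b) b$anchors$gene_b))
  filled <- unlist(lapply(cols, function(cl) tab[[cl]][tab[[cl]] != "."]))
  expect_true(all(filled %in% anchors))
  # slot identity is region-wise: within each reference chromosome every
  # slot column is pure in one truth subgenome, the three slots cover all
  # three subgenomes, and the cell/dot pattern equals the simulated
  # retention for that subgenome
  truth <- sim$truth$ancestry
  sub_of <- stats::setNames(truth$hex_copy, truth$id)
  for (ch in unique(tab$ref_chrom)) {
    rows <- tab$ref_chrom == ch
    slot_sub <- vapply(cols, function(cl) {
      v <- tab[[cl]][rows]; v <- v[v != "."]
      subs <- unique(sub_of[v])
      expect_length(subs, 1L)   # purity within the chromosome
      subs
    }, character(1))
    expect_setequal(unname(slot_sub), c("a", "b", "c"))
    ref_anc <- sub("^ref_", "", tab$ref_gene[rows])
    for (i in seq_along(cols)) {
      survivors <- truth$id[truth$genome == "hexa" &
                              truth$hex_copy == slot_sub[i] &
                              truth$anc_gene %in% ref_anc]
      expect_setequal(tab[[cols[i]]][rows][tab[[cols[i]]][rows] != "."],
                      survivors)
    }
  }
})

test_that("dots increase monotonically with the simulated loss rate", {
  dot_fraction <- function(loss) {
    cfg <- sim_config(seed = 17, n_chrom = 2, genes_per_chrom = 80,
                      hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                        loss = c(a = loss, b = loss, c = loss),
                                        p = 0.29),
                      noise_hit_rate = 0)
    sim <- simulate_paleogenomes(cfg)
    bl <- chain_collinear_blocks(filter_hits(sim$hits), sim$genomes$ref,
                                 sim$genomes$hexa)
    layout <- plan_table_layout("ref", data.frame(
      genome = "hexa", shared_hexaploidy = TRUE, n_tetraploidies = 0L))
    tab <- fill_table(layout, sim$genomes$ref, bl)
    cols <- paste0("hexa_p1_s", 1:3)
    m <- as.matrix(as.data.frame(tab)[cols])
    mean(m == ".")
  }
  fr <- vapply(c(0.1, 0.3, 0.5), dot_fraction, numeric(1))
  expect_true(all(diff(fr) > 0))
})
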