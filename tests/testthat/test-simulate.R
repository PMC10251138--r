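test_that("triplication without loss conserves every gene in three copies", {
  cfg <- sim_config(seed = 1, n_chrom = 7, genes_per_chrom = 200,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0, b = 0, c = 0), p = 0.29),
                    noise_hit_rate = 0)
  sim <- simulate_paleogenomes(cfg)
  hexa <- sim$genomes$hexa
  expect_equal(length(unique(hexa$genes$chrom)), 21L)
  expect_equal(nrow(hexa$genes), 4200L)
  anc_counts <- table(sim$truth$ancestry$anc_gene[
    sim$truth$ancestry$genome == "hexa"])
  expect_true(all(anc_counts == 3L))
})

test_that("genome-wide retention ordering matches configured loss rates", {
  cfg <- sim_config(seed = 2, n_chrom = 3, genes_per_chrom = 100,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0.2, b = 0.35, c = 0.5),
                                      p = 0.29))
  sim <- simulate_paleogenomes(cfg)
  anc <- sim$truth$ancestry[sim$truth$ancestry$genome == "hexa", ]
  retained <- table(anc$hex_copy)
  expect_true(retained[["a"]] > retained[["b"]])
  expect_true(retained[["b"]] > retained[["c"]])
  expect_equal(unname(sim$truth$subgenome_labels[c("a", "b", "c")]),
               c("LF", "MF1", "MF2"))
})

test_that("the same seed reproduces identical output", {
  cfg <- sim_config(seed = 33, n_chrom = 2, genes_per_chrom = 60,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0.1, b = 0.2, c = 0.3),
                                      p = 0.29))
  s1 <- simulate_paleogenomes(cfg)
  s2 <- simulate_paleogenomes(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("pair Ks values are drawn around the event-node means", {
  cfg <- sim_config(seed = 4, n_chrom = 2, genes_per_chrom = 80,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0, b = 0, c = 0), p = 0.29),
                    ingroup_split = list(ks_mu = 0.56, ks_sigma = 0.05,
                                         names = c("lsa", "han")))
  sim <- simulate_paleogenomes(cfg)
  mu <- tapply(sim$pairs$ks, sim$pairs$event, mean)
  expect_equal(unname(mu["HEX"]), 0.95, tolerance = 0.02)
  expect_equal(unname(mu["SPL"]), 0.56, tolerance = 0.02)
  expect_equal(unname(mu["DIV"]), 1.52, tolerance = 0.02)
})

test_that("lineage rate multipliers scale the drawn Ks", {
  cfg <- sim_config(seed = 6, n_chrom = 2, genes_per_chrom = 60,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0, b = 0, c = 0), p = 0.29),
                    lineage_rates = list(hexa = 1.25))
  sim <- simulate_paleogenomes(cfg)
  # reference-ingroup pairs use the mean of the two lineage rates
  mu_div <- mean(sim$pairs$ks[sim$pairs$event == "DIV"])
  expect_equal(mu_div, 1.52 * (1 + 1.25) / 2, tolerance = 0.03)
  mu_hex <- mean(sim$pairs$ks[sim$pairs$event == "HEX"])
  expect_equal(mu_hex, 0.95 * 1.25, tolerance = 0.03)
})

test_that("CDS emission hits the requested Ks targets", {
  set.seed(9)
  a0 <- emit_cds(0, codons = 100)
  expect_identical(a0[["cds_a"]], a0[["cds_b"]])
  a <- emit_cds(0.56, codons = 300)
  ks <- nei_gojobori(make_codon_pair(a[["cds_a"]], a[["cds_b"]]))$Ks
  expect_gte(ks, 0.51); expect_lte(ks, 0.61)
  expect_error(emit_cds(5.0), "saturat")
})

test_that("excessive loss that would empty a chromosome is rejected", {
  cfg <- sim_config(seed = 7, n_chrom = 2, genes_per_chrom = 20,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0.97, b = 0.97, c = 0.97),
                                      p = 0.9))
  expect_error(simulate_paleogenomes(cfg))
})

test_that("simulation files land in reader-compatible formats", {
  cfg <- sim_config(seed = 8, n_chrom = 2, genes_per_chrom = 40,
                    hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.05,
                                      loss = c(a = 0.1, b = 0.2, c = 0.3),
                                      p = 0.29))
  sim <- simulate_paleogenomes(cfg)
  dir <- tempfile()
  write_simulation(sim, dir)
  g <- load_gene_annotations(file.path(dir, "hexa.bed"), format = "bed",
                             genome_name = "hexa")
  expect_equal(nrow(g$genes), nrow(sim$genomes$hexa$genes))
  expect_equal(g$genes$order_index, sim$genomes$hexa$genes$order_index)
  h <- load_hits(file.path(dir, "hits.tsv"))
  expect_equal(nrow(h), nrow(sim$hits))
})
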