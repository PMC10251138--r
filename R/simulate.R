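# Seeded paleogenome simulator. An ancestral gene order is carried through a
# reference/ingroup divergence, a shared hexaploidization (WGT) with
# per-subgenome biased gene loss (geometric run lengths), optional ingroup
# speciation and lineage tetraploidization (WGD), and chromosome
# rearrangements applied through the karyotype algebra. Every emitted gene
# is traceable to one ancestral gene; pair Ks values are drawn from the
# event node's normal distribution; homology hits (plus sub-threshold
# noise) and optional CDS pairs are emitted in the formats the readers
# consume.

#' Simulation configuration
#'
#' Defaults describe a hexaploid ingroup versus a conservative outgroup
#' reference: 7 ancestral chromosomes of 200 genes, a reference/ingroup
#' divergence peak at Ks 1.52, a shared triplication at Ks 0.95 with biased
#' per-subgenome loss (rates 0.2 / 0.35 / 0.5, geometric run parameter
#' 0.29), and an optional ingroup split at Ks 0.56.
#'
#' @param seed integer seed fixing all outputs.
#' @param n_chrom,genes_per_chrom ancestral genome dimensions.
#' @param segments_per_chrom rearrangement granularity (breakpoints fall
#'   between segments).
#' @param reference_name outgroup reference genome name.
#' @param divergence list `(ks_mu, ks_sigma)` for the reference/ingroup
#'   split.
#' @param hexaploidy list `(ks_mu, ks_sigma, loss, p, allo_offsets)`: the
#'   shared triplication; `loss` is the per-subgenome loss fraction (named
#'   a/b/c), `p` the geometric run-length parameter, `allo_offsets`
#'   optional per-subgenome additive Ks offsets.
#' @param ingroup_split `NULL` for a single ingroup genome, else list
#'   `(ks_mu, ks_sigma, names)` with two descendant genome names.
#' @param tetraploidy `NULL`, or list `(genome, ks_mu, ks_sigma, loss, p)`
#'   for a later duplication in one descendant (`loss` named `1`/`2`).
#' @param ingroup_name ingroup genome name when there is no split.
#' @param ancestral_events rearrangements on the ingroup stem (after the
#'   WGT, before the split): a list of [rearrangement_event()]s, or a named
#'   count vector (e.g. `c(EEJ = 3)`) drawn with random valid operands.
#' @param lineage_events named list (per descendant genome) of the same.
#' @param lineage_rates named Ks rate multipliers per genome (default 1).
#' @param noise_hit_rate fraction of spurious sub-threshold hits added.
#' @param cds emit per-pair CDS sequences via [emit_cds()] (slower).
#' @param codons,ka_ks CDS length and Ka/Ks ratio for emitted pairs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 7L, genes_per_chrom = 200L,
                       segments_per_chrom = 4L,
                       reference_name = "ref",
                       divergence = list(ks_mu = 1.52, ks_sigma = 0.12),
                       hexaploidy = list(ks_mu = 0.95, ks_sigma = 0.08,
                                         loss = c(a = 0.2, b = 0.35, c = 0.5),
                                         p = 0.29),
                       ingroup_split = NULL,
                       tetraploidy = NULL,
                       ingroup_name = "hexa",
                       ancestral_events = NULL,
                       lineage_events = NULL,
                       lineage_rates = NULL,
                       noise_hit_rate = 0.02,
                       cds = FALSE, codons = 300L, ka_ks = 0.2) {
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              genes_per_chrom = genes_per_chrom,
              segments_per_chrom = segments_per_chrom,
              reference_name = reference_name, divergence = divergence,
              hexaploidy = hexaploidy, ingroup_split = ingroup_split,
              tetraploidy = tetraploidy, ingroup_name = ingroup_name,
              ancestral_events = ancestral_events,
              lineage_events = lineage_events,
              lineage_rates = lineage_rates,
              noise_hit_rate = noise_hit_rate,
              cds = cds, codons = codons, ka_ks = ka_ks)
  stopifnot(cfg$n_chrom >= 1, cfg$genes_per_chrom >= cfg$segments_per_chrom)
  if (!is.null(cfg$hexaploidy)) {
    stopifnot(all(cfg$hexaploidy$loss >= 0), all(cfg$hexaploidy$loss < 1),
              cfg$hexaploidy$p > 0, cfg$hexaploidy$p <= 1)
  }
  class(cfg) <- "sim_config"
  cfg
}

# place geometric-length loss runs on a logical retention vector (per
# chromosome boundaries given by `chrom`) until `target` genes are lost;
# runs do not overlap and are resampled up to 100 times.
place_loss_runs <- function(n, chrom, target, p) {
  retained <- rep(TRUE, n)
  runs <- list()
  lost <- 0L
  tries <- 0L
  while (lost < target) {
    len <- stats::rgeom(1, p) + 1L
    len <- min(len, target - lost + 2L)
    start <- sample.int(n, 1L)
    span <- start:min(start + len - 1L, n)
    ok <- all(retained[span]) && length(unique(chrom[span])) == 1L &&
      length(span) == len
    if (!ok) {
      tries <- tries + 1L
      if (tries > 100L) stop("could not place loss runs without overlap; ",
                             "loss rate too high")
      next
    }
    tries <- 0L
    retained[span] <- FALSE
    runs[[length(runs) + 1L]] <- c(start = start, length = len)
    lost <- lost + len
  }
  list(retained = retained, runs = do.call(rbind, runs))
}

# random valid operands for event-kind counts on a karyotype
random_events <- function(kar, counts) {
  evs <- list()
  for (kind in names(counts)) {
    for (i in seq_len(counts[[kind]])) {
      n <- length(kar$chromosomes)
      lens <- lengths(kar$chromosomes)
      ev <- switch(kind,
        EEJ = {
          if (n < 2L) stop("no valid EEJ operands")
          ab <- sample.int(n, 2L)
          rearrangement_event("EEJ", a = ab[1], b = ab[2],
                              flip = stats::runif(1) < 0.5)
        },
        NCF = {
          hosts <- which(lens >= 2L)
          if (!length(hosts) || n < 2L) stop("no valid NCF operands")
          a <- sample(rep(hosts, 2L), 1L)
          b <- sample(rep(setdiff(seq_len(n), a), 2L), 1L)
          rearrangement_event("NCF", a = a, b = b,
                              pos_a = sample.int(lens[a] - 1L, 1L))
        },
        RCT = {
          ok <- which(lens >= 2L)
          if (length(ok) < 2L) stop("no valid RCT operands")
          ab <- sample(ok, 2L)
          rearrangement_event("RCT", a = ab[1], b = ab[2],
                              pos_a = sample.int(lens[ab[1]] - 1L, 1L),
                              pos_b = sample.int(lens[ab[2]] - 1L, 1L))
        },
        NCT = {
          srcs <- which(lens >= 2L)
          if (!length(srcs) || n < 2L) stop("no valid NCT operands")
          a <- sample(rep(srcs, 2L), 1L)
          b <- sample(rep(setdiff(seq_len(n), a), 2L), 1L)
          from <- sample.int(lens[a], 1L)
          to <- min(lens[a], from + sample.int(2L, 1L) - 1L)
          if (from == 1L && to == lens[a]) to <- lens[a] - 1L
          rearrangement_event("NCT", a = a, b = b, from = from, to = to,
                              pos_b = sample.int(lens[b] + 1L, 1L) - 1L)
        },
        FISSION = {
          srcs <- which(lens >= 2L)
          if (!length(srcs)) stop("no valid FISSION operands")
          a <- sample(rep(srcs, 2L), 1L)
          rearrangement_event("FISSION", a = a,
                              pos_a = sample.int(lens[a] - 1L, 1L))
        },
        stop("unsupported random event kind: ", kind))
      kar <- apply_event(kar, ev)
      evs[[length(evs) + 1L]] <- ev
    }
  }
  list(karyotype = kar, events = evs)
}

as_event_list <- function(spec, kar) {
  if (is.null(spec)) return(list(karyotype = kar, events = list()))
  if (is.list(spec) && length(spec) && inherits(spec[[1]], "rearrangement_event")) {
    for (ev in spec) kar <- apply_event(kar, ev)
    return(list(karyotype = kar, events = spec))
  }
  random_events(kar, spec)
}

#' Simulate paleopolyploid genomes with known truth
#'
#' Runs the scenario described by a [sim_config()] and returns genomes,
#' homology hits, per-pair truth (event node and drawn Ks), optional CDS
#' pairs, and truth tables (gene ancestry with subgenome labels, loss runs,
#' planted rearrangements, karyotype snapshots). The same seed always
#' reproduces identical output.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (named list of `genome` objects), `hits`
#'   (data.frame), `pairs` (truth: `gene_a`, `gene_b`, `event`, `ks`),
#'   `cds` (named vector, present when `config$cds`), and `truth` (list:
#'   `ancestry`, `loss_runs`, `events`, `karyotypes`, `subgenome_labels`).
#' @export
simulate_paleogenomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nchr <- config$n_chrom
  gpc <- config$genes_per_chrom
  nseg <- config$segments_per_chrom

  # ancestral segments and genes
  seg_genes <- list()
  anc_chroms <- list()
  for (ci in seq_len(nchr)) {
    genes <- sprintf("c%dg%03d", ci, seq_len(gpc))
    cuts <- floor(seq(0L, gpc, length.out = nseg + 1L))
    segs <- sprintf("C%d.%d", ci, seq_len(nseg))
    for (k in seq_len(nseg))
      seg_genes[[segs[k]]] <- genes[(cuts[k] + 1L):cuts[k + 1L]]
    anc_chroms[[ci]] <- segs
  }
  anc_kar <- new_karyotype(anc_chroms, name = "ancestor")

  hex <- config$hexaploidy
  hex_labels <- names(hex$loss)
  if (is.null(hex_labels)) hex_labels <- letters[seq_along(hex$loss)]
  # WGT: copy-suffixed segments; seg_genes extended per copy
  post_wgt <- apply_event(anc_kar, rearrangement_event("WGT",
                                                       copy_labels = hex_labels))
  seg_meta <- data.frame(seg = unlist(post_wgt$chromosomes),
                         stringsAsFactors = FALSE)
  seg_meta$base <- sub(paste0("(", paste(hex_labels, collapse = "|"), ")$"),
                       "", seg_meta$seg)
  seg_meta$hex_copy <- substring(seg_meta$seg, nchar(seg_meta$base) + 1L)
  for (i in seq_len(nrow(seg_meta)))
    seg_genes[[seg_meta$seg[i]]] <- seg_genes[[seg_meta$base[i]]]

  # per-subgenome biased loss with geometric run lengths
  loss_runs_truth <- list()
  for (k in seq_along(hex_labels)) {
    lab <- hex_labels[k]
    segs_k <- seg_meta$seg[seg_meta$hex_copy == lab]
    # genome order of this subgenome's genes, with chromosome ids
    gvec <- unlist(lapply(segs_k, function(s) seg_genes[[s]]),
                   use.names = FALSE)
    cvec <- rep(seq_along(segs_k), lengths(seg_genes[segs_k]))
    # chromosome boundaries at the original ancestral chromosomes
    cvec <- rep(sub("\\..*", "", segs_k), lengths(seg_genes[segs_k]))
    target <- round(hex$loss[[k]] * length(gvec))
    if (target > 0L) {
      pl <- place_loss_runs(length(gvec), cvec, target, hex$p)
      keep <- split(pl$retained, rep(segs_k, lengths(seg_genes[segs_k])))
      for (s in segs_k) seg_genes[[s]] <- seg_genes[[s]][keep[[s]]]
      if (any(lengths(seg_genes[segs_k]) == 0L))
        stop("subgenome ", lab, " loss emptied a segment; lower the rate")
      loss_runs_truth[[lab]] <- data.frame(
        subgenome = lab, length = pl$runs[, "length"])
    }
  }

  # ancestral (shared) rearrangements on the hexaploid stem
  anc_ev <- as_event_list(config$ancestral_events, post_wgt)
  stem_kar <- anc_ev$karyotype
  stem_kar$name <- "ingroup_ancestor"

  # lineages
  ling <- list()
  if (is.null(config$ingroup_split)) {
    ling[[config$ingroup_name]] <- stem_kar
  } else {
    for (nm in config$ingroup_split$names) ling[[nm]] <- stem_kar
  }
  lineage_events_truth <- list()
  for (nm in names(ling)) {
    le <- as_event_list(config$lineage_events[[nm]], ling[[nm]])
    ling[[nm]] <- le$karyotype
    ling[[nm]]$name <- nm
    lineage_events_truth[[nm]] <- le$events
  }

  # lineage tetraploidy (WGD) with its own biased loss
  tet <- config$tetraploidy
  seg_genes_g <- stats::setNames(vector("list", length(ling)), names(ling))
  for (nm in names(ling)) seg_genes_g[[nm]] <- seg_genes
  tet_labels <- NULL
  if (!is.null(tet)) {
    nm <- tet$genome
    if (!nm %in% names(ling)) stop("tetraploidy genome not in lineages: ", nm)
    tet_labels <- names(tet$loss)
    if (is.null(tet_labels)) tet_labels <- as.character(seq_along(tet$loss))
    ling[[nm]] <- apply_event(ling[[nm]],
                              rearrangement_event("WGD",
                                                  copy_labels = tet_labels))
    sg <- seg_genes_g[[nm]]
    for (s in unlist(ling[[nm]]$chromosomes)) {
      base <- sub(paste0("(", paste(tet_labels, collapse = "|"), ")$"), "", s)
      sg[[s]] <- sg[[base]]
    }
    # per-copy loss
    for (k in seq_along(tet_labels)) {
      lab <- tet_labels[k]
      segs_k <- grep(paste0(lab, "$"),
                     unlist(ling[[nm]]$chromosomes), value = TRUE)
      segs_k <- seg_id(segs_k)
      gl <- lengths(sg[segs_k])
      gvec_n <- sum(gl)
      cvec <- rep(segs_k, gl)
      target <- round(tet$loss[[k]] * gvec_n)
      if (target > 0L) {
        pl <- place_loss_runs(gvec_n, cvec, target, tet$p)
        keep <- split(pl$retained, rep(segs_k, gl))
        for (s in segs_k) sg[[s]] <- sg[[s]][keep[[s]]]
        loss_runs_truth[[paste0(nm, "_", lab)]] <- data.frame(
          subgenome = paste0(nm, "_", lab), length = pl$runs[, "length"])
      }
    }
    seg_genes_g[[nm]] <- sg
  }

  # ---- materialize genome objects --------------------------------------
  hex_pat <- paste0("(", paste(hex_labels, collapse = "|"), ")")
  copy_of_seg <- function(s) {
    # returns c(hex, tet) copy labels parsed from the segment id suffix
    s0 <- seg_id(s)
    tetl <- ""
    if (!is.null(tet_labels)) {
      m <- regmatches(s0, regexpr(paste0("(",
                                         paste(tet_labels, collapse = "|"),
                                         ")$"), s0))
      if (length(m)) { tetl <- m; s0 <- sub(paste0(m, "$"), "", s0) }
    }
    hx <- regmatches(s0, regexpr(paste0(hex_pat, "$"), s0))
    c(hex = if (length(hx)) hx else "", tet = tetl)
  }
  materialize <- function(kar, sg, gname, has_copies) {
    rows <- list()
    for (ci in seq_along(kar$chromosomes)) {
      chrom_name <- sprintf("%s_chr%d", gname, ci)
      pos <- 0L
      for (s in kar$chromosomes[[ci]]) {
        g <- sg[[seg_id(s)]]
        strand <- "+"
        if (startsWith(s, "-")) { g <- rev(g); strand <- "-" }
        if (!length(g)) next
        cp <- if (has_copies) copy_of_seg(s) else c(hex = "", tet = "")
        suffix <- paste0(cp[["hex"]], cp[["tet"]])
        ids <- if (nzchar(suffix)) sprintf("%s_%s_%s", gname, g, suffix)
               else sprintf("%s_%s", gname, g)
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids, chrom = chrom_name,
          start = (pos + seq_along(g) - 1L) * 1000L,
          end = (pos + seq_along(g) - 1L) * 1000L + 900L,
          strand = strand, anc_gene = g,
          hex_copy = cp[["hex"]], tet_copy = cp[["tet"]],
          segment = seg_id(s), stringsAsFactors = FALSE)
        pos <- pos + length(g)
      }
    }
    df <- do.call(rbind, rows)
    if (is.null(df) || !nrow(df))
      stop("lineage ", gname, " lost all genes")
    df
  }

  gene_tables <- list()
  gene_tables[[config$reference_name]] <-
    materialize(anc_kar, seg_genes[names(seg_genes) %in%
                                     unlist(anc_chroms)],
                config$reference_name, has_copies = FALSE)
  for (nm in names(ling))
    gene_tables[[nm]] <- materialize(ling[[nm]], seg_genes_g[[nm]], nm,
                                     has_copies = TRUE)
  empty_chrom <- vapply(names(ling), function(nm) {
    tb <- table(gene_tables[[nm]]$chrom)
    length(tb) < length(ling[[nm]]$chromosomes)
  }, logical(1))
  if (any(empty_chrom))
    stop("gene loss emptied a chromosome in: ",
         paste(names(ling)[empty_chrom], collapse = ", "))

  hex_events <- c("ECH-like")
  genomes <- list()
  for (nm in names(gene_tables)) {
    evs <- character()
    if (nm != config$reference_name) {
      evs <- "HEX"
      if (!is.null(tet) && identical(tet$genome, nm)) evs <- c(evs, "TET")
    }
    genomes[[nm]] <- new_genome(nm, gene_tables[[nm]][
      c("id", "chrom", "start", "end", "strand")], ploidy_events = evs)
  }

  # ---- homologous pairs, events, Ks ------------------------------------
  rates <- stats::setNames(rep(1, length(gene_tables)), names(gene_tables))
  if (!is.null(config$lineage_rates))
    rates[names(config$lineage_rates)] <- unlist(config$lineage_rates)
  copies <- do.call(rbind, lapply(names(gene_tables), function(nm) {
    df <- gene_tables[[nm]]
    data.frame(genome = nm, id = df$id, anc_gene = df$anc_gene,
               hex_copy = if (is.null(df$hex_copy)) "" else df$hex_copy,
               tet_copy = if (is.null(df$tet_copy)) "" else df$tet_copy,
               stringsAsFactors = FALSE)
  }))
  allo <- hex$allo_offsets

  pair_rows <- list()
  split_cfg <- config$ingroup_split
  by_anc <- split(seq_len(nrow(copies)), copies$anc_gene)
  for (idx in by_anc) {
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      g1 <- copies$genome[i1]; g2 <- copies$genome[i2]
      ref1 <- g1 == config$reference_name
      ref2 <- g2 == config$reference_name
      if (ref1 || ref2) {
        ev <- "DIV"; mu <- config$divergence$ks_mu
        sg <- config$divergence$ks_sigma
      } else if (copies$hex_copy[i1] != copies$hex_copy[i2]) {
        ev <- "HEX"; mu <- hex$ks_mu; sg <- hex$ks_sigma
        if (!is.null(allo))
          mu <- mu + sum(allo[c(copies$hex_copy[i1], copies$hex_copy[i2])],
                         na.rm = TRUE)
      } else if (g1 != g2) {
        ev <- "SPL"; mu <- split_cfg$ks_mu; sg <- split_cfg$ks_sigma
      } else if (copies$tet_copy[i1] != copies$tet_copy[i2]) {
        ev <- "TET"; mu <- tet$ks_mu; sg <- tet$ks_sigma
      } else next
      rate <- mean(c(rates[[g1]], rates[[g2]]))
      ks <- max(0, stats::rnorm(1, mu * rate, sg))
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(gene_a = copies$id[i1], gene_b = copies$id[i2],
                   event = ev, ks = ks, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pair_rows)

  hits <- data.frame(query = pairs$gene_a, subject = pairs$gene_b,
                     pident = 90, evalue = 1e-50, score = 200,
                     stringsAsFactors = FALSE)
  n_noise <- round(config$noise_hit_rate * nrow(hits))
  if (n_noise > 0L) {
    all_ids <- copies$id
    noise <- data.frame(query = sample(all_ids, n_noise, replace = TRUE),
                        subject = sample(all_ids, n_noise, replace = TRUE),
                        pident = 30, evalue = 1e-3, score = 50,
                        stringsAsFactors = FALSE)
    noise <- noise[noise$query != noise$subject, , drop = FALSE]
    hits <- rbind(hits, noise)
  }

  cds_pairs <- NULL
  if (isTRUE(config$cds)) {
    emitted <- lapply(pairs$ks, emit_cds, codons = config$codons,
                      ka_ks = config$ka_ks)
    cds_pairs <- data.frame(
      gene_a = pairs$gene_a, gene_b = pairs$gene_b,
      cds_a = vapply(emitted, `[[`, character(1), "cds_a"),
      cds_b = vapply(emitted, `[[`, character(1), "cds_b"),
      stringsAsFactors = FALSE)
  }

  # subgenome truth labels: least loss -> LF
  rank_labels <- c("LF", "MF1", "MF2")
  o <- order(hex$loss)
  subgenome_labels <- stats::setNames(character(length(hex_labels)), hex_labels)
  subgenome_labels[o] <- rank_labels[seq_along(o)]

  truth <- list(
    ancestry = copies,
    loss_runs = if (length(loss_runs_truth))
      do.call(rbind, loss_runs_truth) else NULL,
    events = list(ancestral = anc_ev$events, lineage = lineage_events_truth),
    karyotypes = c(list(ancestor = anc_kar, post_wgt = post_wgt,
                        ingroup_ancestor = stem_kar), ling),
    subgenome_labels = subgenome_labels,
    gene_tables = gene_tables)
  list(genomes = genomes, hits = hits, pairs = pairs, cds_pairs = cds_pairs,
       truth = truth, config = config)
}

#' Emit a CDS pair with a controlled synonymous divergence
#'
#' Generates a random stop-free coding sequence and introduces synonymous
#' third-position substitutions until [nei_gojobori()] measures the target
#' Ks (within about 0.02 at 300 codons), plus nonsynonymous substitutions
#' at the configured Ka/Ks. Targets beyond the sequence's synonymous
#' capacity (saturation) are an error.
#'
#' @param target_ks desired Ks (>= 0).
#' @param codons sequence length in codons.
#' @param ka_ks Ka/Ks ratio for added nonsynonymous changes.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return named character vector `c(cds_a = ..., cds_b = ...)`.
#' @export
emit_cds <- function(target_ks, codons = 300L, ka_ks = 0.2, seed = NULL) {
  stopifnot(target_ks >= 0)
  if (!is.null(seed)) set.seed(seed)
  tab <- ng_tables()
  sense <- names(tab$aa)[!tab$is_stop]
  # avoid codons one substitution away from a stop for simplicity of
  # nonsynonymous edits; any sense codon is fine for the backbone
  cds_a_codons <- sample(sense, codons, replace = TRUE)
  cds_b <- cds_a_codons
  # the JC correction diverges as pS -> 3/4; targets that close to the pole
  # cannot be placed reliably and are treated as saturated
  p_target <- 3 / 4 * (1 - exp(-4 / 3 * target_ks))
  if (p_target >= 3 / 4 - 0.01)
    stop("target Ks is saturated (required pS within 0.01 of 3/4)")
  S <- sum(tab$syn_sites[cds_a_codons])
  sd_needed <- p_target * S

  # candidate synonymous single changes: third-position swaps that keep the
  # amino acid and avoid stops
  syn_alt <- function(codon) {
    base3 <- substr(codon, 3, 3)
    for (b in sample(setdiff(c("A", "C", "G", "T"), base3))) {
      alt <- paste0(substr(codon, 1, 2), b)
      if (!tab$is_stop[[alt]] && tab$aa[[alt]] == tab$aa[[codon]])
        return(alt)
    }
    NA_character_
  }
  cand <- which(!is.na(vapply(cds_a_codons, syn_alt, character(1))))
  if (length(cand) < ceiling(sd_needed))
    stop("target Ks is saturated for this sequence (needs ",
         ceiling(sd_needed), " synonymous changes, ", length(cand),
         " sites available)")
  cand <- sample(cand)
  n_apply <- min(length(cand), max(0L, round(sd_needed)))
  applied <- integer()
  apply_n <- function(k) {
    b <- cds_a_codons
    for (i in seq_len(k)) b[cand[i]] <- syn_alt(cds_a_codons[cand[i]])
    b
  }
  measure <- function(b) {
    pr <- make_codon_pair(paste(cds_a_codons, collapse = ""),
                          paste(b, collapse = ""))
    nei_gojobori(pr)$Ks
  }
  k <- n_apply
  b <- apply_n(k)
  ks <- measure(b)
  for (it in seq_len(50L)) {
    if (is.na(ks)) stop("target Ks is saturated (measured pS >= 3/4)")
    if (abs(ks - target_ks) <= 0.02) break
    k <- if (ks < target_ks) min(k + 1L, length(cand)) else max(k - 1L, 0L)
    b2 <- apply_n(k)
    ks2 <- measure(b2)
    if (!is.na(ks2) && abs(ks2 - target_ks) >= abs(ks - target_ks)) break
    b <- b2; ks <- ks2
  }
  # nonsynonymous changes at untouched codons (first-position swaps that
  # change the amino acid, avoid stops)
  ka_target <- ka_ks * target_ks
  if (ka_target > 0) {
    N <- 3 * codons - S
    pn_target <- 3 / 4 * (1 - exp(-4 / 3 * ka_target))
    nd_needed <- round(pn_target * N)
    non_alt <- function(codon) {
      base1 <- substr(codon, 1, 1)
      for (bb in sample(setdiff(c("A", "C", "G", "T"), base1))) {
        alt <- paste0(bb, substr(codon, 2, 3))
        if (!tab$is_stop[[alt]] && tab$aa[[alt]] != tab$aa[[codon]])
          return(alt)
      }
      NA_character_
    }
    free <- setdiff(seq_len(codons), cand[seq_len(k)])
    free <- free[!is.na(vapply(cds_a_codons[free], non_alt, character(1)))]
    for (i in utils::head(sample(free), nd_needed))
      b[i] <- non_alt(cds_a_codons[i])
  }
  c(cds_a = paste(cds_a_codons, collapse = ""),
    cds_b = paste(b, collapse = ""))
}

#' Write a simulation to disk in standard formats
#'
#' Writes per-genome BED gene orders, BLAST-tabular hits, truth TSVs, and
#' (when present) CDS FASTA.
#'
#' @param sim result of [simulate_paleogenomes()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$genomes))
    write_genome_bed(sim$genomes[[nm]], file.path(dir, paste0(nm, ".bed")))
  write_hits(sim$hits, file.path(dir, "hits.tsv"))
  utils::write.table(sim$pairs, file.path(dir, "pairs_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$ancestry, file.path(dir, "ancestry_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$cds_pairs))
    utils::write.table(sim$cds_pairs, file.path(dir, "cds_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(sim$truth$karyotypes))
    write_karyotype(sim$truth$karyotypes[[nm]],
                    file.path(dir, paste0("karyotype_", nm, ".txt")))
  invisible(dir)
}
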