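# Event classification of synteny blocks by Ks medians, and assembly of the
# reference-anchored multigenome alignment table: one row per reference
# gene, three reference panels (the reference's own hexaploid copies), and
# per aligned genome 3 * 2^N slot columns per panel; "." marks an ortholog
# lost or translocated.

#' Classify a synteny block to an evolutionary event by its Ks median
#'
#' The block is assigned the event whose expected Ks peak lies closest to
#' the block's Ks median, provided the distance is within that event's
#' tolerance. Two peaks equidistant within 1e-9 give `"unclassified(tie)"`.
#'
#' @param block a `synteny_block` with a defined `ks_median`.
#' @param peaks data.frame with columns `event`, `mu`, `tol`.
#' @return the block with `event` set (possibly `"unclassified"` or
#'   `"unclassified(tie)"`).
#' @export
classify_block_event <- function(block, peaks) {
  stopifnot(all(c("event", "mu", "tol") %in% names(peaks)))
  if (is.na(block$ks_median)) {
    block$event <- "unclassified"
    block$flag <- "ks_median_missing"
    return(block)
  }
  d <- abs(block$ks_median - peaks$mu)
  o <- order(d)
  if (length(o) >= 2L && abs(d[o[1]] - d[o[2]]) < 1e-9) {
    block$event <- "unclassified(tie)"
  } else if (d[o[1]] <= peaks$tol[o[1]]) {
    block$event <- peaks$event[o[1]]
  } else {
    block$event <- "unclassified"
  }
  block
}

#' Classify a list of blocks
#' @param blocks list of `synteny_block` objects.
#' @inheritParams classify_block_event
#' @return list of classified blocks.
#' @export
classify_blocks <- function(blocks, peaks)
  lapply(blocks, classify_block_event, peaks = peaks)

#' Count gene pairs and genes attributed to an event
#'
#' @param blocks list of classified `synteny_block` objects.
#' @param event event label.
#' @return list with `n_pairs` (anchors in blocks of the event) and
#'   `n_genes` (distinct gene ids among them).
#' @export
count_event_homologs <- function(blocks, event) {
  sel <- Filter(function(b) identical(b$event, event), blocks)
  if (!length(sel)) return(list(n_pairs = 0L, n_genes = 0L))
  anchors <- do.call(rbind, lapply(sel, function(b)
    b$anchors[, c("gene_a", "gene_b")]))
  list(n_pairs = nrow(anchors),
       n_genes = length(unique(c(anchors$gene_a, anchors$gene_b))))
}

#' Plan the column layout of the multigenome alignment table
#'
#' The reference (which carries the shared hexaploidy) contributes three
#' panels; within each panel every aligned genome gets `m_g = 3 * 2^N_g`
#' slot columns, where `N_g` is its number of tetraploidies after the
#' shared hexaploidy. Total columns: `3 * (1 + sum(m_g))` (e.g. a reference
#' plus one hexaploid genome plus one hexaploid + tetraploid genome gives
#' `(1 + 3 + 6) * 3 = 30`).
#'
#' @param reference reference genome name.
#' @param genomes data.frame with columns `genome`, `shared_hexaploidy`
#'   (logical), `n_tetraploidies` (N_g >= 0); may have zero rows.
#' @return data.frame layout with one row per column: `panel`, `genome`,
#'   `slot` (0 for the reference column), `name`; attribute `n_columns`.
#' @export
plan_table_layout <- function(reference, genomes = NULL) {
  if (is.null(genomes))
    genomes <- data.frame(genome = character(), shared_hexaploidy = logical(),
                          n_tetraploidies = integer())
  if (nrow(genomes) && !all(genomes$shared_hexaploidy))
    stop("genome(s) lacking the shared hexaploidy cannot be represented: ",
         paste(genomes$genome[!genomes$shared_hexaploidy], collapse = ", "))
  m_g <- if (nrow(genomes)) 3L * 2L^genomes$n_tetraploidies else integer()
  rows <- list()
  for (p in 1:3) {
    rows[[length(rows) + 1L]] <-
      data.frame(panel = p, genome = reference, slot = 0L,
                 name = sprintf("%s_p%d", reference, p),
                 stringsAsFactors = FALSE)
    for (gi in seq_len(nrow(genomes))) {
      rows[[length(rows) + 1L]] <-
        data.frame(panel = p, genome = genomes$genome[gi],
                   slot = seq_len(m_g[gi]),
                   name = sprintf("%s_p%d_s%d", genomes$genome[gi], p,
                                  seq_len(m_g[gi])),
                   stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, rows)
  rownames(layout) <- NULL
  stopifnot(nrow(layout) == 3L * (1L + sum(m_g)))
  attr(layout, "n_columns") <- nrow(layout)
  attr(layout, "reference") <- reference
  layout
}

# group block row-side intervals by overlap and rank blocks within a group
# by retention (anchor count, descending); returns a slot per block.
region_slot_assign <- function(spans) {
  # spans: data.frame(idx, chrom, lo, hi, n_anchors)
  spans$slot <- NA_integer_
  spans$group <- NA_integer_
  gid <- 0L
  for (ch in unique(spans$chrom)) {
    s <- spans[spans$chrom == ch, , drop = FALSE]
    s <- s[order(s$lo, s$hi), , drop = FALSE]
    cur_hi <- -Inf
    for (i in seq_len(nrow(s))) {
      if (s$lo[i] > cur_hi) gid <- gid + 1L
      spans$group[spans$idx == s$idx[i]] <- gid
      cur_hi <- max(cur_hi, s$hi[i])
    }
  }
  for (g in unique(spans$group)) {
    sel <- spans$group == g
    o <- order(-spans$n_anchors[sel], spans$lo[sel], spans$idx[sel])
    spans$slot[sel][o] <- seq_len(sum(sel))
  }
  spans
}

#' Fill the multigenome alignment table
#'
#' Builds the table row by reference gene. Panel 1's reference column holds
#' the gene itself; panels 2 and 3 hold its hexaploid paralogs, assigned
#' region-wise from the within-reference paralogous blocks. Each aligned
#' genome's slot columns hold the syntenic ortholog occupying that subgenome
#' copy, taken from reference-vs-genome orthologous blocks; slot identity is
#' region-wise (blocks overlapping on the reference are clustered, ranked by
#' anchor count so the most-retained region gets slot 1). Cells with no
#' supporting anchor are `"."` (ortholog lost or translocated). Panels 2 and
#' 3 of an aligned genome are filled through the reference paralog occupying
#' that panel. Regions with more distinct orthologous regions than slots are
#' flagged and the extras reported in the `overflow` attribute.
#'
#' @param layout a [plan_table_layout()] result.
#' @param ref_genome the reference `genome` object.
#' @param ortho_blocks list of classified reference-vs-genome
#'   `synteny_block`s (reference on the a-side) for the aligned genomes.
#' @param para_blocks list of classified within-reference blocks (the
#'   shared-hexaploidy paralog regions).
#' @return object of class `alignment_table`: data.frame with `ref_gene`,
#'   `ref_chrom` and one character column per layout column; attributes
#'   `layout`, `reference`, `overflow`.
#' @export
fill_table <- function(layout, ref_genome, ortho_blocks, para_blocks = list()) {
  reference <- attr(layout, "reference")
  genes <- ref_genome$genes
  n <- nrow(genes)
  row_of <- stats::setNames(seq_len(n), genes$id)
  tab <- data.frame(ref_gene = genes$id, ref_chrom = genes$chrom,
                    stringsAsFactors = FALSE)
  for (nm in layout$name) tab[[nm]] <- rep(".", n)
  tab[[sprintf("%s_p1", reference)]] <- genes$id
  overflow <- list()

  # --- reference panels 2/3 from paralogous blocks (directed copies) ----
  if (length(para_blocks)) {
    dir_rec <- list()
    for (b in para_blocks) {
      dir_rec[[length(dir_rec) + 1L]] <- list(
        chrom = b$chrom_a, lo = min(b$anchors$order_a),
        hi = max(b$anchors$order_a), n_anchors = nrow(b$anchors),
        rows = b$anchors$gene_a, partners = b$anchors$gene_b)
      dir_rec[[length(dir_rec) + 1L]] <- list(
        chrom = b$chrom_b, lo = min(b$anchors$order_b),
        hi = max(b$anchors$order_b), n_anchors = nrow(b$anchors),
        rows = b$anchors$gene_b, partners = b$anchors$gene_a)
    }
    spans <- data.frame(idx = seq_along(dir_rec),
                        chrom = vapply(dir_rec, `[[`, character(1), "chrom"),
                        lo = vapply(dir_rec, `[[`, numeric(1), "lo"),
                        hi = vapply(dir_rec, `[[`, numeric(1), "hi"),
                        n_anchors = vapply(dir_rec, `[[`, numeric(1), "n_anchors"),
                        stringsAsFactors = FALSE)
    spans <- region_slot_assign(spans)
    for (i in seq_along(dir_rec)) {
      slot <- spans$slot[spans$idx == i]
      if (slot > 2L) {
        overflow[[length(overflow) + 1L]] <-
          data.frame(genome = reference, chrom = dir_rec[[i]]$chrom,
                     lo = dir_rec[[i]]$lo, hi = dir_rec[[i]]$hi,
                     slot_needed = slot, stringsAsFactors = FALSE)
        next
      }
      col <- sprintf("%s_p%d", reference, slot + 1L)
      tab[[col]][row_of[dir_rec[[i]]$rows]] <- dir_rec[[i]]$partners
    }
  }

  # --- aligned genomes: slot assignment per genome, panels via paralogs --
  for (gname in setdiff(unique(layout$genome), reference)) {
    m_g <- max(layout$slot[layout$genome == gname])
    gb <- Filter(function(b) b$genome_b == gname && b$genome_a == reference,
                 ortho_blocks)
    if (!length(gb)) next
    spans <- data.frame(
      idx = seq_along(gb),
      chrom = vapply(gb, `[[`, character(1), "chrom_a"),
      lo = vapply(gb, function(b) min(b$anchors$order_a), numeric(1)),
      hi = vapply(gb, function(b) max(b$anchors$order_a), numeric(1)),
      n_anchors = vapply(gb, function(b) nrow(b$anchors), numeric(1)),
      stringsAsFactors = FALSE)
    spans <- region_slot_assign(spans)
    # cell map: reference gene -> ortholog per slot
    cell <- vector("list", m_g)
    for (i in seq_along(gb)) {
      slot <- spans$slot[spans$idx == i]
      if (slot > m_g) {
        overflow[[length(overflow) + 1L]] <-
          data.frame(genome = gname, chrom = gb[[i]]$chrom_a,
                     lo = spans$lo[spans$idx == i],
                     hi = spans$hi[spans$idx == i],
                     slot_needed = slot, stringsAsFactors = FALSE)
        next
      }
      prev <- cell[[slot]]
      add <- stats::setNames(gb[[i]]$anchors$gene_b, gb[[i]]$anchors$gene_a)
      cell[[slot]] <- c(prev, add)
    }
    for (p in 1:3) {
      panel_ref <- tab[[sprintf("%s_p%d", reference, p)]]
      for (s in seq_len(m_g)) {
        if (is.null(cell[[s]])) next
        hit <- cell[[s]][panel_ref]
        col <- sprintf("%s_p%d_s%d", gname, p, s)
        tab[[col]] <- ifelse(is.na(hit), ".", unname(hit))
      }
    }
  }
  overflow <- if (length(overflow)) do.call(rbind, overflow) else NULL
  structure(tab, layout = layout, reference = reference,
            overflow = overflow, class = c("alignment_table", "data.frame"))
}

#' Write an alignment table to TSV
#' @param table an `alignment_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
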