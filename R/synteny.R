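# Collinear block chaining: per chromosome pair, dynamic programming over
# homology hits finds maximal monotone chains (run separately for the two
# diagonal directions) under a maximum intervening-gene gap on both genomes;
# chains are extracted greedily by anchor count, without anchor reuse.

new_synteny_block <- function(genome_a, genome_b, chrom_a, chrom_b,
                              anchors, orientation) {
  structure(list(genome_a = genome_a, genome_b = genome_b,
                 chrom_a = chrom_a, chrom_b = chrom_b,
                 anchors = anchors, orientation = orientation,
                 ks_median = NA_real_, event = NA_character_,
                 flag = NA_character_),
            class = "synteny_block")
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("<synteny_block> %s:%s ~ %s:%s, %d anchors (%s)%s\n",
              x$genome_a, x$chrom_a, x$genome_b, x$chrom_b,
              nrow(x$anchors), x$orientation,
              if (!is.na(x$ks_median))
                sprintf(", Ks median %.3f", x$ks_median) else ""))
  invisible(x)
}

# longest strictly-monotone chain with bounded gaps; pts has columns qi, si.
# dir = +1 (si increasing) or -1. Returns indices of the best chain.
best_chain <- function(pts, max_gap, dir) {
  n <- nrow(pts)
  if (!n) return(integer())
  o <- order(pts$qi, dir * pts$si)
  qi <- pts$qi[o]; si <- pts$si[o] * dir
  L <- rep(1L, n); prev <- rep(0L, n)
  lim <- max_gap + 1L
  for (j in seq_len(n)) {
    cand <- which(qi < qi[j] & qi >= qi[j] - lim &
                    si < si[j] & si >= si[j] - lim)
    if (length(cand)) {
      k <- cand[which.max(L[cand])]
      L[j] <- L[k] + 1L
      prev[j] <- k
    }
  }
  j <- which.max(L)
  chain <- integer(L[j])
  for (i in seq(L[j], 1L)) {
    chain[i] <- j
    j <- prev[j]
  }
  o[chain]
}

#' Chain homology hits into collinear synteny blocks
#'
#' For every chromosome pair, finds blocks of anchored gene pairs whose order
#' indices are strictly monotone in both genomes (same or inverted
#' orientation), with at most `max_gap` intervening genes between consecutive
#' anchors on either genome. Blocks are extracted greedily by anchor count
#' and never share an anchor within a chromosome pair. Chains shorter than
#' `min_anchors` are discarded.
#'
#' For an intragenomic comparison pass the same genome twice: self-pairs are
#' excluded and each unordered gene pair is used once.
#'
#' @param hits hit data.frame (`query`, `subject`); gene ids not found in
#'   either genome are an error.
#' @param genome_a,genome_b `genome` objects.
#' @param max_gap maximum intervening genes between consecutive anchors.
#' @param min_anchors minimum anchors per reported block.
#' @return list of `synteny_block` objects.
#' @export
chain_collinear_blocks <- function(hits, genome_a, genome_b,
                                   max_gap = 50, min_anchors = 5) {
  ga <- genome_a$genes; gb <- genome_b$genes
  self_cmp <- identical(genome_a$name, genome_b$name)
  in_a <- hits$query %in% ga$id
  in_b <- hits$subject %in% gb$id
  # allow swapped hits (query drawn from genome_b)
  swap <- !in_a & hits$query %in% gb$id & hits$subject %in% ga$id
  if (any(swap)) {
    tmp <- hits$query[swap]
    hits$query[swap] <- hits$subject[swap]
    hits$subject[swap] <- tmp
    in_a <- hits$query %in% ga$id
    in_b <- hits$subject %in% gb$id
  }
  bad <- !(in_a & in_b)
  if (any(bad)) {
    unknown <- setdiff(unique(c(hits$query[!in_a], hits$subject[!in_b])),
                       c(ga$id, gb$id))
    if (length(unknown))
      stop("unknown gene id(s) in hits: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    hits <- hits[!bad, , drop = FALSE]
  }
  if (self_cmp) hits <- hits[hits$query != hits$subject, , drop = FALSE]

  a_chrom <- stats::setNames(ga$chrom, ga$id)
  a_ord <- stats::setNames(ga$order_index, ga$id)
  b_chrom <- stats::setNames(gb$chrom, gb$id)
  b_ord <- stats::setNames(gb$order_index, gb$id)

  pts <- data.frame(gene_a = hits$query, gene_b = hits$subject,
                    ca = unname(a_chrom[hits$query]),
                    cb = unname(b_chrom[hits$subject]),
                    qi = unname(a_ord[hits$query]),
                    si = unname(b_ord[hits$subject]),
                    stringsAsFactors = FALSE)
  if (self_cmp) {
    # one point per unordered pair; on the same chromosome keep qi < si
    same <- pts$ca == pts$cb
    flip <- same & pts$qi > pts$si
    pts[flip, c("gene_a", "gene_b", "ca", "cb", "qi", "si")] <-
      pts[flip, c("gene_b", "gene_a", "cb", "ca", "si", "qi")]
    cross <- !same & pts$ca > pts$cb
    pts[cross, c("gene_a", "gene_b", "ca", "cb", "qi", "si")] <-
      pts[cross, c("gene_b", "gene_a", "cb", "ca", "si", "qi")]
  }
  pts <- unique(pts)

  blocks <- list()
  for (key in unique(paste(pts$ca, pts$cb, sep = "\r"))) {
    sub <- pts[paste(pts$ca, pts$cb, sep = "\r") == key, , drop = FALSE]
    repeat {
      up <- best_chain(sub, max_gap, +1L)
      dn <- best_chain(sub, max_gap, -1L)
      use_up <- length(up) >= length(dn)
      chain <- if (use_up) up else dn
      if (length(chain) < min_anchors) break
      anc <- sub[chain, c("gene_a", "gene_b", "qi", "si"), drop = FALSE]
      names(anc) <- c("gene_a", "gene_b", "order_a", "order_b")
      anc$ks <- NA_real_
      rownames(anc) <- NULL
      blocks[[length(blocks) + 1L]] <- new_synteny_block(
        genome_a$name, genome_b$name, sub$ca[1], sub$cb[1], anc,
        orientation = if (use_up) "same" else "inverted")
      sub <- sub[-chain, , drop = FALSE]
      if (nrow(sub) < min_anchors) break
    }
  }
  blocks
}

#' Flatten synteny blocks to a one-anchor-per-row table
#'
#' @param blocks list of `synteny_block` objects.
#' @return data.frame with `block_id`, genome/chromosome columns, gene ids,
#'   order indices, `orientation`, `ks`, and block `ks_median`/`event`.
#' @export
blocks_to_df <- function(blocks) {
  if (!length(blocks))
    return(data.frame(block_id = integer(), genome_a = character(),
                      genome_b = character(), chrom_a = character(),
                      chrom_b = character(), gene_a = character(),
                      gene_b = character(), order_a = integer(),
                      order_b = integer(), orientation = character(),
                      ks = numeric(), ks_median = numeric(),
                      event = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(block_id = i, genome_a = b$genome_a, genome_b = b$genome_b,
               chrom_a = b$chrom_a, chrom_b = b$chrom_b,
               gene_a = b$anchors$gene_a, gene_b = b$anchors$gene_b,
               order_a = b$anchors$order_a, order_b = b$anchors$order_b,
               orientation = b$orientation, ks = b$anchors$ks,
               ks_median = b$ks_median, event = b$event,
               stringsAsFactors = FALSE)
  }))
}

#' Write synteny blocks to TSV (one anchor per row)
#' @param blocks list of `synteny_block` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  utils::write.table(blocks_to_df(blocks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Modal orthology depth ratio between two genomes
#'
#' For each gene of a genome, counts the blocks whose anchor span on that
#' genome's chromosome covers the gene's order index; the genome's depth is
#' the modal count over covered genes. A region of the reference matching
#' `d` regions of the query (e.g. one region against three orthologous
#' regions after a triplication) yields a ratio `d_ref : d_query` of 1:3.
#'
#' @param blocks list of `synteny_block` objects between the two genomes.
#' @param ref_genome,query_genome `genome` objects matching the blocks'
#'   `genome_a`/`genome_b`.
#' @return list with `d_ref`, `d_query`, `ratio` (string), and `flag`
#'   (`"no_blocks"` when undefined).
#' @export
block_depth_ratio <- function(blocks, ref_genome, query_genome) {
  blocks <- Filter(function(b) b$genome_a == ref_genome$name &&
                     b$genome_b == query_genome$name, blocks)
  if (!length(blocks))
    return(list(d_ref = NA_integer_, d_query = NA_integer_,
                ratio = NA_character_, flag = "no_blocks"))
  depth_one <- function(genes, side) {
    cov <- integer(nrow(genes))
    key <- paste(genes$chrom)
    for (b in blocks) {
      chrom <- if (side == "a") b$chrom_a else b$chrom_b
      ords <- if (side == "a") b$anchors$order_a else b$anchors$order_b
      sel <- genes$chrom == chrom &
        genes$order_index >= min(ords) & genes$order_index <= max(ords)
      cov[sel] <- cov[sel] + 1L
    }
    cov <- cov[cov > 0L]
    if (!length(cov)) return(NA_integer_)
    tab <- table(cov)
    as.integer(names(tab)[which.max(tab)])
  }
  # one reference region matching d query regions means each reference gene
  # is covered by d blocks, and each query gene by the reference multiplicity
  d_ref <- depth_one(query_genome$genes, "b")
  d_query <- depth_one(ref_genome$genes, "a")
  list(d_ref = d_ref, d_query = d_query,
       ratio = paste(d_ref, d_query, sep = ":"), flag = NA_character_)
}
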