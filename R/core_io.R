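#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open [start, end).
# GFF3 is read/written 1-based inclusive, BED 0-based half-open, so that
# files round-trip exactly in their native convention.

#' Construct a genome object from a gene table
#'
#' A genome is an ordered collection of genes on named chromosomes. Genes are
#' sorted by chromosome and start coordinate and receive a contiguous
#' `order_index` (0-based rank along the chromosome), the backbone coordinate
#' used by synteny chaining, alignment tables and sliding-window statistics.
#'
#' @param name genome name (e.g. `"vvi"`).
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end` and
#'   optionally `strand` (`"+"`/`"-"`, default `"+"`) and `family_size`
#'   (default 1). Coordinates are 0-based half-open.
#' @param ploidy_events character vector of polyploidy event labels this
#'   lineage experienced, oldest first (e.g. `c(ECH = 3, ACH = 3)` given as
#'   `c("ECH","ACH")`); used by alignment-table layout planning.
#' @return an object of class `genome` with elements `name`, `genes`
#'   (sorted data.frame with `order_index`) and `ploidy_events`.
#' @export
new_genome <- function(name, genes, ploidy_events = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  need <- c("id", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols))
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  genes$id <- as.character(genes$id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (is.null(genes$strand)) genes$strand <- "+"
  if (is.null(genes$family_size)) genes$family_size <- 1L
  dup <- genes$id[duplicated(genes$id)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (any(genes$start >= genes$end))
    stop("gene(s) with start >= end: ",
         paste(genes$id[genes$start >= genes$end][1:min(3, sum(genes$start >= genes$end))],
               collapse = ", "))
  if (any(genes$family_size < 1L)) stop("family_size must be >= 1")
  o <- order(genes$chrom, genes$start, genes$end, method = "radix")
  genes <- genes[o, c("id", "chrom", "start", "end", "strand", "family_size"),
                 drop = FALSE]
  genes$order_index <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                                  FUN = seq_along) - 1L
  rownames(genes) <- NULL
  structure(list(name = name, genes = genes,
                 ploidy_events = as.character(ploidy_events)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d genes on %d chromosomes\n",
              x$name, nrow(x$genes), length(unique(x$genes$chrom))))
  if (length(x$ploidy_events))
    cat("  ploidy events:", paste(x$ploidy_events, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
summary.genome <- function(object, ...) {
  tab <- table(object$genes$chrom)
  cat(sprintf("Genome %s: %d genes, %d chromosomes\n",
              object$name, nrow(object$genes), length(tab)))
  print(tab)
  invisible(tab)
}

#' Load gene annotations from GFF3 or BED
#'
#' Reads gene features into a [new_genome()] object. Input need not be
#' coordinate-sorted; genes are sorted and ranked per chromosome. Duplicated
#' gene ids are rejected.
#'
#' @param path file path.
#' @param format `"gff3"` (1-based inclusive; features of type in `feature`
#'   are used, ids from the `ID` attribute) or `"bed"` (BED6, 0-based
#'   half-open, ids from column 4).
#' @param genome_name name to give the genome.
#' @param feature GFF3 feature types to keep (default `"gene"`).
#' @param ploidy_events passed to [new_genome()].
#' @return a `genome` object.
#' @export
load_gene_annotations <- function(path, format = c("gff3", "bed"),
                                  genome_name, feature = "gene",
                                  ploidy_events = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "gff3") {
    df <- df[as.character(df$type) %in% feature, , drop = FALSE]
    if (!nrow(df)) stop("no '", paste(feature, collapse = "/"),
                        "' features in ", path)
    if (is.null(df$ID) || anyNA(df$ID))
      stop("GFF3 feature(s) of type ", paste(feature, collapse = "/"),
           " without ID attribute in ", path)
    ids <- as.character(df$ID)
  } else {
    if (is.null(df$name) || anyNA(df$name))
      stop("BED input needs a name column (BED4+): ", path)
    ids <- as.character(df$name)
  }
  # rtracklayer yields 1-based inclusive; internal storage is 0-based half-open
  genes <- data.frame(id = ids, chrom = as.character(df$seqnames),
                      start = df$start - 1L, end = df$end,
                      strand = as.character(df$strand),
                      stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  new_genome(genome_name, genes, ploidy_events = ploidy_events)
}

#' Write a genome's gene order to BED6
#'
#' Coordinates are written 0-based half-open; score column carries the
#' `order_index`, so a written file reloads to an identical genome.
#'
#' @param genome a `genome` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_bed <- function(genome, path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand, name = g$id, score = g$order_index)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Load CDS sequences from FASTA
#'
#' @param paths one or more FASTA files.
#' @return named character vector of uppercase sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
load_cds_fasta <- function(paths) {
  out <- character()
  for (p in paths) {
    if (!file.exists(p)) stop("no such file: ", p)
    ss <- Biostrings::readDNAStringSet(p)
    seqs <- toupper(as.character(ss))
    names(seqs) <- sub("\\s.*", "", names(ss))
    out <- c(out, seqs)
  }
  if (anyDuplicated(names(out)))
    stop("duplicate sequence id(s): ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Load homology hits from 12-column BLAST tabular output
#'
#' Reads `outfmt 6` rows into a hit table. Self-hits (query == subject) are
#' dropped. Malformed rows are rejected with their line number.
#'
#' @param path BLAST tabular file.
#' @return data.frame with columns `query`, `subject`, `pident`, `evalue`,
#'   `score` (the bit score).
#' @export
load_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (!length(ln))
    return(data.frame(query = character(), subject = character(),
                      pident = numeric(), evalue = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("malformed BLAST tabular row (", lengths(fields)[bad[1]],
         " columns, expected 12) at line ", bad[1])
  m <- do.call(rbind, fields)
  hits <- data.frame(query = m[, 1], subject = m[, 2],
                     pident = as.numeric(m[, 3]),
                     evalue = as.numeric(m[, 11]),
                     score = as.numeric(m[, 12]),
                     stringsAsFactors = FALSE)
  if (anyNA(hits$evalue) || anyNA(hits$score))
    stop("non-numeric evalue/score at line ",
         which(is.na(hits$evalue) | is.na(hits$score))[1])
  if (any(hits$evalue < 0)) stop("negative E-value at line ",
                                 which(hits$evalue < 0)[1])
  hits[hits$query != hits$subject, , drop = FALSE]
}

#' Write hits as 12-column BLAST tabular
#'
#' Only query, subject, percent identity, E-value and bit score carry
#' information; the remaining columns are filled with placeholders so that
#' the file parses as standard `outfmt 6`.
#' @param hits hit data.frame (see [load_hits()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  pid <- if (is.null(hits$pident)) rep(100, n) else hits$pident
  df <- data.frame(hits$query, hits$subject, pid,
                   100L, 0L, 0L, 1L, 100L, 1L, 100L,
                   format(hits$evalue, scientific = TRUE),
                   hits$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene family sizes from the homology-hit graph
#'
#' The family size of a gene is one plus its number of distinct homology
#' partners among hits passing the E-value screen (the gene itself counts as
#' one member). By default partners are pooled across all genomes; set
#' `within_genome = TRUE` (and supply `genomes`) to count only same-genome
#' partners.
#'
#' @param hits hit data.frame.
#' @param max_evalue hits with `evalue >= max_evalue` are ignored.
#' @param genomes optional list of `genome` objects (required for
#'   `within_genome`).
#' @param within_genome restrict partners to the gene's own genome.
#' @return named integer vector of family sizes.
#' @export
compute_family_sizes <- function(hits, max_evalue = 1e-5, genomes = NULL,
                                 within_genome = FALSE) {
  h <- hits[hits$evalue < max_evalue, c("query", "subject"), drop = FALSE]
  if (within_genome) {
    if (is.null(genomes)) stop("within_genome = TRUE requires `genomes`")
    g_of <- gene_genome_map(genomes)
    h <- h[!is.na(g_of[h$query]) & !is.na(g_of[h$subject]) &
             g_of[h$query] == g_of[h$subject], , drop = FALSE]
  }
  edges <- unique(rbind(
    data.frame(a = h$query, b = h$subject, stringsAsFactors = FALSE),
    data.frame(a = h$subject, b = h$query, stringsAsFactors = FALSE)))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  deg <- table(edges$a)
  fam <- as.integer(deg) + 1L
  names(fam) <- names(deg)
  fam
}

gene_genome_map <- function(genomes) {
  ids <- unlist(lapply(genomes, function(g) g$genes$id), use.names = FALSE)
  nms <- unlist(lapply(genomes, function(g) rep(g$name, nrow(g$genes))),
                use.names = FALSE)
  stats::setNames(nms, ids)
}

#' Filter homology hits for synteny analysis
#'
#' Retains hits with `evalue < max_evalue`, `score > min_score` (both strict,
#' matching the conventional BLASTP screen) and both genes in families of
#' fewer than `max_family` members. Family sizes are computed from the
#' E-value-screened hit graph unless supplied.
#'
#' @param hits hit data.frame.
#' @param genomes optional list of `genome` objects (used for
#'   `within_genome` family counting).
#' @param max_evalue,min_score,max_family filter thresholds.
#' @param family_sizes optional named vector overriding graph-based counts.
#' @param within_genome see [compute_family_sizes()].
#' @return filtered hit data.frame; the operation is idempotent.
#' @export
filter_hits <- function(hits, genomes = NULL, max_evalue = 1e-5,
                        min_score = 100, max_family = 50,
                        family_sizes = NULL, within_genome = FALSE) {
  keep <- hits$evalue < max_evalue & hits$score > min_score
  h <- hits[keep, , drop = FALSE]
  if (is.null(family_sizes))
    family_sizes <- compute_family_sizes(hits, max_evalue = max_evalue,
                                         genomes = genomes,
                                         within_genome = within_genome)
  fam <- function(id) {
    f <- family_sizes[id]
    f[is.na(f)] <- 1L
    f
  }
  h <- h[fam(h$query) < max_family & fam(h$subject) < max_family, ,
         drop = FALSE]
  rownames(h) <- NULL
  h
}
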