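# Nei-Gojobori (1986) Ka/Ks on codon alignments. Potential sites are the
# per-codon fractions of single-nucleotide fates that are synonymous
# (mutations creating stop codons count as nonsynonymous, so S + N = 3n);
# observed differences average the minimal mutational pathways between two
# codons with equal weight, excluding pathways through stop codons.

.ng_env <- new.env(parent = emptyenv())

ng_bases <- c("A", "C", "G", "T")

ng_codons <- function() {
  g <- expand.grid(p3 = ng_bases, p2 = ng_bases, p1 = ng_bases,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

ng_translate <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

ng_tables <- function() {
  if (!is.null(.ng_env$tab)) return(.ng_env$tab)
  codons <- ng_codons()
  aa <- ng_translate(codons)
  names(aa) <- codons
  is_stop <- aa == "*"

  mutate1 <- function(codon, pos, base) {
    s <- strsplit(codon, "")[[1]]
    s[pos] <- base
    paste(s, collapse = "")
  }

  # fractional synonymous sites per codon
  syn_sites <- stats::setNames(numeric(length(codons)), codons)
  for (cd in codons[!is_stop]) {
    s <- 0
    for (pos in 1:3) {
      cur <- substr(cd, pos, pos)
      for (b in setdiff(ng_bases, cur)) {
        m <- mutate1(cd, pos, b)
        if (!is_stop[[m]] && aa[[m]] == aa[[cd]]) s <- s + 1 / 3
      }
    }
    syn_sites[[cd]] <- s
  }

  # pathway-averaged synonymous/nonsynonymous differences per codon pair
  sd_mat <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (i == j || is_stop[i] || is_stop[j]) next
      x <- codons[i]; y <- codons[j]
      d <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
      if (!length(d)) next
      ords <- perms[[as.character(length(d))]]
      path_syn <- numeric(); path_non <- numeric(); valid <- logical()
      for (ord in ords) {
        cur <- x; sy <- 0; no <- 0; ok <- TRUE
        for (step in seq_along(ord)) {
          pos <- d[ord[step]]
          nxt <- mutate1(cur, pos, substr(y, pos, pos))
          if (is_stop[[nxt]] && step < length(ord)) ok <- FALSE
          if (is_stop[[nxt]] || is_stop[[cur]] ||
              aa[[nxt]] != aa[[cur]]) no <- no + 1 else sy <- sy + 1
          cur <- nxt
        }
        path_syn <- c(path_syn, sy); path_non <- c(path_non, no)
        valid <- c(valid, ok)
      }
      use <- if (any(valid)) valid else rep(TRUE, length(valid))
      sd_mat[i, j] <- mean(path_syn[use])
      nd_mat[i, j] <- mean(path_non[use])
    }
  }
  .ng_env$tab <- list(syn_sites = syn_sites, sd = sd_mat, nd = nd_mat,
                      aa = aa, is_stop = is_stop)
  .ng_env$tab
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Build an aligned codon pair from two CDS sequences
#'
#' Pairs codons either positionally (equal-length CDSs) or through a protein
#' alignment whose degapped sequences must match the CDS translations. Codon
#' columns containing an alignment gap or any non-ACGT character in either
#' sequence are dropped pairwise. Internal stop codons are rejected; a
#' terminal stop present in both sequences is trimmed.
#'
#' @param cds_a,cds_b coding sequences (lengths multiples of 3).
#' @param protein_alignment optional list/vector of two equal-length aligned
#'   amino-acid strings (gap `"-"`), in the order (a, b).
#' @return object of class `codon_pair`: list with `codons_a`, `codons_b`,
#'   `n_codons`.
#' @export
make_codon_pair <- function(cds_a, cds_b, protein_alignment = NULL) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) %% 3L != 0L || nchar(cds_b) %% 3L != 0L)
    stop("CDS length is not a multiple of 3")
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  tab <- ng_tables()
  trans <- function(cod) {
    aa <- rep(NA_character_, length(cod))
    known <- cod %in% names(tab$aa)
    aa[known] <- tab$aa[cod[known]]
    aa
  }
  check_stops <- function(cod, label) {
    aa <- trans(cod)
    internal <- which(!is.na(aa) & aa == "*")
    internal <- internal[internal < length(cod)]
    if (length(internal))
      stop("internal stop codon in sequence ", label,
           " at codon ", internal[1])
  }
  check_stops(ca, "a"); check_stops(cb, "b")
  # trim a terminal stop
  if (length(ca) && !is.na(trans(ca[length(ca)])) &&
      trans(ca[length(ca)]) == "*") ca <- ca[-length(ca)]
  if (length(cb) && !is.na(trans(cb[length(cb)])) &&
      trans(cb[length(cb)]) == "*") cb <- cb[-length(cb)]

  if (is.null(protein_alignment)) {
    if (length(ca) != length(cb))
      stop("CDS lengths differ and no protein alignment was given")
  } else {
    pa <- strsplit(toupper(protein_alignment[[1]]), "")[[1]]
    pb <- strsplit(toupper(protein_alignment[[2]]), "")[[1]]
    if (length(pa) != length(pb))
      stop("aligned protein sequences differ in length")
    if (sum(pa != "-") != length(ca) || sum(pb != "-") != length(cb))
      stop("protein alignment does not match CDS translations")
    ia <- ib <- 0L
    keep_a <- integer(0); keep_b <- integer(0)
    for (k in seq_along(pa)) {
      if (pa[k] != "-") ia <- ia + 1L
      if (pb[k] != "-") ib <- ib + 1L
      if (pa[k] != "-" && pb[k] != "-") {
        keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
      }
    }
    ca <- ca[keep_a]; cb <- cb[keep_b]
  }
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  structure(list(codons_a = ca, codons_b = cb, n_codons = length(ca)),
            class = "codon_pair")
}

#' Nei-Gojobori Ka and Ks for a codon pair
#'
#' Potential synonymous (S) and nonsynonymous (N) site counts are averaged
#' over the two sequences; observed differences weight all minimal
#' mutational pathways equally, excluding pathways through stop codons.
#' Proportions are corrected with the Jukes-Cantor formula
#' d = -(3/4) log(1 - (4/3) p), undefined for p >= 3/4 (saturation).
#'
#' @param pair a [make_codon_pair()] object.
#' @return list with `Ka`, `Ks` (NA when undefined), `S`, `N`, `Sd`, `Nd`,
#'   and `status` (`"ok"`, `"saturated"`, or `"no_synonymous_sites"`);
#'   `S + N` always equals `3 * n_codons`.
#' @export
nei_gojobori <- function(pair) {
  stopifnot(inherits(pair, "codon_pair"))
  tab <- ng_tables()
  n <- pair$n_codons
  if (n == 0L)
    return(list(Ka = NA_real_, Ks = NA_real_, S = 0, N = 0, Sd = 0, Nd = 0,
                status = "empty"))
  s_a <- sum(tab$syn_sites[pair$codons_a])
  s_b <- sum(tab$syn_sites[pair$codons_b])
  S <- (s_a + s_b) / 2
  N <- 3 * n - S
  idx <- cbind(match(pair$codons_a, names(tab$syn_sites)),
               match(pair$codons_b, names(tab$syn_sites)))
  Sd <- sum(tab$sd[idx])
  Nd <- sum(tab$nd[idx])
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  status <- "ok"
  if (S <= 0) {
    Ks <- NA_real_
    status <- "no_synonymous_sites"
  } else {
    pS <- Sd / S
    Ks <- jc(pS)
    if (is.na(Ks)) status <- "saturated"
  }
  Ka <- if (N > 0) jc(Nd / N) else NA_real_
  list(Ka = Ka, Ks = Ks, S = S, N = N, Sd = Sd, Nd = Nd, status = status)
}

#' Ka/Ks for a table of gene pairs
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param cds named character vector of CDS sequences.
#' @return `pairs` with added columns `Ka`, `Ks`, `S`, `N`, `status`.
#' @export
ks_for_pairs <- function(pairs, cds) {
  miss <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(miss))
    stop("CDS missing for gene(s): ", paste(utils::head(miss, 3), collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- make_codon_pair(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
    nei_gojobori(p)
  })
  pairs$Ka <- vapply(res, `[[`, numeric(1), "Ka")
  pairs$Ks <- vapply(res, `[[`, numeric(1), "Ks")
  pairs$S <- vapply(res, `[[`, numeric(1), "S")
  pairs$N <- vapply(res, `[[`, numeric(1), "N")
  pairs$status <- vapply(res, `[[`, character(1), "status")
  pairs
}

#' Attach per-anchor Ks values and the block Ks median
#'
#' @param block a `synteny_block`.
#' @param cds named character vector of CDS sequences, or a precomputed
#'   data.frame from [ks_for_pairs()] with columns `gene_a`, `gene_b`, `Ks`.
#' @return the block with `anchors$ks` filled and `ks_median` set (median
#'   over anchors with defined Ks; `NA` and `flag = "all_ks_missing"` when
#'   no anchor has a defined value).
#' @export
annotate_block_ks <- function(block, cds) {
  anchors <- block$anchors
  if (is.data.frame(cds)) {
    key <- paste(cds$gene_a, cds$gene_b, sep = "\r")
    key2 <- paste(cds$gene_b, cds$gene_a, sep = "\r")
    lut <- stats::setNames(c(cds$Ks, cds$Ks), c(key, key2))
    ks <- unname(lut[paste(anchors$gene_a, anchors$gene_b, sep = "\r")])
  } else {
    tabd <- ks_for_pairs(data.frame(gene_a = anchors$gene_a,
                                    gene_b = anchors$gene_b,
                                    stringsAsFactors = FALSE), cds)
    ks <- tabd$Ks
  }
  block$anchors$ks <- ks
  if (all(is.na(ks))) {
    block$ks_median <- NA_real_
    block$flag <- "all_ks_missing"
  } else {
    block$ks_median <- stats::median(ks, na.rm = TRUE)
  }
  block
}
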