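# Independent oracles and fixture builders used across the suite.

# ---- toy genome builders -------------------------------------------------

toy_genome <- function(name, n_chrom = 1L, genes_per_chrom = 10L) {
  rows <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
    data.frame(id = sprintf("%s_c%dg%02d", name, ci, seq_len(genes_per_chrom)),
               chrom = sprintf("%s_chr%d", name, ci),
               start = (seq_len(genes_per_chrom) - 1L) * 100L,
               end = (seq_len(genes_per_chrom) - 1L) * 100L + 90L,
               stringsAsFactors = FALSE)
  }))
  new_genome(name, rows)
}

toy_hits <- function(query, subject, evalue = 1e-50, score = 200) {
  data.frame(query = query, subject = subject, pident = 90,
             evalue = evalue, score = score, stringsAsFactors = FALSE)
}

# ---- exhaustive codon-fate Nei-Gojobori oracle ---------------------------
# Written independently of the package implementation: direct loops over
# the 9 single-nucleotide fates per codon for site counting, and explicit
# recursion over pathway orderings for multi-hit codons.

oracle_ng <- local({
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  aa_of <- function(codon) unname(gc_tab[codon])

  syn_fraction <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (b in bases) {
        if (b == substr(codon, pos, pos)) next
        mut <- codon
        substr(mut, pos, pos) <- b
        if (aa_of(mut) != "*" && aa_of(mut) == aa_of(codon)) s <- s + 1 / 3
      }
    }
    s
  }

  path_counts <- function(x, y) {
    d <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (!length(d)) return(c(sd = 0, nd = 0))
    enumerate <- function(cur, remaining) {
      if (!length(remaining)) return(list(c(sd = 0, nd = 0, ok = 1)))
      out <- list()
      for (i in seq_along(remaining)) {
        pos <- remaining[i]
        nxt <- cur
        substr(nxt, pos, pos) <- substr(y, pos, pos)
        step_stop <- aa_of(nxt) == "*" && length(remaining) > 1L
        syn <- aa_of(nxt) != "*" && aa_of(cur) != "*" &&
          aa_of(nxt) == aa_of(cur)
        for (tail in enumerate(nxt, remaining[-i])) {
          out[[length(out) + 1L]] <- c(
            sd = unname(tail["sd"]) + as.numeric(syn),
            nd = unname(tail["nd"]) + as.numeric(!syn),
            ok = unname(tail["ok"]) * as.numeric(!step_stop))
        }
      }
      out
    }
    paths <- enumerate(x, d)
    m <- do.call(rbind, paths)
    ok <- m[, "ok"] == 1
    if (!any(ok)) ok <- rep(TRUE, nrow(m))
    c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
  }

  function(cds_a, cds_b) {
    split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    ca <- split3(cds_a); cb <- split3(cds_b)
    S <- (sum(vapply(ca, syn_fraction, numeric(1))) +
            sum(vapply(cb, syn_fraction, numeric(1)))) / 2
    N <- 3 * length(ca) - S
    sd <- nd <- 0
    for (i in seq_along(ca)) {
      pc <- path_counts(ca[i], cb[i])
      sd <- sd + pc["sd"]; nd <- nd + pc["nd"]
    }
    jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
    list(Ka = unname(jc(nd / N)),
         Ks = if (S > 0) unname(jc(sd / S)) else NA_real_,
         S = unname(S), N = unname(N), Sd = unname(sd), Nd = unname(nd))
  }
})

random_sense_cds <- function(n_codons) {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

mutate_cds <- function(cds, n_mut) {
  s <- strsplit(cds, "")[[1]]
  pos <- sample(length(s), n_mut)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  out <- paste(s, collapse = "")
  # resample if a stop codon was created (oracle and engine both reject)
  split3 <- substring(out, seq(1, nchar(out), 3), seq(3, nchar(out), 3))
  if (any(gc_tab_stops(split3))) return(mutate_cds(cds, n_mut))
  out
}

gc_tab_stops <- function(codons) {
  gc_tab <- Biostrings::GENETIC_CODE
  unname(gc_tab[codons] == "*")
}

# ---- independent longest-chain oracle ------------------------------------
# Length of the longest strictly monotone chain (either direction) under
# the intervening-gene gap bound, by a plain recursive search with
# memoisation over "longest chain starting at j".

oracle_longest_chain <- function(qi, si, max_gap) {
  lim <- max_gap + 1
  best_overall <- 0L
  for (dir in c(1, -1)) {
    n <- length(qi)
    if (!n) next
    q <- qi; s <- si * dir
    memo_len <- rep(NA_integer_, n)
    longest_from <- function(j) {
      if (!is.na(memo_len[j])) return(memo_len[j])
      best_l <- 1L
      for (k in seq_len(n)) {
        if (q[k] > q[j] && q[k] <= q[j] + lim &&
            s[k] > s[j] && s[k] <= s[j] + lim) {
          l <- 1L + longest_from(k)
          if (l > best_l) best_l <- l
        }
      }
      memo_len[j] <<- best_l
      best_l
    }
    lens <- vapply(seq_len(n), longest_from, integer(1))
    best_overall <- max(best_overall, max(lens))
  }
  best_overall
}

# block structural invariants: strict monotonicity and gap bound
expect_block_invariants <- function(block, max_gap, min_anchors) {
  a <- block$anchors
  expect_gte(nrow(a), min_anchors)
  expect_true(all(diff(a$order_a) > 0))
  expect_true(all(diff(a$order_a) <= max_gap + 1))
  if (block$orientation == "same") {
    expect_true(all(diff(a$order_b) > 0))
    expect_true(all(diff(a$order_b) <= max_gap + 1))
  } else {
    expect_true(all(diff(a$order_b) < 0))
    expect_true(all(-diff(a$order_b) <= max_gap + 1))
  }
}
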