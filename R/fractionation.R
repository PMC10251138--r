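# Post-polyploidy fractionation statistics over a reference-anchored
# alignment: sliding-window retention per subgenome copy, run lengths of
# consecutively lost genes with a one-parameter geometric model, subgenome
# assignment by fractionation rank (LF/MF1/MF2), and the P-index of
# between-subgenome retention asymmetry.

#' Sliding-window gene retention per subgenome copy
#'
#' Slides a window along the reference gene order of each chromosome and
#' counts, per subgenome slot, the reference genes whose ortholog is
#' retained (cell not `"."`). A chromosome shorter than the window yields a
#' single truncated window, flagged.
#'
#' @param cells character matrix or data.frame of alignment-table cells
#'   (rows = reference genes in order, columns = subgenome slots; `"."`
#'   marks a lost/translocated ortholog).
#' @param chrom character vector of reference chromosomes, one per row.
#' @param window window size in genes (default 50).
#' @param step step between window starts (default `window / 2`).
#' @return data.frame with `chrom`, `start_index`, `end_index` (1-based,
#'   inclusive), one retained-count column per slot, and `flag`.
#' @export
retention_profile <- function(cells, chrom, window = 50L,
                              step = max(1L, window %/% 2L)) {
  cells <- as.matrix(cells)
  stopifnot(nrow(cells) == length(chrom), window >= 1L, step >= 1L)
  slots <- colnames(cells)
  if (is.null(slots)) slots <- paste0("slot", seq_len(ncol(cells)))
  out <- list()
  for (ch in unique(chrom)) {
    m <- cells[chrom == ch, , drop = FALSE]
    n <- nrow(m)
    if (n < window) {
      starts <- 1L; ends <- n; flag <- "truncated_window"
    } else {
      starts <- seq(1L, n - window + 1L, by = step)
      ends <- starts + window - 1L
      flag <- NA_character_
    }
    counts <- t(vapply(seq_along(starts), function(i)
      colSums(m[starts[i]:ends[i], , drop = FALSE] != "."),
      numeric(ncol(m))))
    df <- data.frame(chrom = ch, start_index = starts, end_index = ends,
                     stringsAsFactors = FALSE)
    df[slots] <- counts
    df$flag <- flag
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run lengths of consecutively lost genes
#'
#' Maximal runs of `"."` cells along the reference gene order; runs never
#' span a chromosome boundary. The run lengths sum to the total dot count.
#'
#' @param column character vector of cells (gene id or `"."`) in reference
#'   order.
#' @param chrom optional chromosome per cell; runs break at boundaries.
#' @return integer vector of run lengths (possibly empty).
#' @export
loss_runs <- function(column, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("chr", length(column))
  out <- integer()
  for (ch in unique(chrom)) {
    v <- column[chrom == ch] == "."
    r <- rle(v)
    out <- c(out, r$lengths[r$values])
  }
  out
}

#' Fit the geometric loss-run model
#'
#' Models the length k of a run of consecutively lost genes as geometric:
#' `f(k | p) = (1 - p)^(k - 1) * p`, with `p` the expansion parameter. `p`
#' is estimated by least squares of the empirical length frequencies against
#' the model; the closed-form maximum-likelihood estimate `1 / mean(k)` is
#' reported alongside. The fit's coefficient of determination and the
#' regression F-test against the constant-mean model are returned.
#'
#' @param run_lengths integer vector of observed run lengths (>= `min_runs`
#'   unless a frequency table is given).
#' @param freq optional named numeric vector of length frequencies (names =
#'   k); overrides `run_lengths` for the least-squares fit.
#' @param min_runs minimum number of runs required (default 20).
#' @return object of class `geometric_loss_model`: list with `p` (least
#'   squares), `p_mle` (`1/mean`), `r_squared`, `f_statistic`, `f_test_p`,
#'   `n_runs`, `flag` (`"degenerate"` when all runs share one length, in
#'   which case `p` falls back to the closed form).
#' @export
fit_geometric <- function(run_lengths = NULL, freq = NULL, min_runs = 20L) {
  if (is.null(freq)) {
    if (is.null(run_lengths) || length(run_lengths) < min_runs)
      stop("need at least ", min_runs, " runs (or a frequency table)")
    stopifnot(all(run_lengths >= 1))
    tab <- table(run_lengths)
    freq <- as.numeric(tab) / length(run_lengths)
    names(freq) <- names(tab)
    n_runs <- length(run_lengths)
    p_mle <- 1 / mean(run_lengths)
  } else {
    stopifnot(!is.null(names(freq)), all(freq >= 0))
    n_runs <- NA_integer_
    k_all <- as.numeric(names(freq))
    p_mle <- 1 / (sum(k_all * freq) / sum(freq))
  }
  k <- as.numeric(names(freq))
  if (length(k) == 1L) {
    return(structure(list(p = p_mle, p_mle = p_mle, r_squared = NA_real_,
                          f_statistic = NA_real_, f_test_p = NA_real_,
                          n_runs = n_runs, freq = freq, flag = "degenerate"),
                     class = "geometric_loss_model"))
  }
  model <- function(p) (1 - p)^(k - 1) * p
  sse <- function(p) sum((freq - model(p))^2)
  opt <- stats::optimize(sse, interval = c(1e-6, 1), tol = 1e-9)
  # the boundary p = 1 (all runs length 1) is not interior to optimize()
  p_hat <- if (sse(1) < opt$objective) 1 else opt$minimum
  ss_res <- sse(p_hat)
  ss_tot <- sum((freq - mean(freq))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  m <- length(k)
  f_stat <- f_p <- NA_real_
  if (m > 2L && ss_res > 0) {
    f_stat <- (ss_tot - ss_res) / (ss_res / (m - 2L))
    f_p <- stats::pf(f_stat, 1, m - 2L, lower.tail = FALSE)
  }
  structure(list(p = p_hat, p_mle = p_mle, r_squared = r2,
                 f_statistic = f_stat, f_test_p = f_p,
                 n_runs = n_runs, freq = freq, flag = NA_character_),
            class = "geometric_loss_model")
}

#' @export
print.geometric_loss_model <- function(x, ...) {
  cat(sprintf("<geometric_loss_model> p = %.4f (MLE 1/mean = %.4f)%s\n",
              x$p, x$p_mle,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  if (!is.na(x$r_squared))
    cat(sprintf("  R^2 = %.4f, F = %.3g (p = %.3g)\n",
                x$r_squared, x$f_statistic, x$f_test_p))
  invisible(x)
}

#' @export
coef.geometric_loss_model <- function(object, ...) c(p = object$p)

#' Rank subgenome copies by fractionation (LF / MF1 / MF2)
#'
#' For each homologous region, the copy retaining the most reference
#' orthologs is labelled LF (least fractionated), the middle copy MF1, and
#' the copy retaining fewest MF2. Ties are broken by the total retained
#' genes on the harbouring chromosome, then lexicographically by copy id;
#' tie-broken regions are flagged.
#'
#' @param retention data.frame with columns `region`, `copy`, `retained`,
#'   and optionally `chrom` (harbouring chromosome of the copy).
#' @return list with `regions` (input plus `label` and `tie` columns) and,
#'   when `chrom` is present, `chromosomes` (modal label per copy
#'   chromosome, the region-stitched subgenome assembly).
#' @export
assign_subgenomes <- function(retention) {
  need <- c("region", "copy", "retained")
  if (!all(need %in% names(retention)))
    stop("`retention` needs columns: ", paste(need, collapse = ", "))
  labs3 <- c("LF", "MF1", "MF2")
  has_chrom <- "chrom" %in% names(retention)
  chrom_tot <- if (has_chrom)
    tapply(retention$retained, retention$chrom, sum) else NULL
  out <- lapply(split(retention, retention$region), function(r) {
    if (nrow(r) != 3L)
      stop("region ", r$region[1], " has ", nrow(r),
           " copies; subgenome ranking needs exactly 3")
    tb1 <- if (has_chrom) -as.numeric(chrom_tot[r$chrom]) else rep(0, 3)
    o <- order(-r$retained, tb1, r$copy)
    r$label[o] <- labs3
    r$tie <- anyDuplicated(r$retained) > 0L
    r
  })
  regions <- do.call(rbind, out)
  rownames(regions) <- NULL
  res <- list(regions = regions)
  if (has_chrom) {
    modal <- vapply(split(regions$label, regions$chrom), function(l) {
      tl <- table(l)
      names(tl)[which.max(tl)]
    }, character(1))
    res$chromosomes <- data.frame(chrom = names(modal), label = unname(modal),
                                  stringsAsFactors = FALSE)
  }
  res
}

#' Test for divergent retention across subgenome copies
#'
#' Chi-square goodness-of-fit of retained gene counts against equal
#' retention across copies (`df = copies - 1`). When any expected count is
#' below 5 the exact multinomial tail probability is computed instead
#' (flagged).
#'
#' @param counts integer vector of retained counts, one per copy (>= 2
#'   copies, positive total).
#' @return list with `statistic`, `df`, `p_value`, `method`.
#' @export
retention_divergence_test <- function(counts) {
  k <- length(counts)
  stopifnot(k >= 2L, sum(counts) > 0)
  n <- sum(counts)
  expected <- n / k
  stat <- sum((counts - expected)^2 / expected)
  if (expected >= 5) {
    return(list(statistic = stat, df = k - 1L,
                p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
                method = "chisq"))
  }
  # exact multinomial: total probability of outcomes at least as extreme
  if (n <= 200L && k <= 4L) {
    comps <- compositions_of(n, k)
    stats_ <- rowSums((comps - expected)^2 / expected)
    probs <- apply(comps, 1, function(x) stats::dmultinom(x, prob = rep(1 / k, k)))
    p <- sum(probs[stats_ >= stat - 1e-12])
    return(list(statistic = stat, df = k - 1L, p_value = p,
                method = "exact_multinomial"))
  }
  sim <- stats::chisq.test(counts, p = rep(1 / k, k),
                           simulate.p.value = TRUE, B = 1e5)
  list(statistic = stat, df = k - 1L, p_value = sim$p.value,
       method = "simulated_multinomial")
}

compositions_of <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    sub <- compositions_of(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, sub)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Percentage of reference genes lost from syntenic positions
#'
#' @param lost number of reference genes with no retained ortholog.
#' @param total number of reference genes considered.
#' @return percentage (0-100).
#' @export
percent_lost <- function(lost, total) {
  stopifnot(total > 0, lost >= 0, lost <= total)
  100 * lost / total
}

#' P-index of biased subgenome fractionation
#'
#' Windowed statistic of retention asymmetry between two subgenome copies.
#' Per chromosome c with windows i, each divergent window contributes the
#' sign of `A_i - B_i`; the signed sum is divided by the number of
#' non-tied windows, its absolute value taken, and chromosomes combined
#' with weights proportional to their window counts. Tied windows
#' (`|A_i - B_i| <= min_diff`) contribute nothing and are excluded from the
#' denominator; a chromosome with only tied windows is excluded and the
#' weights renormalized. With more than two copies the index is averaged
#' over all copy pairs. An allopolyploid-like biased loss pattern gives
#' values above 0.3; balanced (auto-like) loss stays below.
#'
#' @param counts matrix or data.frame of per-window retained counts, one
#'   column per subgenome copy (>= 2).
#' @param chrom chromosome id per window (row).
#' @param min_diff smallest `|A - B|` counted as divergence (default 0: any
#'   difference).
#' @return P-index in `[0, 1]` (0 when every window is tied).
#' @export
p_index <- function(counts, chrom, min_diff = 0) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2L, nrow(counts) == length(chrom))
  pairs <- utils::combn(ncol(counts), 2L)
  vals <- apply(pairs, 2L, function(pr)
    p_index_pair(counts[, pr[1]], counts[, pr[2]], chrom, min_diff))
  mean(vals)
}

p_index_pair <- function(A, B, chrom, min_diff = 0) {
  terms <- c(); sizes <- c()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    d <- A[sel] - B[sel]
    div <- abs(d) > min_diff
    n_div <- sum(div)
    if (n_div == 0L) next  # all tied: chromosome excluded
    terms <- c(terms, abs(sum(sign(d[div])) / n_div))
    sizes <- c(sizes, sum(sel))
  }
  if (!length(terms)) return(0)
  w <- sizes / sum(sizes)
  sum(w * terms)
}
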