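# Karyotypes are lists of chromosomes; a chromosome is an ordered vector of
# signed segment ids ("A4", "-Q5"). A chromosome read backwards (reversed,
# all signs flipped) is the same chromosome.

seg_id <- function(s) sub("^-", "", s)
seg_neg <- function(s) ifelse(startsWith(s, "-"), sub("^-", "", s),
                              paste0("-", s))
flip_chrom <- function(chr) rev(seg_neg(chr))

#' Construct a karyotype
#'
#' @param chromosomes list of character vectors of signed segment ids
#'   (a leading `-` marks reverse orientation). Every segment id must occur
#'   exactly once and no chromosome may be empty.
#' @param name optional karyotype name.
#' @return object of class `karyotype`.
#' @export
new_karyotype <- function(chromosomes, name = "") {
  if (!length(chromosomes) || any(lengths(chromosomes) == 0L))
    stop("karyotype must have no empty chromosomes")
  ids <- seg_id(unlist(chromosomes, use.names = FALSE))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("segment id(s) occur more than once: ", paste(dup, collapse = ", "))
  structure(list(name = name, chromosomes = unname(chromosomes)),
            class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("<karyotype> %s: %d chromosomes, %d segments\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$chromosomes),
              length(unlist(x$chromosomes))))
  for (i in seq_along(x$chromosomes))
    cat(sprintf("  chr%-3d %s\n", i, paste(x$chromosomes[[i]], collapse = " ")))
  invisible(x)
}

#' @export
format.karyotype <- function(x, ...)
  vapply(x$chromosomes, paste, character(1), collapse = " ")

#' Write/read karyotypes as structured text (one chromosome per line)
#' @param karyotype a `karyotype`.
#' @param path file path.
#' @return `path` invisibly, or a `karyotype` for the reader.
#' @export
write_karyotype <- function(karyotype, path) {
  writeLines(format(karyotype), path)
  invisible(path)
}

#' @rdname write_karyotype
#' @param name name for the loaded karyotype.
#' @export
read_karyotype <- function(path, name = "") {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  new_karyotype(strsplit(trimws(ln), "\\s+"), name = name)
}

#' Build a chromosome rearrangement event
#'
#' Event kinds and their chromosome-count effects:
#' * `EEJ` — end-to-end joining: chromosome `b` (optionally flipped) is
#'   appended to `a`; count decreases by 1.
#' * `NCF` — nested chromosome fusion: whole chromosome `b` inserted at an
#'   internal breakpoint of `a` (after segment `pos_a`, `1 <= pos_a < length`);
#'   count decreases by 1. A terminal breakpoint is an `EEJ`, not an `NCF`.
#' * `RCT` — reciprocal translocation: terminal portions after `pos_a`/`pos_b`
#'   are exchanged between `a` and `b`; count unchanged.
#' * `NCT` — nonreciprocal translocation: the run `from..to` of chromosome `a`
#'   moves into chromosome `b` after position `pos_b`; count unchanged.
#' * `FISSION` — chromosome `a` splits after `pos_a`; count increases by 1.
#' * `WGD`/`WGT` — whole-genome duplication/triplication: every chromosome is
#'   copied with segment ids suffixed by the copy labels; count x2 / x3.
#'
#' @param kind one of `"EEJ"`, `"NCF"`, `"RCT"`, `"NCT"`, `"FISSION"`,
#'   `"WGD"`, `"WGT"`.
#' @param a,b chromosome indices.
#' @param pos_a,pos_b breakpoint positions (number of segments kept on the
#'   left; 0 allowed for `RCT`/`NCT` insertion points).
#' @param from,to segment-run bounds for `NCT`.
#' @param flip flip chromosome `b` (or the moved run) before joining.
#' @param copy_labels suffixes for `WGD`/`WGT` copies (defaults `~1`, `~2`,
#'   `~3`).
#' @return object of class `rearrangement_event`.
#' @export
rearrangement_event <- function(kind, a = NA, b = NA, pos_a = NA, pos_b = NA,
                                from = NA, to = NA, flip = FALSE,
                                copy_labels = NULL) {
  kind <- match.arg(kind, c("EEJ", "NCF", "RCT", "NCT", "FISSION",
                            "WGD", "WGT"))
  structure(list(kind = kind, a = a, b = b, pos_a = pos_a, pos_b = pos_b,
                 from = from, to = to, flip = flip,
                 copy_labels = copy_labels),
            class = "rearrangement_event")
}

#' Apply a rearrangement event to a karyotype
#'
#' The segment multiset is conserved by every event except `WGD`/`WGT`,
#' which multiply it by 2/3 with copy-suffixed ids.
#'
#' @param karyotype a `karyotype`.
#' @param event a [rearrangement_event()].
#' @return the rearranged `karyotype`.
#' @export
apply_event <- function(karyotype, event) {
  ch <- karyotype$chromosomes
  n <- length(ch)
  chk_idx <- function(i) {
    if (is.na(i) || i < 1L || i > n) stop("chromosome index out of range: ", i)
    as.integer(i)
  }
  out <- switch(
    event$kind,
    EEJ = {
      a <- chk_idx(event$a); b <- chk_idx(event$b)
      if (a == b) stop("EEJ needs two distinct chromosomes")
      joined <- c(ch[[a]], if (isTRUE(event$flip)) flip_chrom(ch[[b]]) else ch[[b]])
      c(ch[-c(a, b)], list(joined))
    },
    NCF = {
      a <- chk_idx(event$a); b <- chk_idx(event$b)
      if (a == b) stop("NCF needs two distinct chromosomes")
      p <- event$pos_a
      if (is.na(p) || p < 1L || p >= length(ch[[a]]))
        stop("NCF breakpoint must be internal (a terminal join is an EEJ)")
      ins <- if (isTRUE(event$flip)) flip_chrom(ch[[b]]) else ch[[b]]
      host <- ch[[a]]
      c(ch[-c(a, b)], list(c(host[seq_len(p)], ins,
                             host[seq(p + 1L, length(host))])))
    },
    RCT = {
      a <- chk_idx(event$a); b <- chk_idx(event$b)
      if (a == b) stop("RCT needs two distinct chromosomes")
      pa <- event$pos_a; pb <- event$pos_b
      ca <- ch[[a]]; cb <- ch[[b]]
      if (is.na(pa) || pa < 0L || pa > length(ca) ||
          is.na(pb) || pb < 0L || pb > length(cb))
        stop("RCT breakpoints out of range")
      na_ <- c(ca[seq_len(pa)], if (pb < length(cb)) cb[seq(pb + 1L, length(cb))])
      nb_ <- c(cb[seq_len(pb)], if (pa < length(ca)) ca[seq(pa + 1L, length(ca))])
      if (!length(na_) || !length(nb_))
        stop("RCT would produce an empty chromosome")
      ch[[a]] <- na_; ch[[b]] <- nb_
      ch
    },
    NCT = {
      a <- chk_idx(event$a); b <- chk_idx(event$b)
      if (a == b) stop("NCT needs two distinct chromosomes")
      ca <- ch[[a]]
      if (is.na(event$from) || is.na(event$to) ||
          event$from < 1L || event$to > length(ca) || event$from > event$to)
        stop("NCT segment run crosses chromosome ends")
      if (event$from == 1L && event$to == length(ca))
        stop("NCT cannot move a whole chromosome (that is EEJ/NCF)")
      run <- ca[seq(event$from, event$to)]
      if (isTRUE(event$flip)) run <- flip_chrom(run)
      rest <- ca[-seq(event$from, event$to)]
      cb <- ch[[b]]
      pb <- event$pos_b
      if (is.na(pb) || pb < 0L || pb > length(cb))
        stop("NCT insertion point out of range")
      ch[[a]] <- rest
      ch[[b]] <- c(cb[seq_len(pb)], run,
                   if (pb < length(cb)) cb[seq(pb + 1L, length(cb))])
      ch
    },
    FISSION = {
      a <- chk_idx(event$a)
      p <- event$pos_a
      if (is.na(p) || p < 1L || p >= length(ch[[a]]))
        stop("fission breakpoint must be internal")
      ca <- ch[[a]]
      c(ch[-a], list(ca[seq_len(p)], ca[seq(p + 1L, length(ca))]))
    },
    WGD = ,
    WGT = {
      k <- if (event$kind == "WGD") 2L else 3L
      labs <- event$copy_labels
      if (is.null(labs)) labs <- paste0("~", seq_len(k))
      if (length(labs) != k) stop("need ", k, " copy labels")
      unlist(lapply(seq_len(k), function(ci) {
        lapply(ch, function(chr) {
          neg <- startsWith(chr, "-")
          paste0(ifelse(neg, "-", ""), seg_id(chr), labs[ci])
        })
      }), recursive = FALSE)
    },
    stop("unknown event kind: ", event$kind))
  new_karyotype(out, name = karyotype$name)
}

#' Chromosome count after a sequence of rearrangement events
#'
#' Fusions (`EEJ`, `NCF`) each reduce the count by one, fissions increase it
#' by one, translocations (`RCT`, `NCT`) leave it unchanged, and `WGD`/`WGT`
#' multiply it by 2/3; events are applied in order.
#'
#' @param initial_count starting chromosome number.
#' @param events character vector of event kinds in order (e.g.
#'   `c(rep("EEJ", 11), "NCF")`), or a list of [rearrangement_event()]s.
#' @return final chromosome count (integer).
#' @export
chromosome_count_after <- function(initial_count, events) {
  if (is.list(events))
    events <- vapply(events, function(e) e$kind, character(1))
  n <- as.integer(initial_count)
  if (n < 1L) stop("initial count must be >= 1")
  for (k in events) {
    n <- switch(k,
                EEJ = n - 1L, NCF = n - 1L, FISSION = n + 1L,
                RCT = n, NCT = n, WGD = n * 2L, WGT = n * 3L,
                stop("unknown event kind: ", k))
    if (n < 1L) stop("chromosome count dropped below 1")
  }
  n
}

#' Expected chromosome number under polyploidy without fusion
#'
#' The count a genome would reach if every polyploidization multiplied the
#' chromosome complement and no fusion ever occurred (e.g. a base of 7 with
#' two successive triplications gives 7 x 3 x 3 = 63).
#'
#' @param base ancestral chromosome number.
#' @param multipliers integer multipliers, one per polyploidy event
#'   (3 for a triplication, 2 for a duplication).
#' @return integer product.
#' @export
expected_chromosomes <- function(base, multipliers = integer()) {
  stopifnot(base >= 1)
  as.integer(base * prod(multipliers))
}

# ---- junction algebra ----------------------------------------------------

# A junction is the ordered adjacency of two signed segments; read backwards
# it is (-b, -a). The canonical form is whichever of the two readings sorts
# first, encoded "a|b".
canonical_junction <- function(a, b) {
  fwd <- paste(a, b, sep = "|")
  rev_ <- paste(seg_neg(b), seg_neg(a), sep = "|")
  ifelse(fwd <= rev_, fwd, rev_)
}

karyotype_junctions <- function(x) {
  ch <- if (inherits(x, "karyotype")) x$chromosomes else x
  out <- character()
  for (chr in ch) {
    if (length(chr) < 2L) next
    out <- c(out, canonical_junction(chr[-length(chr)], chr[-1L]))
  }
  unique(out)
}

junction_pair_key <- function(j) {
  parts <- strsplit(j, "|", fixed = TRUE)
  vapply(parts, function(p) paste(sort(seg_id(p)), collapse = "&"), character(1))
}

#' Infer rearrangement junctions shared by all descendants
#'
#' A segment adjacency present in every descendant genome but absent from the
#' outgroup karyotype is assigned, by Dollo-style parsimony, to the
#' descendants' common ancestor. Junctions whose two segments are adjacent in
#' all descendants but with conflicting relative orientations are excluded
#' and reported in the `conflicts` attribute.
#'
#' @param segment_maps named list of karyotypes (or lists of signed-segment
#'   chromosome vectors), one per descendant genome, expressed in ancestral
#'   segment coordinates.
#' @param outgroup a `karyotype` for the outgroup (pre-rearrangement state).
#' @return character vector of canonical junctions (`"a|b"`), with attribute
#'   `conflicts`.
#' @export
infer_shared_fusions <- function(segment_maps, outgroup) {
  if (length(segment_maps) < 1L) stop("need at least one descendant map")
  jsets <- lapply(segment_maps, karyotype_junctions)
  shared <- Reduce(intersect, jsets)
  out_j <- karyotype_junctions(outgroup)
  shared <- setdiff(shared, out_j)
  # orientation conflicts: same unordered pair adjacent everywhere, but the
  # canonical junction differs between descendants
  all_j <- unique(unlist(jsets))
  keys <- junction_pair_key(all_j)
  conflict_keys <- unique(keys[duplicated(keys)])
  conflicts <- all_j[keys %in% conflict_keys & all_j %in% shared]
  shared <- setdiff(shared, conflicts)
  structure(shared, conflicts = conflicts)
}

# split a canonical junction into its two signed segments
junction_sides <- function(j) strsplit(j, "|", fixed = TRUE)

#' Reconstruct an ancestral karyotype from descendant segment maps
#'
#' Assembles the karyotype of the descendants' most recent common ancestor
#' by chaining junctions: adjacencies shared by all descendants but absent
#' from the outgroup (derived in the ancestor), plus outgroup adjacencies
#' retained in at least one descendant (never broken before the ancestor).
#' Each segment end takes at most one adjacency; competing junctions are
#' resolved by descendant support, then lexicographically. Cycles are broken
#' at the junction with fewest supporting descendants, with a warning.
#'
#' @inheritParams infer_shared_fusions
#' @param min_segment_genes segments shorter than this many genes are dropped
#'   before junction analysis when segment lengths are supplied as the
#'   `gene_count` attribute of `segment_maps`; small inversions and minor
#'   deletions below the threshold are thereby ignored.
#' @return list with `karyotype` (the reconstructed ancestor) and `events`
#'   (data.frame of derived junctions classified as EEJ/NCF/RCT/NCT).
#' @export
reconstruct_ancestral_karyotype <- function(segment_maps, outgroup,
                                            min_segment_genes = 0L) {
  seg_len <- attr(segment_maps, "gene_count")
  if (!is.null(seg_len) && min_segment_genes > 0L) {
    drop <- names(seg_len)[seg_len < min_segment_genes]
    strip <- function(x) {
      ch <- if (inherits(x, "karyotype")) x$chromosomes else x
      ch <- lapply(ch, function(chr) chr[!seg_id(chr) %in% drop])
      ch[lengths(ch) > 0L]
    }
    segment_maps <- lapply(segment_maps, strip)
    outgroup <- new_karyotype(strip(outgroup), name = outgroup$name)
  }
  jsets <- lapply(segment_maps, karyotype_junctions)
  out_j <- karyotype_junctions(outgroup)
  derived <- infer_shared_fusions(segment_maps, outgroup)
  support <- function(j) sum(vapply(jsets, function(s) j %in% s, logical(1)))
  retained <- out_j[vapply(out_j, support, numeric(1)) >= 1L]
  cand <- data.frame(j = c(as.character(derived), retained),
                     derived = rep(c(TRUE, FALSE),
                                   c(length(derived), length(retained))),
                     stringsAsFactors = FALSE)
  cand$support <- vapply(cand$j, support, numeric(1))
  # derived junctions first (they define the ancestor), then by support
  cand <- cand[order(-cand$derived, -cand$support, cand$j), , drop = FALSE]

  segs <- seg_id(unlist(if (inherits(outgroup, "karyotype"))
    outgroup$chromosomes else outgroup, use.names = FALSE))
  # ends: each segment has "h" (left of +) and "t"; adjacency joins T(a)-L(b)
  end_of <- function(s, side) {
    # side "T" = trailing end, "L" = leading end, for signed segment s
    pos <- !startsWith(s, "-")
    id <- seg_id(s)
    if (side == "T") paste0(id, ifelse(pos, ".t", ".h"))
    else             paste0(id, ifelse(pos, ".h", ".t"))
  }
  used <- new.env(parent = emptyenv())
  adj <- list()
  kept <- character()
  for (i in seq_len(nrow(cand))) {
    p <- junction_sides(cand$j[i])[[1]]
    eT <- end_of(p[1], "T"); eL <- end_of(p[2], "L")
    if (is.null(used[[eT]]) && is.null(used[[eL]]) && eT != eL) {
      used[[eT]] <- TRUE; used[[eL]] <- TRUE
      adj[[length(adj) + 1L]] <- c(eT, eL)
      kept <- c(kept, cand$j[i])
    }
  }
  # assemble paths over ends: internal edge links X.h - X.t
  nbr <- new.env(parent = emptyenv())
  for (e in adj) {
    nbr[[e[1]]] <- e[2]
    nbr[[e[2]]] <- e[1]
  }
  visited <- new.env(parent = emptyenv())
  chroms <- list()
  kept_support <- stats::setNames(vapply(kept, support, numeric(1)), kept)
  for (s in segs) {
    if (!is.null(visited[[s]])) next
    # walk left from s.h, then right from s.t
    walk <- function(start_end) {
      path <- character()
      cur_end <- start_end
      repeat {
        nxt <- nbr[[cur_end]]
        if (is.null(nxt)) break
        id <- sub("\\.[ht]$", "", nxt)
        if (!is.null(visited[[id]])) break  # cycle guard
        visited[[id]] <- TRUE
        # entering at .h means oriented +, at .t means -
        sign_pos <- endsWith(nxt, ".h")
        path <- c(path, if (sign_pos) id else paste0("-", id))
        cur_end <- paste0(id, if (sign_pos) ".t" else ".h")
      }
      path
    }
    visited[[s]] <- TRUE
    left <- walk(paste0(s, ".h"))
    right <- walk(paste0(s, ".t"))
    chrom <- c(rev(seg_neg(left)), s, right)
    chroms[[length(chroms) + 1L]] <- chrom
  }
  anc <- new_karyotype(chroms, name = "ancestor")
  events <- classify_derived_junctions(kept[kept %in% as.character(derived)],
                                       anc, outgroup)
  list(karyotype = anc, events = events, junctions = kept)
}

# classify derived junctions against the outgroup structure: junctions that
# join two outgroup chromosome ends are EEJ; a whole outgroup chromosome
# flanked by the two halves of a broken outgroup adjacency is an NCF (its two
# flanking junctions count once); remaining junctions are translocations,
# reported RCT when two of them exchange terminal portions, else NCT.
classify_derived_junctions <- function(junctions, ancestor, outgroup) {
  if (!length(junctions))
    return(data.frame(kind = character(), junction = character(),
                      stringsAsFactors = FALSE))
  och <- outgroup$chromosomes
  term_ends <- unlist(lapply(och, function(chr) {
    c(paste0(seg_id(chr[1]), if (startsWith(chr[1], "-")) ".t" else ".h"),
      paste0(seg_id(chr[length(chr)]),
             if (startsWith(chr[length(chr)], "-")) ".h" else ".t"))
  }))
  chrom_of <- stats::setNames(
    rep(seq_along(och), lengths(och)),
    seg_id(unlist(och, use.names = FALSE)))
  end_of <- function(s, side) {
    pos <- !startsWith(s, "-")
    id <- seg_id(s)
    if (side == "T") paste0(id, ifelse(pos, ".t", ".h"))
    else             paste0(id, ifelse(pos, ".h", ".t"))
  }
  kinds <- character(length(junctions))
  for (i in seq_along(junctions)) {
    p <- junction_sides(junctions[i])[[1]]
    eT <- end_of(p[1], "T"); eL <- end_of(p[2], "L")
    term <- c(eT %in% term_ends, eL %in% term_ends)
    if (all(term)) kinds[i] <- "EEJ"
    else if (any(term)) kinds[i] <- "NCF"   # chromosome end meets a break
    else kinds[i] <- "NCT"
  }
  # two NCF-flagged junctions flanking the same inserted chromosome are one
  # NCF event: collapse by the inserted chromosome id
  df <- data.frame(kind = kinds, junction = junctions,
                   stringsAsFactors = FALSE)
  if (any(df$kind == "NCF")) {
    ncf <- df$kind == "NCF"
    ins_chr <- vapply(which(ncf), function(i) {
      p <- junction_sides(df$junction[i])[[1]]
      eT <- end_of(p[1], "T"); eL <- end_of(p[2], "L")
      side <- if (eT %in% term_ends) p[1] else p[2]
      chrom_of[[seg_id(side)]]
    }, numeric(1))
    first <- !duplicated(ins_chr)
    keep <- rep(TRUE, nrow(df))
    keep[which(ncf)[!first]] <- FALSE
    df <- df[keep, , drop = FALSE]
  }
  # reciprocal pairs among NCT-flagged junctions: both junctions break the
  # same two outgroup chromosomes -> one RCT event
  nct <- which(df$kind == "NCT")
  if (length(nct) >= 2L) {
    pair_chroms <- vapply(nct, function(i) {
      p <- junction_sides(df$junction[i])[[1]]
      paste(sort(c(chrom_of[[seg_id(p[1])]], chrom_of[[seg_id(p[2])]])),
            collapse = "&")
    }, character(1))
    dup_keys <- unique(pair_chroms[duplicated(pair_chroms)])
    for (k in dup_keys) {
      idx <- nct[pair_chroms == k]
      df$kind[idx[1]] <- "RCT"
      df <- df[-idx[-1], , drop = FALSE]
      nct <- which(df$kind == "NCT")
      if (length(nct) < 2L) break
      pair_chroms <- vapply(nct, function(i) {
        p <- junction_sides(df$junction[i])[[1]]
        paste(sort(c(chrom_of[[seg_id(p[1])]], chrom_of[[seg_id(p[2])]])),
              collapse = "&")
      }, character(1))
    }
  }
  rownames(df) <- NULL
  df
}

#' Connection pattern of two adjacent ancestral regions in homologous copies
#'
#' For each homologous copy of an ancestral region pair (A, B), reports how B
#' lies relative to A: `"(A)-(B)"` (colinear on one chromosome),
#' `"(A)-(-B)"` (B inverted relative to A), or `"unlinked"` (A and B on
#' different chromosomes, e.g. separated by translocation).
#'
#' @param copies data.frame with one row per homologous copy and columns
#'   `copy` (label), `chrom_a`, `chrom_b` (harbouring chromosomes) and
#'   `orient_a`, `orient_b` (`"+"`/`"-"`, region orientation from synteny).
#' @return named character vector of connection patterns.
#' @export
connection_patterns <- function(copies) {
  need <- c("copy", "chrom_a", "chrom_b", "orient_a", "orient_b")
  if (!all(need %in% names(copies)))
    stop("`copies` needs columns: ", paste(need, collapse = ", "))
  cp <- ifelse(copies$chrom_a != copies$chrom_b, "unlinked",
               ifelse(copies$orient_a == copies$orient_b,
                      "(A)-(B)", "(A)-(-B)"))
  stats::setNames(cp, copies$copy)
}

#' Infer the two-step hexaploidy order from shared rearrangements
#'
#' A hexaploid's three subgenome copies of a region pair are compared with
#' the outgroup: copies whose connection pattern differs from the
#' outgroup-consistent state carry a derived rearrangement. When exactly two
#' copies share the derived state, those two subgenomes passed through the
#' first-step tetraploid together; the third joined by later hybridization.
#'
#' @param cps named character vector of connection patterns for the three
#'   ingroup copies; names are subgenome labels (e.g. LF/MF1/MF2).
#' @param outgroup_cp the outgroup's connection pattern.
#' @return list with `status` (`"ok"`, `"uninformative"`, or
#'   `"uninformative(outgroup)"`), `first_step` (two subgenome labels) and
#'   `second_step` (one label) when informative.
#' @export
two_step_inference <- function(cps, outgroup_cp) {
  if (length(cps) != 3L || is.null(names(cps)))
    stop("need exactly three named ingroup connection patterns")
  if (outgroup_cp == "unlinked")
    return(list(status = "uninformative(outgroup)",
                first_step = NULL, second_step = NULL))
  derived <- cps != outgroup_cp & cps != "unlinked"
  if (sum(derived) != 2L ||
      length(unique(cps[derived])) != 1L)
    return(list(status = "uninformative",
                first_step = NULL, second_step = NULL))
  list(status = "ok",
       first_step = sort(names(cps)[derived]),
       second_step = names(cps)[!derived])
}
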