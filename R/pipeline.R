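# End-to-end orchestration: load -> filter -> synteny -> Ks -> peaks /
# correction / dating -> event classification -> alignment table ->
# fractionation / P-index -> karyotype. Configured by a YAML file or an
# equivalent R list; each stage's output is written beneath the output
# directory with a manifest, and an unchanged config reuses cached stages.

#' Read a pipeline run configuration
#'
#' @param path YAML file. Recognised keys: `seed`, `reference`, `output`,
#'   `genomes` (list of `name`, `bed`/`gff`, `shared_hexaploidy`,
#'   `n_tetraploidies`, `divergence_event`), `hits`, `ks_table` (TSV with
#'   `gene_a`, `gene_b`, `ks`/`Ks`) or `cds` (FASTA paths), `params`
#'   (`max_gap`, `min_anchors`, `max_evalue`, `min_score`, `max_family`,
#'   `bandwidth`, `min_r2`, `window`, `ks_min`, `ks_max`, `pindex_threshold`),
#'   `peaks` (list of `event`, `mu`, `tol`), `paralog_event`, `calibration`
#'   (`event`, `time_mya`, `corrected_mu`), `karyotypes` (named file paths
#'   with an `outgroup` entry).
#' @return config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg$.base <- base
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$.base)) cfg$.base <- "."
  defaults <- list(max_gap = 50, min_anchors = 5, max_evalue = 1e-5,
                   min_score = 100, max_family = 50, bandwidth = 0.05,
                   min_r2 = 0.95, max_components = 3, window = 50,
                   ks_min = 0.05, ks_max = 1.8, pindex_threshold = 0.3)
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$reference)) stop("config error: no reference genome named")
  nms <- vapply(cfg$genomes, `[[`, character(1), "name")
  if (sum(nms == cfg$reference) != 1L)
    stop("config error: exactly one genome must be the reference")
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
    else file.path(cfg$.base, p)
  for (i in seq_along(cfg$genomes)) {
    cfg$genomes[[i]]$bed <- resolve(cfg$genomes[[i]]$bed)
    cfg$genomes[[i]]$gff <- resolve(cfg$genomes[[i]]$gff)
    f <- cfg$genomes[[i]]$bed %||% cfg$genomes[[i]]$gff
    if (is.null(f) || !file.exists(f))
      stop("config error: annotation file missing for genome ", nms[i])
  }
  cfg$hits <- resolve(cfg$hits)
  if (is.null(cfg$hits) || !file.exists(cfg$hits))
    stop("config error: hits file missing")
  cfg$ks_table <- resolve(cfg$ks_table)
  if (!is.null(cfg$cds)) cfg$cds <- vapply(cfg$cds, resolve, character(1))
  if (!is.null(cfg$karyotypes))
    cfg$karyotypes <- lapply(cfg$karyotypes, resolve)
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(...) message("[paleohexkit] ", ...)

#' Run the full pipeline
#'
#' Executes every stage the configuration enables and writes a report
#' bundle (TSV tables plus `report.json` and `manifest.json`) to the output
#' directory. A rerun with an identical configuration reuses the cached
#' stage results. Stages whose inputs are not configured (e.g. dating
#' without a calibration, karyotype without segment maps) are skipped with
#' a notice; a failing stage halts the pipeline naming the stage.
#'
#' @param config a `run_config` from [read_run_config()], or a path to one.
#' @return the report (list), invisibly the same as `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out_dir <- config$output %||% "paleohexkit_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  p <- config$params

  manifest_path <- file.path(out_dir, "manifest.json")
  cache_path <- file.path(out_dir, "cache.rds")
  cfg_fingerprint <- config[setdiff(names(config), ".base")]
  if (file.exists(manifest_path) && file.exists(cache_path)) {
    old <- tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
                    error = function(e) NULL)
    new_json <- jsonlite::toJSON(cfg_fingerprint, auto_unbox = TRUE,
                                 digits = NA, null = "null")
    if (!is.null(old) && identical(as.character(old$config_json),
                                   as.character(new_json))) {
      pipeline_log("configuration unchanged; reusing cached report")
      return(readRDS(cache_path))
    }
  }

  stage <- function(name, expr) {
    pipeline_log("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genomes <- stage("load", {
    gs <- list()
    for (g in config$genomes) {
      f <- g$bed %||% g$gff
      fmt <- if (!is.null(g$bed)) "bed" else "gff3"
      gs[[g$name]] <- load_gene_annotations(f, format = fmt,
                                            genome_name = g$name)
    }
    gs
  })
  ref <- config$reference
  gmeta <- do.call(rbind, lapply(config$genomes, function(g)
    data.frame(genome = g$name,
               shared_hexaploidy = isTRUE(g$shared_hexaploidy),
               n_tetraploidies = g$n_tetraploidies %||% 0L,
               divergence_event = g$divergence_event %||% NA_character_,
               stringsAsFactors = FALSE)))

  hits <- stage("hits", {
    h <- load_hits(config$hits)
    filter_hits(h, genomes, max_evalue = p$max_evalue,
                min_score = p$min_score, max_family = p$max_family)
  })

  blocks <- stage("synteny", {
    pair_hits <- function(ga, gb) {
      ids_a <- ga$genes$id; ids_b <- gb$genes$id
      keep <- (hits$query %in% ids_a & hits$subject %in% ids_b) |
        (hits$query %in% ids_b & hits$subject %in% ids_a)
      hits[keep, , drop = FALSE]
    }
    bl <- list()
    for (g in setdiff(names(genomes), ref))
      bl <- c(bl, chain_collinear_blocks(
        pair_hits(genomes[[ref]], genomes[[g]]),
        genomes[[ref]], genomes[[g]],
        max_gap = p$max_gap, min_anchors = p$min_anchors))
    bl <- c(bl, chain_collinear_blocks(
      pair_hits(genomes[[ref]], genomes[[ref]]),
      genomes[[ref]], genomes[[ref]],
      max_gap = p$max_gap, min_anchors = p$min_anchors))
    bl
  })
  write_blocks_tsv(blocks, file.path(out_dir, "blocks.tsv"))

  blocks <- stage("ks", {
    if (!is.null(config$ks_table)) {
      kt <- utils::read.delim(config$ks_table, stringsAsFactors = FALSE)
      names(kt)[names(kt) %in% c("ks", "Ks")] <- "Ks"
      lapply(blocks, annotate_block_ks, cds = kt)
    } else if (!is.null(config$cds)) {
      cds <- load_cds_fasta(config$cds)
      lapply(blocks, annotate_block_ks, cds = cds)
    } else {
      pipeline_log("no Ks source configured; Ks stage skipped")
      blocks
    }
  })

  peaks_report <- stage("peaks", {
    res <- list()
    for (g in setdiff(names(genomes), ref)) {
      ks <- unlist(lapply(blocks, function(b)
        if (b$genome_b == g && b$genome_a == ref) b$anchors$ks))
      ks <- ks[is.finite(ks) & ks >= p$ks_min]
      if (length(ks) >= 10)
        res[[paste0(ref, "-", g)]] <-
          fit_ks_peaks(ks, max_components = p$max_components,
                       min_r2 = p$min_r2, bandwidth = p$bandwidth,
                       source = paste0(ref, "-", g, " orthologs"))
    }
    ks_para <- unlist(lapply(blocks, function(b)
      if (b$genome_a == ref && b$genome_b == ref) b$anchors$ks))
    ks_para <- ks_para[is.finite(ks_para) & ks_para >= p$ks_min]
    if (length(ks_para) >= 10)
      res[[paste0(ref, "-", ref)]] <-
        fit_ks_peaks(ks_para, max_components = p$max_components,
                     min_r2 = p$min_r2, bandwidth = p$bandwidth,
                     source = paste0(ref, " paralogs"))
    res
  })

  correction <- stage("correction", {
    div_mu <- vapply(setdiff(names(genomes), ref), function(g) {
      m <- peaks_report[[paste0(ref, "-", g)]]
      if (is.null(m)) return(NA_real_)
      # divergence peak: the dominant component
      m$components$mu[which.max(m$components$weight)]
    }, numeric(1))
    div_mu <- div_mu[!is.na(div_mu)]
    if (length(div_mu) >= 1) first_round_correction(div_mu) else NULL
  })

  dates <- stage("dating", {
    if (is.null(config$calibration)) {
      pipeline_log("no calibration configured; dating skipped")
      NULL
    } else if (is.null(correction)) {
      pipeline_log("no divergence peaks; dating skipped")
      NULL
    } else {
      cal <- config$calibration
      lapply(stats::setNames(correction$corrected_mu, correction$lineage),
             date_event,
             calibration = list(time_mya = unlist(cal$time_mya),
                                corrected_mu = cal$corrected_mu))
    }
  })

  table_res <- NULL
  fractionation_res <- NULL
  if (!is.null(config$peaks)) {
    peak_df <- do.call(rbind, lapply(config$peaks, as.data.frame))
    blocks <- stage("classify", classify_blocks(blocks, peak_df))
    table_res <- stage("table", {
      aligned <- gmeta[gmeta$genome != ref, , drop = FALSE]
      layout <- plan_table_layout(ref, aligned)
      para_ev <- config$paralog_event %||% NA_character_
      ortho <- Filter(function(b) b$genome_b != ref &&
                        (is.na(gmeta$divergence_event[match(b$genome_b, gmeta$genome)]) ||
                           identical(b$event, gmeta$divergence_event[
                             match(b$genome_b, gmeta$genome)])), blocks)
      para <- Filter(function(b) b$genome_a == ref && b$genome_b == ref &&
                       (is.na(para_ev) || identical(b$event, para_ev)), blocks)
      fill_table(layout, genomes[[ref]], ortho, para)
    })
    write_alignment_tsv(table_res, file.path(out_dir, "alignment_table.tsv"))

    fractionation_res <- stage("fractionation", {
      res <- list()
      refchrom <- table_res$ref_chrom
      for (g in setdiff(names(genomes), ref)) {
        cols <- grep(sprintf("^%s_p1_s", g), names(table_res), value = TRUE)
        if (!length(cols)) next
        cells <- as.matrix(as.data.frame(table_res)[cols])
        prof <- retention_profile(cells, refchrom, window = p$window)
        runs <- unlist(lapply(cols, function(cl)
          loss_runs(table_res[[cl]], refchrom)))
        geo <- if (length(runs) >= 20) fit_geometric(runs) else NULL
        pin <- p_index(prof[cols], prof$chrom)
        labels <- NULL
        if (length(cols) == 3L) {
          ret <- data.frame(
            region = rep(paste0(prof$chrom, ":", prof$start_index), 3),
            copy = rep(cols, each = nrow(prof)),
            retained = c(as.matrix(prof[cols])),
            stringsAsFactors = FALSE)
          labels <- assign_subgenomes(ret)$regions
        }
        res[[g]] <- list(profile = prof, geometric = geo, p_index = pin,
                         inferred_nature = if (pin > p$pindex_threshold)
                           "allopolyploid" else "autopolyploid",
                         subgenome_labels = labels)
      }
      res
    })
  } else {
    pipeline_log("no event peaks configured; table/fractionation skipped")
  }

  karyo_res <- stage("karyotype", {
    if (is.null(config$karyotypes)) {
      pipeline_log("no karyotype maps configured; karyotype stage skipped")
      NULL
    } else {
      kf <- config$karyotypes
      outg <- read_karyotype(kf$outgroup, name = "outgroup")
      desc <- lapply(kf[setdiff(names(kf), "outgroup")], read_karyotype)
      rec <- reconstruct_ancestral_karyotype(desc, outg)
      list(ancestor_chromosomes = length(rec$karyotype$chromosomes),
           events = rec$events, karyotype = rec$karyotype)
    }
  })

  report <- list(
    genomes = names(genomes),
    n_filtered_hits = nrow(hits),
    n_blocks = length(blocks),
    peaks = lapply(peaks_report, function(m)
      list(components = m$components, r_squared = m$r_squared,
           source = m$source)),
    correction = correction,
    dates = dates,
    p_index = if (!is.null(fractionation_res))
      lapply(fractionation_res, `[[`, "p_index") else NULL,
    inferred_nature = if (!is.null(fractionation_res))
      lapply(fractionation_res, `[[`, "inferred_nature") else NULL,
    geometric_p = if (!is.null(fractionation_res))
      lapply(fractionation_res, function(x)
        if (!is.null(x$geometric)) x$geometric$p else NA) else NULL,
    table_columns = if (!is.null(table_res))
      attr(table_res, "layout") |> nrow() else NULL,
    karyotype = if (!is.null(karyo_res))
      list(ancestor_chromosomes = karyo_res$ancestor_chromosomes,
           events = karyo_res$events) else NULL,
    seed = config$seed)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 6, force = TRUE,
                       dataframe = "rows")
  jsonlite::write_json(
    list(config_json = as.character(jsonlite::toJSON(cfg_fingerprint,
                                                     auto_unbox = TRUE,
                                                     digits = NA,
                                                     null = "null")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         version = as.character(utils::packageVersion("paleohexkit"))),
    manifest_path, auto_unbox = TRUE)
  full <- list(report = report, blocks = blocks, table = table_res,
               fractionation = fractionation_res, peaks = peaks_report,
               karyotype = karyo_res)
  saveRDS(full, cache_path)
  full
}
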