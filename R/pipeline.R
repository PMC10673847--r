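#' Assign a method to an SN/PPV quadrant
#'
#' Quadrant I is high SN and high PPV (both strictly above 0.5), quadrant
#' II low SN / high PPV, quadrant IV high SN / low PPV, and quadrant III
#' low on both. Points on the 0.5 boundary count as low.
#'
#' @param sn,ppv Numeric vectors in `[0, 1]`; `NA` yields `NA`.
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"` (or `NA`).
#' @export
quadrant_assign <- function(sn, ppv) {
  out <- ifelse(sn > 0.5 & ppv > 0.5, "I",
         ifelse(sn <= 0.5 & ppv > 0.5, "II",
         ifelse(sn > 0.5 & ppv <= 0.5, "IV", "III")))
  out[is.na(sn) | is.na(ppv)] <- NA_character_
  out
}

#' Run configuration for a full two-wave evaluation
#'
#' @param trait Trait label used in report rows.
#' @param wave1,wave2 Variant-record data frames, or paths readable by
#'   [read_sumstats()] with `dialect`.
#' @param nominations List of [nomination_set()] objects (one per method).
#' @param locus_cfg A [locus_config()].
#' @param evaluation A [eval_config()].
#' @param dialect Column mapping used when `wave1`/`wave2` are paths.
#' @param gold_genes Optional gene-record data frame for gene-level methods.
#' @param build_ensemble Also build the ensemble membership matrix.
#' @param out_dir Optional directory for TSV outputs.
#' @return A named list.
#' @export
run_config <- function(trait = "trait", wave1, wave2,
                       nominations = list(),
                       locus_cfg = locus_config(),
                       evaluation = eval_config(),
                       dialect = sumstats_dialect(),
                       gold_genes = NULL,
                       build_ensemble = FALSE, out_dir = NULL) {
  list(trait = trait, wave1 = wave1, wave2 = wave2,
       nominations = nominations, locus_cfg = locus_cfg,
       evaluation = evaluation, dialect = dialect,
       gold_genes = gold_genes, build_ensemble = build_ensemble,
       out_dir = out_dir)
}

#' Run the full two-wave evaluation pipeline
#'
#' Stages: harmonize both waves (p-value truncation, positional
#' deduplication); define wave-1 and wave-2 significant loci; drop from the
#' wave-2 loci any locus overlapping a wave-1 locus by one or more bases
#' (the remaining wave-2 loci are the gold standard); for each nomination
#' set, strip nominations inside wave-1 loci, build merged loci, classify
#' at the configured overlap, and collect SN/PPV/F1; assemble the metrics
#' table with quadrant assignment, the scatter table (methods with at least
#' one nomination), and the ranking table (methods nominating nothing rank
#' `n_methods_total`); optionally the ensemble matrix.
#'
#' @param cfg A [run_config()].
#' @return List with `gwas1_loci`, `gwas2_loci`, `gold_loci`, `metrics`,
#'   `scatter`, `ranking`, `ensemble` (or `NULL`), and a `log` of counts.
#' @export
run_full_evaluation <- function(cfg) {
  load_wave <- function(w) {
    if (is.character(w)) w <- read_sumstats(w, cfg$dialect)
    dedupe_by_position(truncate_pvalues(w))
  }
  wave1 <- load_wave(cfg$wave1)
  wave2 <- load_wave(cfg$wave2)

  gwas1_loci <- define_loci(wave1, cfg$locus_cfg)
  gwas2_loci <- define_loci(wave2, cfg$locus_cfg)
  gold_loci <- exclude_overlapping(gwas2_loci, gwas1_loci, min_overlap = 1)
  log <- list(
    n_wave1 = nrow(wave1), n_wave2 = nrow(wave2),
    n_gwas1_loci = nrow(gwas1_loci), n_gwas2_loci = nrow(gwas2_loci),
    n_gold_excluded = attr(gold_loci, "n_removed"),
    n_gold = nrow(gold_loci)
  )

  eval_cfg <- cfg$evaluation
  per_method <- lapply(cfg$nominations, function(nom) {
    stopifnot(inherits(nom, "nomination_set"))
    if (nom$level == "variant") {
      pts <- exclude_points_in_loci(nom$items, gwas1_loci)
      nom_loci <- windows_from_points(pts, eval_cfg$flank)
      res <- classify_locus_level(nom_loci, gold_loci, eval_cfg)
      n_nom <- nrow(nom_loci)
      n_excluded <- attr(pts, "n_removed")
    } else if (nom$level == "gene") {
      if (is.null(cfg$gold_genes)) {
        stop("gene-level method '", nom$method,
             "' requires gold_genes in the run config", call. = FALSE)
      }
      items <- nom$items
      if (all(c("chrom", "start", "end") %in% names(items))) {
        keep <- exclude_genes_near_loci(items, gwas1_loci, eval_cfg$flank)
      } else {
        key_col <- if (!is.null(items$gene_id) &&
                         !all(is.na(items$gene_id))) "gene_id" else "symbol"
        idx <- match(items[[key_col]], cfg$gold_genes[[key_col]])
        coords <- cfg$gold_genes[idx, , drop = FALSE]
        near_ok <- exclude_genes_near_loci(coords[!is.na(idx), , drop = FALSE],
                                           gwas1_loci, eval_cfg$flank)
        keep_keys <- near_ok[[key_col]]
        keep <- items[is.na(idx) | items[[key_col]] %in% keep_keys, ,
                      drop = FALSE]
        attr(keep, "n_removed") <- nrow(items) - nrow(keep)
      }
      filtered <- nomination_set(nom$method, "gene", keep)
      res <- classify_gene_level(filtered, cfg$gold_genes, eval_cfg,
                                 gold_loci = if (eval_cfg$gene_locus_mode !=
                                                   "id_match") gold_loci)
      n_nom <- nrow(keep)
      n_excluded <- attr(keep, "n_removed")
    } else { # locus level
      nom_loci <- exclude_overlapping(merge_loci(nom$items), gwas1_loci,
                                      min_overlap = 1)
      res <- classify_locus_level(nom_loci, gold_loci, eval_cfg)
      n_nom <- nrow(nom_loci)
      n_excluded <- attr(nom_loci, "n_removed")
    }
    list(method = nom$method, level = nom$level, result = res,
         n_nominated = n_nom, n_excluded = n_excluded)
  })

  metrics <- do.call(rbind, lapply(per_method, function(pm) {
    r <- pm$result
    data.frame(
      trait = cfg$trait, method = pm$method, level = pm$level,
      n_nominated = pm$n_nominated, n_excluded_gwas1 = pm$n_excluded,
      tp = r$tp_nominated, fp = r$fp, gold_covered = r$gold_covered,
      fn = r$fn, sn = r$sn, ppv = r$ppv, f1 = r$f1,
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(metrics)) {
    metrics$quadrant <- quadrant_assign(metrics$sn, metrics$ppv)
    scatter <- metrics[metrics$n_nominated > 0, , drop = FALSE]
    ppv_vec <- stats::setNames(
      ifelse(metrics$n_nominated > 0, metrics$ppv, NA_real_),
      metrics$method
    )
    ranking <- data.frame(
      method = metrics$method, best_ppv = as.numeric(ppv_vec),
      rank = as.integer(rank_methods(ppv_vec, eval_cfg$n_methods_total)),
      stringsAsFactors = FALSE
    )
    ranking <- ranking[order(ranking$rank, ranking$method), , drop = FALSE]
    rownames(ranking) <- NULL
  } else {
    metrics <- data.frame()
    scatter <- data.frame()
    ranking <- data.frame()
  }

  ensemble <- NULL
  if (isTRUE(cfg$build_ensemble) && length(per_method) > 0L) {
    by_method <- lapply(per_method, function(pm) {
      if (pm$level == "variant") {
        pts <- exclude_points_in_loci(
          cfg$nominations[[which(vapply(cfg$nominations, `[[`, "",
                                        "method") == pm$method)]]$items,
          gwas1_loci)
        windows_from_points(pts, eval_cfg$flank)
      } else {
        .empty_loci()
      }
    })
    names(by_method) <- vapply(per_method, `[[`, "", "method")
    ensemble <- flag_gold(
      build_ensemble_matrix(by_method, eval_cfg$min_overlap_locus),
      gold_loci, eval_cfg$min_overlap_locus
    )
  }

  out <- list(gwas1_loci = gwas1_loci, gwas2_loci = gwas2_loci,
              gold_loci = gold_loci, metrics = metrics, scatter = scatter,
              ranking = ranking, ensemble = ensemble, log = log)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_loci(gwas1_loci, file.path(cfg$out_dir, "gwas1_loci.tsv"))
    write_loci(gold_loci, file.path(cfg$out_dir, "gold_loci.tsv"))
    data.table::fwrite(metrics, file.path(cfg$out_dir, "metrics.tsv"),
                       sep = "\t")
    data.table::fwrite(ranking, file.path(cfg$out_dir, "ranking.tsv"),
                       sep = "\t")
  }
  out
}

#' Published multi-method benchmark ranking table
#'
#' Loads the shipped table of best PPV per method and trait from a
#' published 18-method, five-trait benchmark of locus-nomination methods
#' (traits: bipolar disorder, major depressive disorder, schizophrenia,
#' mean platelet volume, white blood cell count), together with the ranks
#' and median ranks printed alongside. Used to validate the ranking
#' arithmetic.
#'
#' @return List with `ppv` (18 x 5 matrix, `NA` = no nominations),
#'   `rank` (18 x 5 integer matrix of printed ranks), and `median_rank`
#'   (named vector of printed medians).
#' @export
published_method_ranking <- function() {
  path <- system.file("extdata", "method_ranking_published.tsv",
                      package = "locuswave", mustWork = TRUE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = "NA")
  traits <- c("BPD", "MDD", "SCZ", "MPV", "WBC")
  ppv <- as.matrix(dt[, paste0(tolower(traits), "_ppv")])
  rank <- as.matrix(dt[, paste0(tolower(traits), "_rank")])
  dimnames(ppv) <- dimnames(rank) <- list(dt$method, traits)
  list(ppv = ppv, rank = rank,
       median_rank = stats::setNames(dt$median_rank, dt$method))
}
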