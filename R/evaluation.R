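#' Evaluation configuration
#'
#' @param flank Window half-width used to turn points/midpoints into loci
#'   (default 500000 bases).
#' @param min_overlap_locus Minimum base overlap for a locus-to-locus true
#'   positive (default 250000; sensitivity grid 1 / 250 kb / 500 kb / 750 kb).
#' @param min_overlap_gene_boundaries Minimum overlap when gene loci are the
#'   annotated boundaries rather than midpoint windows (default 2500).
#' @param gene_locus_mode How gene-level nominations are compared:
#'   `"id_match"` (set operations on gene keys), `"boundaries"`, or
#'   `"midpoint_flank"` (both delegate to the locus-level comparison).
#' @param id_mode Gene key used in `id_match` mode: `"ensembl"` or
#'   `"symbol"`.
#' @param alpha Family-wise error level for the gold-side gene Bonferroni
#'   correction (default 0.05).
#' @param n_methods_total Number of competing methods, used as the rank
#'   assigned to methods that nominated nothing (default 18).
#' @return A named list.
#' @export
eval_config <- function(flank = 500000, min_overlap_locus = 250000,
                        min_overlap_gene_boundaries = 2500,
                        gene_locus_mode = c("id_match", "boundaries",
                                            "midpoint_flank"),
                        id_mode = c("ensembl", "symbol"),
                        alpha = 0.05, n_methods_total = 18) {
  stopifnot(min_overlap_locus >= 1, min_overlap_gene_boundaries >= 1)
  list(flank = flank, min_overlap_locus = min_overlap_locus,
       min_overlap_gene_boundaries = min_overlap_gene_boundaries,
       gene_locus_mode = match.arg(gene_locus_mode),
       id_mode = match.arg(id_mode), alpha = alpha,
       n_methods_total = n_methods_total)
}

#' Internal: assemble a classification result object.
#' SN is computed from the gold side (covered gold items over all gold
#' items) and PPV from the nominated side (confirmed nominations over all
#' nominations); the two numerators can differ when one nominated locus
#' covers several gold loci.
#' @noRd
.classification_result <- function(level, tp_nominated, fp, gold_covered,
                                   fn, items = list()) {
  sn <- if (gold_covered + fn > 0) gold_covered / (gold_covered + fn) else NA_real_
  ppv <- if (tp_nominated + fp > 0) tp_nominated / (tp_nominated + fp) else NA_real_
  structure(list(
    level = level, tp_nominated = tp_nominated, fp = fp,
    gold_covered = gold_covered, fn = fn,
    sn = sn, ppv = ppv, f1 = compute_f1(sn, ppv), items = items
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> level:", x$level, "\n",
      " TP(nominated):", x$tp_nominated, " FP:", x$fp,
      " gold covered:", x$gold_covered, " FN:", x$fn, "\n",
      sprintf("  SN: %s  PPV: %s  F1: %s\n",
              format(x$sn, digits = 4), format(x$ppv, digits = 4),
              format(x$f1, digits = 4)))
  invisible(x)
}

#' F1 score: harmonic mean of sensitivity and positive predictive value
#'
#' @param sn,ppv Proportions in `[0, 1]`; `NA` propagates.
#' @return `0` when `sn + ppv == 0`, otherwise `2 * sn * ppv / (sn + ppv)`.
#' @export
compute_f1 <- function(sn, ppv) {
  if (is.na(sn) || is.na(ppv)) return(NA_real_)
  stopifnot(sn >= 0, sn <= 1, ppv >= 0, ppv <= 1)
  if (sn + ppv == 0) return(0)
  2 * sn * ppv / (sn + ppv)
}

#' Classify variant-level nominations against gold significant variants
#'
#' A true positive is an exact (chrom, pos) match between a nominated
#' variant and a gold-standard genome-wide significant variant. Both inputs
#' are expected to be pre-filtered against earlier-wave significant regions
#' (see [exclude_points_in_loci()] and [exclude_overlapping()]).
#'
#' @param nominated A [nomination_set()] at variant level.
#' @param gold_sig Variant-record data frame of gold significant variants.
#' @return A classification result.
#' @export
classify_variant_level <- function(nominated, gold_sig) {
  if (!inherits(nominated, "nomination_set") || nominated$level != "variant") {
    stop("a variant-level nomination_set is required", call. = FALSE)
  }
  nom_key <- unique(paste(nominated$items$chrom, nominated$items$pos, sep = ":"))
  gold_key <- unique(paste(gold_sig$chrom, gold_sig$pos, sep = ":"))
  tp_keys <- intersect(nom_key, gold_key)
  fp_keys <- setdiff(nom_key, gold_key)
  fn_keys <- setdiff(gold_key, nom_key)
  .classification_result(
    "variant",
    tp_nominated = length(tp_keys), fp = length(fp_keys),
    gold_covered = length(tp_keys), fn = length(fn_keys),
    items = list(tp = tp_keys, fp = fp_keys, fn = fn_keys)
  )
}

#' Classify nominated loci against gold-standard loci
#'
#' A nominated locus is a true positive when it overlaps at least one gold
#' locus by `min_overlap` bases or more, and a false positive otherwise. A
#' gold locus is covered when at least one nominated locus overlaps it by
#' `min_overlap` or more, and a false negative otherwise. PPV is the
#' proportion of nominated loci confirmed; SN is the proportion of gold loci
#' covered. Both lists are expected post-exclusion and internally merged.
#'
#' @param nominated_loci,gold_loci Locus data frames.
#' @param cfg An [eval_config()]; `cfg$min_overlap_locus` sets the overlap
#'   requirement.
#' @return A classification result.
#' @export
classify_locus_level <- function(nominated_loci, gold_loci,
                                 cfg = eval_config()) {
  min_overlap <- cfg$min_overlap_locus
  nom_hit <- .max_overlap(nominated_loci, gold_loci) >= min_overlap
  gold_hit <- .max_overlap(gold_loci, nominated_loci) >= min_overlap
  .classification_result(
    "locus",
    tp_nominated = sum(nom_hit), fp = sum(!nom_hit),
    gold_covered = sum(gold_hit), fn = sum(!gold_hit),
    items = list(
      tp = nominated_loci[nom_hit, , drop = FALSE],
      fp = nominated_loci[!nom_hit, , drop = FALSE],
      fn = gold_loci[!gold_hit, , drop = FALSE]
    )
  )
}

#' Bonferroni-significant gold gene set
#'
#' The gold standard at gene level: genes with a valid p-value below
#' `alpha / n_valid`, where `n_valid` counts genes with a valid p-value.
#'
#' @param gold_genes Gene-record data frame.
#' @param alpha Family-wise error level (default 0.05).
#' @return The significant subset of `gold_genes`.
#' @export
gold_significant_genes <- function(gold_genes, alpha = 0.05) {
  bf <- bonferroni_significant(gold_genes$pvalue, alpha)
  out <- gold_genes[!is.na(bf$mask) & bf$mask, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- bf$threshold
  out
}

#' Exclude genes whose midpoint lies near earlier-wave loci
#'
#' Removes genes whose midpoint falls within `flank` bases of any locus in
#' `loci` (the rule used to stop gene-level methods re-discovering
#' earlier-wave hits).
#'
#' @param genes Gene-record data frame.
#' @param loci Locus data frame (earlier-wave significant loci).
#' @param flank Distance in bases (default 500000).
#' @return Retained genes, with attribute `n_removed`.
#' @export
exclude_genes_near_loci <- function(genes, loci, flank = 500000) {
  if (nrow(genes) == 0L || nrow(loci) == 0L) {
    attr(genes, "n_removed") <- 0L
    return(genes)
  }
  mid <- if ("midpoint" %in% names(genes)) genes$midpoint else gene_midpoint(genes)
  near <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(loci))) {
    near <- near | (genes$chrom == loci$chrom[i] &
                      mid >= loci$start[i] - flank &
                      mid <= loci$end[i] + flank)
  }
  out <- genes[!near, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(near)
  out
}

#' Classify gene-level nominations against a gold gene table
#'
#' In `id_match` mode the comparison is set arithmetic on gene keys
#' (Ensembl-style ids or symbols, per `cfg$id_mode`) between the nominated
#' genes and the Bonferroni-significant gold genes
#' (see [gold_significant_genes()]). In `boundaries` and `midpoint_flank`
#' modes, nominated genes are resolved to coordinates (from their own
#' columns when present, otherwise by key lookup in `gold_genes`), converted
#' to loci via [gene_to_locus()], merged, and compared with
#' [classify_locus_level()] at the mode's overlap requirement (2500 bases
#' for `boundaries`, `cfg$min_overlap_locus` for `midpoint_flank`). The gold
#' side of a locus-mode comparison is `gold_loci` when supplied (e.g., the
#' later wave's variant-based loci); otherwise it is built from the
#' significant gold genes with the same mode.
#'
#' Nominations are expected pre-filtered with [exclude_genes_near_loci()].
#'
#' @param nominated A [nomination_set()] at gene level.
#' @param gold_genes Gene-record data frame with p-values.
#' @param cfg An [eval_config()].
#' @param gold_loci Optional locus data frame used as the gold side in
#'   locus modes.
#' @return A classification result.
#' @export
classify_gene_level <- function(nominated, gold_genes, cfg = eval_config(),
                                gold_loci = NULL) {
  if (!inherits(nominated, "nomination_set") || nominated$level != "gene") {
    stop("a gene-level nomination_set is required", call. = FALSE)
  }
  gold_sig <- gold_significant_genes(gold_genes, cfg$alpha)
  mode <- cfg$gene_locus_mode
  items <- nominated$items

  if (mode == "id_match") {
    key_col <- if (cfg$id_mode == "ensembl") "gene_id" else "symbol"
    nom_keys <- items[[key_col]]
    if (is.null(nom_keys) || all(is.na(nom_keys))) {
      stop("id_mode = '", cfg$id_mode, "' but nominations carry no '",
           key_col, "' values; use id_mode = '",
           if (cfg$id_mode == "ensembl") "symbol" else "ensembl",
           "' instead", call. = FALSE)
    }
    nom_keys <- unique(nom_keys[!is.na(nom_keys)])
    gold_keys <- unique(gold_sig[[key_col]])
    gold_keys <- gold_keys[!is.na(gold_keys)]
    tp <- intersect(nom_keys, gold_keys)
    fp <- setdiff(nom_keys, gold_keys)
    fn <- setdiff(gold_keys, nom_keys)
    return(.classification_result(
      "gene", tp_nominated = length(tp), fp = length(fp),
      gold_covered = length(tp), fn = length(fn),
      items = list(tp = tp, fp = fp, fn = fn)
    ))
  }

  # locus modes: resolve nominated genes to coordinates
  have_coords <- all(c("chrom", "start", "end") %in% names(items)) &&
    !anyNA(items$start)
  if (!have_coords) {
    key_col <- if (!is.null(items$gene_id) && !all(is.na(items$gene_id)))
      "gene_id" else "symbol"
    idx <- match(items[[key_col]], gold_genes[[key_col]])
    unresolved <- is.na(idx)
    if (any(unresolved)) {
      message(sum(unresolved), " nominated gene(s) without coordinates dropped")
    }
    items <- gold_genes[idx[!unresolved], , drop = FALSE]
  }
  min_overlap <- if (mode == "boundaries") cfg$min_overlap_gene_boundaries
    else cfg$min_overlap_locus
  nom_loci <- merge_loci(gene_to_locus(items, mode, cfg$flank))
  if (is.null(gold_loci)) {
    gold_loci <- merge_loci(gene_to_locus(gold_sig, mode, cfg$flank))
  }
  cfg2 <- cfg
  cfg2$min_overlap_locus <- min_overlap
  res <- classify_locus_level(nom_loci, gold_loci, cfg2)
  res$level <- "gene"
  res
}

#' Rank methods by best PPV with competition (Olympic) ranking
#'
#' A method's rank is the number of methods in the same column whose PPV is
#' greater than or equal to its own, so tied methods all receive the lowest
#' (worst) rank of the tied block. Methods with no nominations (missing
#' PPV) rank below methods with a PPV of zero and receive rank `n_total`.
#'
#' @param best_ppv Named numeric vector: one best PPV per method, `NA` for
#'   methods that nominated nothing.
#' @param n_total Total number of competing methods (default 18).
#' @return Named integer vector of ranks.
#' @export
rank_methods <- function(best_ppv, n_total = 18) {
  if (is.null(names(best_ppv)) || anyDuplicated(names(best_ppv))) {
    stop("best_ppv must be uniquely named by method", call. = FALSE)
  }
  valid <- best_ppv[!is.na(best_ppv)]
  ranks <- vapply(best_ppv, function(p) {
    if (is.na(p)) n_total else sum(valid >= p)
  }, numeric(1))
  stats::setNames(as.integer(ranks), names(best_ppv))
}

#' Median rank across traits
#'
#' The middle order statistic for an odd number of traits; for an even
#' number, the lower of the two middle order statistics (kept integral).
#'
#' @param ranks Integer ranks, one per trait, with missing-PPV methods
#'   already mapped to the worst rank.
#' @return A single numeric rank; `NA` for empty input.
#' @export
median_rank <- function(ranks) {
  ranks <- ranks[!is.na(ranks)]
  if (length(ranks) == 0L) return(NA_real_)
  s <- sort(ranks)
  s[ceiling(length(s) / 2)]
}

#' Sensitivity sweep over the minimum-overlap requirement
#'
#' Re-runs the locus-level classification at each overlap requirement
#' (default 1 base, 250 kb, 500 kb, 750 kb). True-positive counts are
#' monotone non-increasing in the requirement.
#'
#' @param nominated_loci,gold_loci Locus data frames.
#' @param overlaps Positive overlap requirements in bases.
#' @param cfg An [eval_config()] supplying the remaining parameters.
#' @return Data frame with one row per overlap value: `min_overlap`, `tp`,
#'   `fp`, `gold_covered`, `fn`, `sn`, `ppv`, `f1`.
#' @export
overlap_sensitivity_sweep <- function(nominated_loci, gold_loci,
                                      overlaps = c(1, 250000, 500000, 750000),
                                      cfg = eval_config()) {
  if (any(overlaps <= 0)) {
    stop("overlap requirements must be positive", call. = FALSE)
  }
  rows <- lapply(overlaps, function(ov) {
    cfg$min_overlap_locus <- ov
    r <- classify_locus_level(nominated_loci, gold_loci, cfg)
    data.frame(min_overlap = ov, tp = r$tp_nominated, fp = r$fp,
               gold_covered = r$gold_covered, fn = r$fn,
               sn = r$sn, ppv = r$ppv, f1 = r$f1)
  })
  do.call(rbind, rows)
}
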