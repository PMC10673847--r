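#' Locus-definition configuration
#'
#' Parameters of the stepwise locus definition: the genome-wide significance
#' threshold, the flank size of the window placed around each lead variant,
#' and the fixed extended-HLA/MHC interval that is always collapsed into a
#' single locus because of its extreme linkage disequilibrium.
#'
#' @param sig_threshold P-value cutoff for genome-wide significance
#'   (default `5e-8`).
#' @param flank Bases added on each side of a lead variant
#'   (default `500000`).
#' @param hla_chrom,hla_start,hla_end The extended HLA region
#'   (default chr6:25,000,000-35,000,000).
#' @return A named list.
#' @export
locus_config <- function(sig_threshold = 5e-8, flank = 500000,
                         hla_chrom = "6", hla_start = 25000000,
                         hla_end = 35000000) {
  stopifnot(sig_threshold > 0, sig_threshold < 1, flank > 0,
            hla_start < hla_end)
  list(sig_threshold = sig_threshold, flank = flank, hla_chrom = hla_chrom,
       hla_start = hla_start, hla_end = hla_end)
}

#' Internal: merge overlapping intervals (>= 1 base, closed arithmetic)
#' and recompute lead/member fields from a significant-variant table.
#' `sig` may be NULL when no member bookkeeping is wanted.
#' @noRd
.merge_intervals <- function(iv, sig = NULL) {
  if (nrow(iv) == 0L) return(.empty_loci())
  out <- do.call(rbind, lapply(split(iv, iv$chrom), function(chr_iv) {
    chr_iv <- chr_iv[order(chr_iv$start, chr_iv$end), , drop = FALSE]
    merged <- chr_iv[1, c("chrom", "start", "end"), drop = FALSE]
    for (i in seq_len(nrow(chr_iv))[-1]) {
      last <- nrow(merged)
      if (chr_iv$start[i] <= merged$end[last]) { # closed intervals: touch = overlap
        merged$end[last] <- max(merged$end[last], chr_iv$end[i])
      } else {
        merged <- rbind(merged, chr_iv[i, c("chrom", "start", "end")])
      }
    }
    merged
  }))
  rownames(out) <- NULL
  out <- out[order(.chrom_key(out$chrom), out$start), , drop = FALSE]
  .annotate_loci(out, sig)
}

#' Internal: fill lead/member columns of a merged interval set from the
#' significant variants (or point table with optional pvalue) they contain.
#' @noRd
.annotate_loci <- function(iv, sig = NULL) {
  n <- nrow(iv)
  iv$lead_pos <- rep(NA_real_, n)
  iv$lead_p <- rep(NA_real_, n)
  iv$n_members <- rep(0L, n)
  iv$is_hla <- rep(FALSE, n)
  members <- vector("list", n)
  if (!is.null(sig) && nrow(sig) > 0L) {
    has_p <- "pvalue" %in% names(sig) && any(!is.na(sig$pvalue))
    for (i in seq_len(n)) {
      inside <- sig$chrom == iv$chrom[i] &
        sig$pos >= iv$start[i] & sig$pos <= iv$end[i]
      m <- sig[inside, , drop = FALSE]
      members[[i]] <- m$pos
      iv$n_members[i] <- nrow(m)
      if (nrow(m) > 0L && has_p) {
        ord <- order(m$pvalue, .chrom_key(m$chrom), m$pos)
        iv$lead_pos[i] <- m$pos[ord[1]]
        iv$lead_p[i] <- m$pvalue[ord[1]]
      } else if (nrow(m) > 0L) {
        iv$lead_pos[i] <- m$pos[1]
      }
    }
  }
  iv$members <- members
  rownames(iv) <- NULL
  iv
}

#' Define significant loci from summary statistics by stepwise windowing
#'
#' The algorithm the whole framework rests on:
#' 1. take all variants with `p < sig_threshold`;
#' 2. repeatedly pick the remaining variant with the smallest p-value
#'    (ties broken by chromosome then position), place a closed interval
#'    `[pos - flank, pos + flank]` around it, and remove every significant
#'    variant on that chromosome inside the interval;
#' 3. merge emitted intervals that overlap by at least one base on the same
#'    chromosome;
#' 4. replace every chromosome-6 locus overlapping the extended HLA region
#'    with its union with that fixed interval, then merge all such loci into
#'    a single locus flagged `is_hla`.
#'
#' Every significant variant ends up in exactly one returned locus, and the
#' returned loci are pairwise non-overlapping within a chromosome.
#'
#' @param records Variant-record data frame, deduplicated by position.
#' @param cfg A [locus_config()].
#' @return Locus data frame with columns `chrom`, `start`, `end`,
#'   `lead_pos`, `lead_p`, `n_members`, `is_hla`, and list-column `members`
#'   (positions of member significant variants).
#' @export
define_loci <- function(records, cfg = locus_config()) {
  sig <- records[!is.na(records$pvalue) &
                   records$pvalue < cfg$sig_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) return(.annotate_loci(.empty_loci(), NULL))
  sig <- .order_by_position(sig)

  remaining <- sig
  iv <- list()
  while (nrow(remaining) > 0L) {
    ord <- order(remaining$pvalue, .chrom_key(remaining$chrom), remaining$pos)
    lead <- remaining[ord[1], ]
    iv[[length(iv) + 1L]] <- data.frame(
      chrom = lead$chrom, start = lead$pos - cfg$flank,
      end = lead$pos + cfg$flank, stringsAsFactors = FALSE
    )
    covered <- remaining$chrom == lead$chrom &
      remaining$pos >= lead$pos - cfg$flank &
      remaining$pos <= lead$pos + cfg$flank
    remaining <- remaining[!covered, , drop = FALSE]
  }
  loci <- .merge_intervals(do.call(rbind, iv), sig)

  # extended-HLA collapsing: union-then-merge, so a locus reaching past the
  # fixed bounds keeps its extension
  hla_hit <- loci$chrom == cfg$hla_chrom &
    loci$start <= cfg$hla_end & loci$end >= cfg$hla_start
  if (any(hla_hit)) {
    hla <- data.frame(
      chrom = cfg$hla_chrom,
      start = min(cfg$hla_start, loci$start[hla_hit]),
      end = max(cfg$hla_end, loci$end[hla_hit]),
      stringsAsFactors = FALSE
    )
    loci <- rbind(loci[!hla_hit, c("chrom", "start", "end")],
                  hla[, c("chrom", "start", "end")])
    loci <- .merge_intervals(loci, sig)
    loci$is_hla <- loci$chrom == cfg$hla_chrom &
      loci$start <= cfg$hla_end & loci$end >= cfg$hla_start
  }
  loci
}

#' Build merged loci from point nominations
#'
#' Places a closed `[pos - flank, pos + flank]` window around each point and
#' collapses windows that overlap by any amount on the same chromosome into a
#' single locus. When the points carry a `pvalue` column, the lead fields of
#' each merged locus come from its smallest-p point.
#'
#' @param points Data frame with `chrom`, `pos`, optional `pvalue`.
#' @param flank Window half-width in bases (default 500000).
#' @return Locus data frame (see [define_loci()]).
#' @export
windows_from_points <- function(points, flank = 500000) {
  if (nrow(points) == 0L) return(.annotate_loci(.empty_loci(), NULL))
  iv <- data.frame(chrom = points$chrom, start = points$pos - flank,
                   end = points$pos + flank, stringsAsFactors = FALSE)
  .merge_intervals(iv, points)
}

#' Overlap length between two loci in bases (closed-interval arithmetic)
#'
#' Returns 0 for different chromosomes or disjoint intervals, otherwise
#' `min(end_a, end_b) - max(start_a, start_b) + 1`.
#'
#' @param a,b Single-row locus data frames (or lists with `chrom`, `start`,
#'   `end`).
#' @return Integer-valued overlap in bases.
#' @export
overlap_length <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0)
  max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]) + 1)
}

#' Internal: for each row of `a`, the maximum base overlap against any row
#' of `b` (same-chromosome, closed intervals). Vectorized via IRanges.
#' @noRd
.max_overlap <- function(a, b) {
  if (nrow(a) == 0L) return(numeric(0))
  if (nrow(b) == 0L) return(rep(0, nrow(a)))
  lv <- unique(c(a$chrom, b$chrom))
  gra <- GenomicRanges::GRanges(
    factor(a$chrom, levels = lv),
    IRanges::IRanges(start = a$start, end = a$end)
  )
  grb <- GenomicRanges::GRanges(
    factor(b$chrom, levels = lv),
    IRanges::IRanges(start = b$start, end = b$end)
  )
  hits <- GenomicRanges::findOverlaps(gra, grb)
  out <- rep(0, nrow(a))
  if (length(hits) > 0L) {
    qa <- S4Vectors::queryHits(hits)
    sb <- S4Vectors::subjectHits(hits)
    w <- pmin(a$end[qa], b$end[sb]) - pmax(a$start[qa], b$start[sb]) + 1
    agg <- tapply(w, qa, max)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Remove target loci that overlap an exclusion set
#'
#' Drops every target locus whose overlap with any exclusion locus is at
#' least `min_overlap` bases. With the default `min_overlap = 1`, any degree
#' of overlap removes the locus -- the rule used to strip earlier-wave hits
#' from a gold standard.
#'
#' @param target,exclusion Locus data frames.
#' @param min_overlap Minimum base overlap that triggers removal.
#' @return Retained target loci, with attribute `n_removed`.
#' @export
exclude_overlapping <- function(target, exclusion, min_overlap = 1) {
  stopifnot(min_overlap >= 1)
  if (nrow(target) == 0L || nrow(exclusion) == 0L) {
    attr(target, "n_removed") <- 0L
    return(target)
  }
  drop <- .max_overlap(target, exclusion) >= min_overlap
  out <- target[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Remove points lying inside any locus interval
#'
#' Used to strip nominated variants that fall within the boundaries of
#' earlier-wave significant loci (the loci already embody the +/-flank
#' windows, so a plain containment test suffices).
#'
#' @param points Data frame with `chrom`, `pos`.
#' @param loci Locus data frame.
#' @return Retained points, with attribute `n_removed`.
#' @export
exclude_points_in_loci <- function(points, loci) {
  if (nrow(points) == 0L || nrow(loci) == 0L) {
    attr(points, "n_removed") <- 0L
    return(points)
  }
  inside <- rep(FALSE, nrow(points))
  for (i in seq_len(nrow(loci))) {
    inside <- inside | (points$chrom == loci$chrom[i] &
                          points$pos >= loci$start[i] &
                          points$pos <= loci$end[i])
  }
  out <- points[!inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(inside)
  out
}

#' Turn gene records into loci
#'
#' `boundaries` mode uses the annotated gene interval as the locus;
#' `midpoint_flank` mode places `[midpoint - flank, midpoint + flank]`
#' around the gene midpoint. No clipping is applied at chromosome ends, so
#' starts may fall below 1.
#'
#' @param genes Gene-record data frame.
#' @param mode `"boundaries"` or `"midpoint_flank"`.
#' @param flank Half-width for midpoint mode (default 500000).
#' @return Locus data frame (one row per gene, not merged).
#' @export
gene_to_locus <- function(genes, mode = c("boundaries", "midpoint_flank"),
                          flank = 500000) {
  mode <- match.arg(mode)
  if (nrow(genes) == 0L) return(.annotate_loci(.empty_loci(), NULL))
  mid <- if ("midpoint" %in% names(genes)) genes$midpoint else gene_midpoint(genes)
  iv <- if (mode == "boundaries") {
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = genes$chrom, start = mid - flank, end = mid + flank,
               stringsAsFactors = FALSE)
  }
  out <- .annotate_loci(iv, NULL)
  out$gene_id <- genes$gene_id
  out
}

#' Merge overlapping loci in a list into single loci
#'
#' Collapses loci that overlap by at least one base on the same chromosome
#' (used, e.g., to merge overlapping gene windows before a locus-to-locus
#' comparison, avoiding double counting).
#'
#' @param loci Locus data frame.
#' @return Merged locus data frame.
#' @export
merge_loci <- function(loci) {
  if (nrow(loci) == 0L) return(.annotate_loci(.empty_loci(), NULL))
  .merge_intervals(loci[, c("chrom", "start", "end")], NULL)
}
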