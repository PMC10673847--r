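#' Nominate variants in the suggestive p-value band
#'
#' Selects variants with `lower <= p < upper` (defaults: the band between
#' genome-wide significance, 5e-8, and the conventional suggestive cutoff,
#' 1e-5). Genome-wide significant variants are deliberately not included:
#' the suggestive set and the significant set partition `{p < upper}`.
#'
#' @param records Variant-record data frame with truncated p-values.
#' @param lower,upper Band bounds (inclusive lower, exclusive upper).
#' @return A [nomination_set()] at variant level, method `"suggestive"`.
#' @export
nominate_suggestive <- function(records, lower = 5e-8, upper = 1e-5) {
  keep <- !is.na(records$pvalue) &
    records$pvalue >= lower & records$pvalue < upper
  nomination_set("suggestive", "variant",
                 records[keep, , drop = FALSE])
}

#' Annotation-category significance thresholds
#'
#' The four variant-impact categories and their family-wise-error-weighted
#' p-value thresholds: loss-of-function `5.5e-7`, moderate impact `1.1e-7`,
#' low impact `1.0e-8`, and other `1.7e-9`.
#'
#' @return Named numeric vector of thresholds.
#' @export
sveinbjornsson_thresholds <- function() {
  c(loss_of_function = 5.5e-7, moderate = 1.1e-7,
    low = 1.0e-8, other = 1.7e-9)
}

#' Nominate variants by annotation-category thresholds
#'
#' Each variant is assigned one of four impact categories from the
#' annotation table (matched on chrom + pos; unannotated variants default to
#' the catch-all `"other"` category, which carries the most stringent
#' threshold) and is nominated when its p-value falls below that category's
#' threshold; see [sveinbjornsson_thresholds()].
#'
#' @param records Variant-record data frame.
#' @param annotations Data frame with `chrom`, `pos`, `impact_category`.
#' @return A [nomination_set()] at variant level, method
#'   `"sveinbjornsson"`; items carry the resolved `impact_category`.
#' @export
nominate_sveinbjornsson <- function(records, annotations) {
  if (missing(annotations) || is.null(annotations)) {
    stop("an annotation table with impact categories is required",
         call. = FALSE)
  }
  thresholds <- sveinbjornsson_thresholds()
  bad <- setdiff(unique(annotations$impact_category), names(thresholds))
  if (length(bad) > 0L) {
    stop("unknown impact categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(records$chrom, records$pos, sep = ":")
  akey <- paste(annotations$chrom, annotations$pos, sep = ":")
  category <- annotations$impact_category[match(key, akey)]
  category[is.na(category)] <- "other"
  nominated <- !is.na(records$pvalue) &
    records$pvalue < thresholds[category]
  items <- records[nominated, , drop = FALSE]
  items$impact_category <- category[nominated]
  rownames(items) <- NULL
  nomination_set("sveinbjornsson", "variant", items)
}

#' Weighted-eQTL configuration
#'
#' Parameters of the weighted-Bonferroni eQTL prioritisation. `alpha` and
#' `power` document the family-wise error target and power target of the
#' weighting scheme; the number of included variants `M` and the eSNP
#' fraction `epsilon` are measured from the data at run time. In
#' `"general"` mode the raw weight of an eSNP is `sqrt(-log10(p_eQTL))`; in
#' `"binary"` mode eSNPs share a single relative weight `binary_ratio`
#' (non-eSNPs always have raw weight 1).
#'
#' @param alpha Family-wise error target (default 0.05).
#' @param power Target power (default 0.6).
#' @param mode `"general"` or `"binary"`.
#' @param binary_ratio Relative eSNP/non-eSNP weight for binary mode
#'   (must be positive).
#' @return A named list.
#' @export
weighted_eqtl_config <- function(alpha = 0.05, power = 0.6,
                                 mode = c("general", "binary"),
                                 binary_ratio = 2) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, power > 0, power <= 1, binary_ratio > 0)
  list(alpha = alpha, power = power, mode = mode,
       binary_ratio = binary_ratio)
}

#' Nominate variants by weighted-Bonferroni eQTL prioritisation
#'
#' Assigns each of the M variants a raw weight -- `sqrt(-log10(p_eQTL))`
#' for eSNPs and 1 for all others in general mode, or `binary_ratio` for
#' eSNPs and 1 otherwise in binary mode -- normalizes the weights to mean 1
#' over all M variants (which preserves the family-wise error rate of the
#' weighted Bonferroni procedure), and forms weighted p-values
#' `p_w = min(1, p / w)`. A variant is nominated when `p_w < sig_threshold`.
#' With `novel_only = TRUE` variants already significant unweighted
#' (`p < sig_threshold`) are additionally removed from the set; by default
#' that exclusion is left to the evaluation stage so all methods are
#' filtered identically.
#'
#' eSNP rows whose eQTL p-value is not in (0, 1) are rejected with a warning
#' and do not enter M.
#'
#' @param records Variant-record data frame.
#' @param annotations Data frame with `chrom`, `pos`, `is_esnp`, and
#'   `eqtl_pvalue` for eSNPs.
#' @param cfg A [weighted_eqtl_config()].
#' @param sig_threshold Weighted significance cutoff (default 5e-8).
#' @param novel_only Drop variants already significant unweighted.
#' @return A [nomination_set()] at variant level, method
#'   `"weighted_eqtl"`; items carry `weight` and `weighted_p`. Attributes
#'   `M` (variants used) and `epsilon` (eSNP fraction) are attached to the
#'   set.
#' @export
weighted_eqtl_nominate <- function(records, annotations,
                                   cfg = weighted_eqtl_config(),
                                   sig_threshold = 5e-8,
                                   novel_only = FALSE) {
  if (missing(annotations) || is.null(annotations)) {
    stop("an annotation table flagging eSNPs is required", call. = FALSE)
  }
  key <- paste(records$chrom, records$pos, sep = ":")
  akey <- paste(annotations$chrom, annotations$pos, sep = ":")
  idx <- match(key, akey)
  is_esnp <- !is.na(idx) & annotations$is_esnp[idx]
  eqtl_p <- ifelse(is_esnp, annotations$eqtl_pvalue[idx], NA_real_)

  bad <- is_esnp & (is.na(eqtl_p) | eqtl_p <= 0 | eqtl_p >= 1)
  if (any(bad)) {
    warning(sum(bad), " eSNP record(s) with eQTL p-value outside (0, 1) ",
            "rejected", call. = FALSE)
    records <- records[!bad, , drop = FALSE]
    is_esnp <- is_esnp[!bad]
    eqtl_p <- eqtl_p[!bad]
  }
  M <- nrow(records)
  if (M == 0L) {
    out <- nomination_set("weighted_eqtl", "variant", records)
    attr(out, "M") <- 0L
    attr(out, "epsilon") <- NA_real_
    return(out)
  }
  raw_w <- ifelse(is_esnp,
                  if (cfg$mode == "general") sqrt(-log10(eqtl_p))
                  else cfg$binary_ratio,
                  1)
  w <- raw_w / mean(raw_w) # mean-1 normalization over all M variants
  weighted_p <- pmin(1, records$pvalue / w)
  nominated <- !is.na(weighted_p) & weighted_p < sig_threshold
  if (novel_only) {
    nominated <- nominated & records$pvalue >= sig_threshold
  }
  items <- records[nominated, , drop = FALSE]
  items$weight <- w[nominated]
  items$weighted_p <- weighted_p[nominated]
  rownames(items) <- NULL
  out <- nomination_set("weighted_eqtl", "variant", items)
  attr(out, "M") <- M
  attr(out, "epsilon") <- mean(is_esnp)
  attr(out, "weights") <- w
  out
}

#' Bonferroni significance mask
#'
#' Thresholds p-values at `alpha / n_valid`, where `n_valid` counts the
#' non-missing p-values -- the correction applied to any method that
#' reports p-values without its own significance threshold.
#'
#' @param pvalues Numeric vector (may contain `NA`).
#' @param alpha Family-wise error level (default 0.05).
#' @return List with `mask` (logical, `NA` where the p-value was missing),
#'   `threshold` (`NA` when no valid p-values), and `n_valid`.
#' @export
bonferroni_significant <- function(pvalues, alpha = 0.05) {
  valid <- !is.na(pvalues)
  n_valid <- sum(valid)
  threshold <- if (n_valid > 0L) alpha / n_valid else NA_real_
  mask <- rep(NA, length(pvalues))
  if (n_valid > 0L) mask[valid] <- pvalues[valid] < threshold
  list(mask = mask, threshold = threshold, n_valid = n_valid)
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up q-values with the usual monotone adjustment
#' (`stats::p.adjust(method = "BH")`); significance is `q < q_level`.
#'
#' @param pvalues Numeric vector (may contain `NA`).
#' @param q_level FDR cutoff (default 0.05).
#' @return List with `mask` (logical, `NA` where missing), `qvalues`, and
#'   `n_valid`.
#' @export
fdr_significant <- function(pvalues, q_level = 0.05) {
  valid <- !is.na(pvalues)
  qvalues <- rep(NA_real_, length(pvalues))
  mask <- rep(NA, length(pvalues))
  if (any(valid)) {
    qvalues[valid] <- stats::p.adjust(pvalues[valid], method = "BH")
    mask[valid] <- qvalues[valid] < q_level
  }
  list(mask = mask, qvalues = qvalues, n_valid = sum(valid))
}
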