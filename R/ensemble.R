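#' Build the deduplicated loci x methods membership matrix
#'
#' Stepwise construction used for UpSet-style intersection analysis:
#' methods are processed from largest to smallest number of nominated loci
#' (ties broken by method name); the first method's loci seed the matrix;
#' each later method contributes only loci that do not already overlap a
#' matrix locus by at least `min_overlap` bases; and every locus added to
#' the matrix is tested against every method's loci to fill its row, so a
#' row records all methods that nominated that region.
#'
#' @param nominations_by_method Named list of locus data frames, each
#'   already merged and pre-filtered against earlier-wave loci.
#' @param min_overlap Minimum base overlap for two loci to count as the
#'   same nomination (default 250000). `Inf` disables deduplication: every
#'   locus becomes its own row, with membership only for its own method.
#' @return An object of class `ensemble_matrix`: list with `loci` (locus
#'   data frame with a `source_method` column), `methods` (ordered names),
#'   `membership` (logical loci x methods matrix), and `gold_flag`
#'   (`NA` until [flag_gold()] is applied).
#' @export
build_ensemble_matrix <- function(nominations_by_method,
                                  min_overlap = 250000) {
  if (length(nominations_by_method) == 0L) {
    return(structure(list(loci = .empty_loci(), methods = character(0),
                          membership = matrix(FALSE, 0, 0),
                          gold_flag = logical(0)),
                     class = "ensemble_matrix"))
  }
  if (is.null(names(nominations_by_method)) ||
      anyDuplicated(names(nominations_by_method))) {
    stop("nominations_by_method must be uniquely named", call. = FALSE)
  }
  counts <- vapply(nominations_by_method, nrow, integer(1))
  method_order <- names(nominations_by_method)[order(-counts,
                                                     names(nominations_by_method))]

  matrix_loci <- NULL
  source_method <- character(0)
  for (m in method_order) {
    loci_m <- nominations_by_method[[m]]
    if (nrow(loci_m) == 0L) next
    loci_m <- loci_m[order(.chrom_key(loci_m$chrom), loci_m$start), ,
                     drop = FALSE]
    if (is.null(matrix_loci)) {
      new <- rep(TRUE, nrow(loci_m))
    } else if (is.infinite(min_overlap)) {
      new <- rep(TRUE, nrow(loci_m))
    } else {
      new <- .max_overlap(loci_m, matrix_loci) < min_overlap
    }
    if (any(new)) {
      add <- loci_m[new, , drop = FALSE]
      # a method's own new loci are pairwise non-overlapping (merged input),
      # so they can be appended in one block
      matrix_loci <- if (is.null(matrix_loci)) add else
        rbind(matrix_loci[, c("chrom", "start", "end")],
              add[, c("chrom", "start", "end")])
      matrix_loci <- matrix_loci[, c("chrom", "start", "end"), drop = FALSE]
      source_method <- c(source_method, rep(m, sum(new)))
    }
  }
  if (is.null(matrix_loci)) {
    return(structure(list(loci = .empty_loci(),
                          methods = method_order,
                          membership = matrix(FALSE, 0, length(method_order),
                                              dimnames = list(NULL, method_order)),
                          gold_flag = logical(0)),
                     class = "ensemble_matrix"))
  }
  rownames(matrix_loci) <- NULL

  membership <- matrix(FALSE, nrow(matrix_loci), length(method_order),
                       dimnames = list(NULL, method_order))
  for (m in method_order) {
    loci_m <- nominations_by_method[[m]]
    if (nrow(loci_m) == 0L) next
    if (is.infinite(min_overlap)) {
      membership[, m] <- FALSE
    } else {
      membership[, m] <- .max_overlap(matrix_loci, loci_m) >= min_overlap
    }
  }
  # the contributing method always owns its row (relevant when
  # min_overlap = Inf, where the overlap test is vacuously false)
  for (i in seq_len(nrow(matrix_loci))) {
    membership[i, source_method[i]] <- TRUE
  }

  loci <- .annotate_loci(matrix_loci, NULL)
  loci$source_method <- source_method
  structure(list(loci = loci, methods = method_order,
                 membership = membership,
                 gold_flag = rep(NA, nrow(loci))),
            class = "ensemble_matrix")
}

#' @export
print.ensemble_matrix <- function(x, ...) {
  cat("<ensemble_matrix>", nrow(x$loci), "loci x", length(x$methods),
      "methods\n")
  if (nrow(x$loci) > 0L) {
    supp <- rowSums(x$membership)
    cat("  support counts:", paste(table(supp), collapse = " "),
        "(k =", paste(names(table(supp)), collapse = " "), ")\n")
  }
  invisible(x)
}

#' Flag ensemble-matrix loci confirmed by the gold standard
#'
#' Sets each row's `gold_flag` to whether the locus overlaps any gold locus
#' by at least `min_overlap` bases (the same rule as
#' [classify_locus_level()]).
#'
#' @param matrix An `ensemble_matrix`.
#' @param gold_loci Locus data frame (gold standard, post-exclusion).
#' @param min_overlap Minimum base overlap (default 250000).
#' @return The matrix with `gold_flag` populated.
#' @export
flag_gold <- function(matrix, gold_loci, min_overlap = 250000) {
  stopifnot(inherits(matrix, "ensemble_matrix"))
  if (nrow(matrix$loci) == 0L) {
    matrix$gold_flag <- logical(0)
    return(matrix)
  }
  matrix$gold_flag <- .max_overlap(matrix$loci, gold_loci) >= min_overlap
  matrix
}

#' PPV stratified by the number of nominating methods
#'
#' For each support level k, reports the PPV over loci nominated by at
#' least k methods (the cumulative reading behind "minimum number of
#' methods necessary") and over loci nominated by exactly k methods (which
#' exposes any non-monotonicity).
#'
#' @param matrix An `ensemble_matrix` with `gold_flag` populated (see
#'   [flag_gold()]).
#' @return Data frame with columns `support`, `n_loci_ge`, `ppv_ge`,
#'   `n_loci_eq`, `ppv_eq`; PPV is `NA` for empty strata.
#' @export
ppv_by_support <- function(matrix) {
  stopifnot(inherits(matrix, "ensemble_matrix"))
  if (nrow(matrix$loci) == 0L) {
    return(data.frame(support = integer(0), n_loci_ge = integer(0),
                      ppv_ge = numeric(0), n_loci_eq = integer(0),
                      ppv_eq = numeric(0)))
  }
  if (anyNA(matrix$gold_flag)) {
    stop("gold_flag not populated; run flag_gold() first", call. = FALSE)
  }
  support <- rowSums(matrix$membership)
  ks <- seq_len(max(length(matrix$methods), 1L))
  rows <- lapply(ks, function(k) {
    ge <- support >= k
    eq <- support == k
    data.frame(
      support = k,
      n_loci_ge = sum(ge),
      ppv_ge = if (any(ge)) mean(matrix$gold_flag[ge]) else NA_real_,
      n_loci_eq = sum(eq),
      ppv_eq = if (any(eq)) mean(matrix$gold_flag[eq]) else NA_real_
    )
  })
  do.call(rbind, rows)
}
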