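#' Column-mapping dialect for delimited summary-statistics files
#'
#' Names the header columns that hold each field of a variant record. Only
#' `chrom`, `pos`, and `pvalue` are mandatory; the rest may be `NULL` when the
#' file does not carry them.
#'
#' @param chrom,pos,pvalue Header names of the chromosome, base-position, and
#'   p-value columns.
#' @param rsid,a1,a2,freq,effect Optional header names for the variant
#'   identifier, alleles, allele frequency, and signed effect (or odds ratio).
#' @return A named list used by [read_sumstats()].
#' @export
#' @examples
#' sumstats_dialect(chrom = "CHR", pos = "BP", pvalue = "P", rsid = "SNP")
sumstats_dialect <- function(chrom = "CHR", pos = "POS", pvalue = "P",
                             rsid = NULL, a1 = NULL, a2 = NULL,
                             freq = NULL, effect = NULL) {
  list(chrom = chrom, pos = pos, pvalue = pvalue, rsid = rsid,
       a1 = a1, a2 = a2, freq = freq, effect = effect)
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a whitespace- or tab-delimited file with a header, maps columns
#' through a [sumstats_dialect()], normalizes chromosome labels (a leading
#' `"chr"` prefix is stripped), and drops rows whose chromosome, position, or
#' p-value cannot be parsed. Unparseable p-values are `NA`, negative, or
#' greater than one; a parsed zero is kept (it is handled by
#' [truncate_pvalues()]). The number of dropped rows is attached as attribute
#' `n_dropped`.
#'
#' @param path Path to the file.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @return A data frame of variant records with columns `chrom`, `pos`,
#'   `rsid`, `a1`, `a2`, `freq`, `effect`, `pvalue`, sorted by
#'   (chrom, pos), with attribute `n_dropped`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character", showProgress = FALSE)
  mandatory <- c("chrom", "pos", "pvalue")
  for (field in mandatory) {
    col <- dialect[[field]]
    if (is.null(col) || !(col %in% names(dt))) {
      stop("summary-statistics column for '", field, "' (",
           col %||% "<unset>", ") not found in ", path, call. = FALSE)
    }
  }
  if (nrow(dt) == 0L) {
    warning("empty summary-statistics file: ", path, call. = FALSE)
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      rsid = character(0), a1 = character(0),
                      a2 = character(0), freq = numeric(0),
                      effect = numeric(0), pvalue = numeric(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  grab <- function(field, as = identity) {
    col <- dialect[[field]]
    if (is.null(col) || !(col %in% names(dt))) rep(NA, nrow(dt)) else as(dt[[col]])
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    chrom  = .norm_chrom(grab("chrom")),
    pos    = num(grab("pos")),
    rsid   = as.character(grab("rsid")),
    a1     = as.character(grab("a1")),
    a2     = as.character(grab("a2")),
    freq   = num(grab("freq")),
    effect = num(grab("effect")),
    pvalue = num(grab("pvalue")),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(out$chrom) & nzchar(out$chrom) &
    !is.na(out$pos) & out$pos >= 1 &
    !is.na(out$pvalue) & out$pvalue >= 0 & out$pvalue <= 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(n_dropped, " row(s) with unparseable chrom/pos/p dropped from ",
            basename(path))
  }
  out <- .order_by_position(out[ok, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write variant records as tab-delimited text
#'
#' Writes records with full double precision so a read/write/read round trip
#' preserves `chrom`, `pos`, and `pvalue` exactly.
#'
#' @param records Variant-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  out <- data.frame(
    CHR = records$chrom,
    POS = sprintf("%.0f", records$pos),
    SNP = records$rsid %||% NA_character_,
    A1 = records$a1, A2 = records$a2,
    FREQ = sprintf("%.17g", records$freq),
    EFFECT = sprintf("%.17g", records$effect),
    P = sprintf("%.17g", records$pvalue),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Floor extreme p-values at the smallest reliably representable value
#'
#' Replaces every p-value below `floor` -- including parsed zeros from text
#' files whose true values underflowed double precision -- by `floor`
#' (default `7.41e-323`). Idempotent and order-preserving.
#'
#' @param records Variant-record data frame with a `pvalue` column.
#' @param floor Replacement value; p-values below it are set to it.
#' @return The records with truncated p-values.
#' @export
truncate_pvalues <- function(records, floor = 7.41e-323) {
  low <- !is.na(records$pvalue) & records$pvalue < floor
  records$pvalue[low] <- floor
  records
}

#' Keep one record per genomic position
#'
#' When several records share a (chrom, pos), the one with the smallest
#' p-value is retained; p-value ties are broken by lexicographically smallest
#' rsid, then first occurrence. Idempotent.
#'
#' @param records Variant-record data frame.
#' @return Deduplicated records sorted by (chrom, pos).
#' @export
dedupe_by_position <- function(records) {
  if (nrow(records) == 0L) return(records)
  rsid <- if ("rsid" %in% names(records)) records$rsid else rep(NA_character_, nrow(records))
  ord <- order(.chrom_key(records$chrom), records$pos, records$pvalue,
               xtfrm(rsid), seq_len(nrow(records)), na.last = TRUE)
  records <- records[ord, , drop = FALSE]
  keep <- !duplicated(paste(records$chrom, records$pos, sep = ":"))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter records to those with required fields present and parseable
#'
#' @param records Variant-record data frame.
#' @param require Character subset of `c("rsid", "freq", "effect")`.
#' @return Filtered records with attribute `n_retained`.
#' @export
filter_valid <- function(records, require = character(0)) {
  if (length(require) > 0L) {
    require <- unique(match.arg(require, c("rsid", "freq", "effect"),
                                several.ok = TRUE))
  }
  ok <- rep(TRUE, nrow(records))
  if ("rsid" %in% require) {
    ok <- ok & !is.na(records$rsid) & nzchar(records$rsid) & records$rsid != "."
  }
  if ("freq" %in% require) {
    ok <- ok & is.finite(records$freq) & records$freq >= 0 & records$freq <= 1
  }
  if ("effect" %in% require) {
    ok <- ok & is.finite(records$effect)
  }
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_retained") <- nrow(out)
  out
}

#' Column-mapping dialect for gene score tables
#'
#' @param gene_id,chrom,start,end Mandatory header names.
#' @param symbol,pvalue Optional header names.
#' @return A named list used by [read_gene_table()].
#' @export
gene_dialect <- function(gene_id = "GENE", chrom = "CHR", start = "START",
                         end = "END", symbol = NULL, pvalue = NULL) {
  list(gene_id = gene_id, chrom = chrom, start = start, end = end,
       symbol = symbol, pvalue = pvalue)
}

#' Read a gene score table (e.g. gene-based association output)
#'
#' Rows with malformed boundaries (non-numeric, or `start > end`) are dropped
#' with a warning; the drop count is attached as attribute `n_dropped`. Both
#' the stable gene id and the symbol are retained so downstream matching can
#' use either key.
#'
#' @param path Path to a delimited text file with a header.
#' @param dialect Column mapping from [gene_dialect()].
#' @return Data frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `midpoint`, `pvalue`.
#' @export
read_gene_table <- function(path, dialect = gene_dialect()) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character", showProgress = FALSE)
  for (field in c("gene_id", "chrom", "start", "end")) {
    col <- dialect[[field]]
    if (is.null(col) || !(col %in% names(dt))) {
      stop("gene-table column for '", field, "' (", col %||% "<unset>",
           ") not found in ", path, call. = FALSE)
    }
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  grab <- function(field) {
    col <- dialect[[field]]
    if (is.null(col) || !(col %in% names(dt))) rep(NA_character_, nrow(dt)) else dt[[col]]
  }
  out <- data.frame(
    gene_id = as.character(dt[[dialect$gene_id]]),
    symbol = as.character(grab("symbol")),
    chrom = .norm_chrom(dt[[dialect$chrom]]),
    start = num(dt[[dialect$start]]),
    end = num(dt[[dialect$end]]),
    pvalue = num(grab("pvalue")),
    stringsAsFactors = FALSE
  )
  ok <- is.finite(out$start) & is.finite(out$end) & out$start <= out$end
  if (any(!ok)) {
    warning(sum(!ok), " gene row(s) with malformed boundaries dropped",
            call. = FALSE)
  }
  out <- out[ok, , drop = FALSE]
  out$midpoint <- gene_midpoint(out)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Gene midpoint, `floor((start + end) / 2)`
#' @param genes Gene-record data frame.
#' @return Numeric vector of midpoints.
#' @export
gene_midpoint <- function(genes) {
  floor((genes$start + genes$end) / 2)
}

#' Construct a nomination set
#'
#' A nomination set is one method's output: a collection of nominated
#' variants, genes, or loci tagged with the method name and the evaluation
#' level.
#'
#' @param method Method name.
#' @param level One of `"variant"`, `"gene"`, `"locus"`.
#' @param items Data frame of nominated items. Variant level requires
#'   `chrom` and `pos`; gene level requires `gene_id` and/or `symbol`;
#'   locus level requires `chrom`, `start`, `end`.
#' @return Object of class `nomination_set`.
#' @export
nomination_set <- function(method, level = c("variant", "gene", "locus"),
                           items) {
  level <- match.arg(level)
  needed <- switch(level,
    variant = c("chrom", "pos"),
    gene = character(0),
    locus = c("chrom", "start", "end"))
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols) > 0L) {
    stop("nomination items at level '", level, "' need column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (level == "gene" && !any(c("gene_id", "symbol") %in% names(items))) {
    stop("gene-level nomination items need 'gene_id' or 'symbol'",
         call. = FALSE)
  }
  structure(list(method = method, level = level, items = items),
            class = "nomination_set")
}

#' @export
print.nomination_set <- function(x, ...) {
  cat("<nomination_set> method:", x$method, " level:", x$level,
      " items:", nrow(x$items), "\n")
  invisible(x)
}

#' Read a per-method nomination file
#'
#' Variant-level files carry `chrom` + `pos` columns, gene-level files a gene
#' id and/or symbol (with an optional score), locus-level files
#' `chrom` + `start` + `end`.
#'
#' @param path Path to a tab-delimited file with a header.
#' @param level Evaluation level of the method.
#' @param dialect Named list mapping fields to header names. Defaults per
#'   level: variant `list(chrom = "CHR", pos = "POS")`; gene
#'   `list(gene_id = "GENE", symbol = "SYMBOL", score = "SCORE")`; locus
#'   `list(chrom = "CHR", start = "START", end = "END")`.
#' @param method Method name; defaults to the file name without extension.
#' @return A [nomination_set()].
#' @export
read_nominations <- function(path, level = c("variant", "gene", "locus"),
                             dialect = NULL, method = NULL) {
  level <- match.arg(level)
  method <- method %||% sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character", showProgress = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))
  pick <- function(field, default) {
    col <- (dialect[[field]] %||% default)
    if (col %in% names(dt)) dt[[col]] else NULL
  }
  items <- switch(level,
    variant = {
      chrom <- pick("chrom", "CHR"); pos <- pick("pos", "POS")
      if (is.null(chrom) || is.null(pos)) {
        stop("variant-level nominations need chrom and pos columns",
             call. = FALSE)
      }
      df <- data.frame(chrom = .norm_chrom(chrom), pos = num(pos),
                       stringsAsFactors = FALSE)
      p <- pick("pvalue", "P")
      if (!is.null(p)) df$pvalue <- num(p)
      ok <- !is.na(df$pos)
      if (any(!ok)) message(sum(!ok), " unresolvable nomination(s) dropped")
      df[ok, , drop = FALSE]
    },
    gene = {
      df <- data.frame(stringsAsFactors = FALSE, row.names = NULL)
      id <- pick("gene_id", "GENE"); sym <- pick("symbol", "SYMBOL")
      if (is.null(id) && is.null(sym)) {
        stop("gene-level nominations need a gene id or symbol column",
             call. = FALSE)
      }
      df <- data.frame(
        gene_id = if (is.null(id)) NA_character_ else as.character(id),
        symbol = if (is.null(sym)) NA_character_ else as.character(sym),
        stringsAsFactors = FALSE
      )
      sc <- pick("score", "SCORE")
      if (!is.null(sc)) df$score <- num(sc)
      df
    },
    locus = {
      chrom <- pick("chrom", "CHR")
      st <- pick("start", "START"); en <- pick("end", "END")
      if (is.null(chrom) || is.null(st) || is.null(en)) {
        stop("locus-level nominations need chrom, start, end columns",
             call. = FALSE)
      }
      data.frame(chrom = .norm_chrom(chrom), start = num(st), end = num(en),
                 stringsAsFactors = FALSE)
    })
  rownames(items) <- NULL
  nomination_set(method, level, items)
}

#' Write loci as tab-delimited text (1-based closed intervals)
#'
#' @param loci Locus data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  out <- data.frame(
    chrom = loci$chrom,
    start = sprintf("%.0f", loci$start),
    end = sprintf("%.0f", loci$end),
    lead_pos = ifelse(is.na(loci$lead_pos), "NA", sprintf("%.0f", loci$lead_pos)),
    lead_p = sprintf("%.17g", loci$lead_p),
    n_members = loci$n_members,
    is_hla = loci$is_hla,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read loci written by [write_loci()]
#' @param path Input path.
#' @return Locus data frame.
#' @export
read_loci <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character", showProgress = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))
  data.frame(
    chrom = .norm_chrom(dt$chrom),
    start = num(dt$start), end = num(dt$end),
    lead_pos = num(dt$lead_pos), lead_p = num(dt$lead_p),
    n_members = as.integer(dt$n_members),
    is_hla = as.logical(dt$is_hla),
    stringsAsFactors = FALSE
  )
}

#' Export loci as BED (0-based, half-open)
#'
#' On write, 1-based closed intervals `[start, end]` become BED lines
#' `start - 1, end`. Starts below 1 (possible for unclipped windows) are
#' clamped at 0 and the number of clamped records is reported in a message
#' and as attribute `n_clamped` on the returned path.
#'
#' @param loci Locus data frame.
#' @param path Output path.
#' @return `path`, invisibly, with attribute `n_clamped`.
#' @export
write_bed <- function(loci, path) {
  bed_start <- pmax(loci$start - 1, 0)
  n_clamped <- sum(loci$start - 1 < 0)
  if (n_clamped > 0L) {
    message(n_clamped, " locus start(s) clamped at 0 in BED export")
  }
  out <- data.frame(
    chrom = loci$chrom,
    start = sprintf("%.0f", bed_start),
    end = sprintf("%.0f", loci$end),
    name = ifelse(isTRUE(loci$is_hla) | loci$is_hla,
                  "HLA", sprintf("locus_%d", seq_len(nrow(loci)))),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  out_path <- path
  attr(out_path, "n_clamped") <- n_clamped
  invisible(out_path)
}
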