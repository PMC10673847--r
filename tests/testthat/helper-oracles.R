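# Brute-force reference implementations used to cross-check the package's
# interval machinery. Deliberately written with plain loops and no shared
# helpers so they are independent of the code paths they validate.

# Closed-interval overlap in bases between two intervals on one chromosome.
oracle_overlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  max(0, min(e1, e2) - max(s1, s2) + 1)
}

# Stepwise locus definition: repeated smallest-p lead extraction, then
# quadratic pairwise merging to a fixpoint, then HLA collapsing.
oracle_define_loci <- function(records, sig_threshold = 5e-8,
                               flank = 500000, hla_chrom = "6",
                               hla_start = 25e6, hla_end = 35e6) {
  sig <- records[!is.na(records$pvalue) & records$pvalue < sig_threshold, ,
                 drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  chrom_num <- function(ch) {
    v <- suppressWarnings(as.numeric(ch))
    ifelse(is.na(v), 1000, v)
  }
  iv <- data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), stringsAsFactors = FALSE)
  left <- sig
  while (nrow(left) > 0L) {
    best <- 1L
    for (i in seq_len(nrow(left))) {
      better <- left$pvalue[i] < left$pvalue[best] ||
        (left$pvalue[i] == left$pvalue[best] &&
           (chrom_num(left$chrom[i]) < chrom_num(left$chrom[best]) ||
              (chrom_num(left$chrom[i]) == chrom_num(left$chrom[best]) &&
                 left$pos[i] < left$pos[best])))
      if (better) best <- i
    }
    lead <- left[best, ]
    iv <- rbind(iv, data.frame(chrom = lead$chrom,
                               start = lead$pos - flank,
                               end = lead$pos + flank))
    drop <- rep(FALSE, nrow(left))
    for (i in seq_len(nrow(left))) {
      drop[i] <- left$chrom[i] == lead$chrom &&
        left$pos[i] >= lead$pos - flank && left$pos[i] <= lead$pos + flank
    }
    left <- left[!drop, , drop = FALSE]
  }
  # quadratic merge to fixpoint
  merged <- TRUE
  while (merged) {
    merged <- FALSE
    for (i in seq_len(nrow(iv))) {
      for (j in seq_len(nrow(iv))) {
        if (i >= j || i > nrow(iv) || j > nrow(iv)) next
        if (oracle_overlap(iv$chrom[i], iv$start[i], iv$end[i],
                           iv$chrom[j], iv$start[j], iv$end[j]) >= 1) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  # HLA collapsing: union all chr-6 intervals touching the fixed region
  hit <- rep(FALSE, nrow(iv))
  for (i in seq_len(nrow(iv))) {
    hit[i] <- oracle_overlap(iv$chrom[i], iv$start[i], iv$end[i],
                             hla_chrom, hla_start, hla_end) >= 1
  }
  if (any(hit)) {
    u <- data.frame(chrom = hla_chrom,
                    start = min(hla_start, iv$start[hit]),
                    end = max(hla_end, iv$end[hit]))
    iv <- rbind(iv[!hit, , drop = FALSE], u)
    # re-merge after the union
    merged <- TRUE
    while (merged) {
      merged <- FALSE
      for (i in seq_len(nrow(iv))) {
        for (j in seq_len(nrow(iv))) {
          if (i >= j) next
          if (oracle_overlap(iv$chrom[i], iv$start[i], iv$end[i],
                             iv$chrom[j], iv$start[j], iv$end[j]) >= 1) {
            iv$start[i] <- min(iv$start[i], iv$start[j])
            iv$end[i] <- max(iv$end[i], iv$end[j])
            iv <- iv[-j, , drop = FALSE]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
  }
  iv <- iv[order(chrom_num(iv$chrom), iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# Pairwise-scan classification of nominated vs gold loci.
oracle_classify <- function(nominated, gold, min_overlap) {
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(nominated))) {
    hit <- FALSE
    for (j in seq_len(nrow(gold))) {
      if (oracle_overlap(nominated$chrom[i], nominated$start[i],
                         nominated$end[i], gold$chrom[j], gold$start[j],
                         gold$end[j]) >= min_overlap) hit <- TRUE
    }
    if (hit) tp <- tp + 1L else fp <- fp + 1L
  }
  covered <- 0L
  for (j in seq_len(nrow(gold))) {
    hit <- FALSE
    for (i in seq_len(nrow(nominated))) {
      if (oracle_overlap(nominated$chrom[i], nominated$start[i],
                         nominated$end[i], gold$chrom[j], gold$start[j],
                         gold$end[j]) >= min_overlap) hit <- TRUE
    }
    if (hit) covered <- covered + 1L
  }
  list(tp = tp, fp = fp, gold_covered = covered,
       fn = nrow(gold) - covered)
}

# Stepwise ensemble-matrix construction with explicit loops.
oracle_ensemble <- function(by_method, min_overlap) {
  counts <- vapply(by_method, nrow, integer(1))
  ord <- names(by_method)[order(-counts, names(by_method))]
  rows <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), stringsAsFactors = FALSE)
  for (m in ord) {
    loci <- by_method[[m]]
    if (nrow(loci) == 0L) next
    chrom_num <- suppressWarnings(as.numeric(loci$chrom))
    chrom_num[is.na(chrom_num)] <- 1000
    loci <- loci[order(chrom_num, loci$start), , drop = FALSE]
    for (i in seq_len(nrow(loci))) {
      dup <- FALSE
      for (r in seq_len(nrow(rows))) {
        if (oracle_overlap(loci$chrom[i], loci$start[i], loci$end[i],
                           rows$chrom[r], rows$start[r],
                           rows$end[r]) >= min_overlap) dup <- TRUE
      }
      if (!dup) {
        rows <- rbind(rows, data.frame(chrom = loci$chrom[i],
                                       start = loci$start[i],
                                       end = loci$end[i]))
      }
    }
  }
  membership <- matrix(FALSE, nrow(rows), length(ord),
                       dimnames = list(NULL, ord))
  for (r in seq_len(nrow(rows))) {
    for (m in ord) {
      loci <- by_method[[m]]
      for (i in seq_len(nrow(loci))) {
        if (oracle_overlap(rows$chrom[r], rows$start[r], rows$end[r],
                           loci$chrom[i], loci$start[i],
                           loci$end[i]) >= min_overlap) {
          membership[r, m] <- TRUE
        }
      }
    }
  }
  list(loci = rows, membership = membership)
}

# Random variant table on a compact two-chromosome genome.
random_records <- function(n, seed, p_sig = 0.3, genome = c("1" = 2e7, "2" = 2e7)) {
  set.seed(seed)
  chrom <- sample(names(genome), n, replace = TRUE)
  pos <- vapply(chrom, function(ch) sample.int(genome[[ch]], 1L), numeric(1))
  p <- ifelse(runif(n) < p_sig, 10^runif(n, -14, -7.4), runif(n))
  df <- data.frame(chrom = chrom, pos = pos, pvalue = p,
                   stringsAsFactors = FALSE)
  df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
}

# Random merged locus set.
random_loci <- function(n, seed, genome = c("1" = 2e7, "2" = 2e7)) {
  pts <- random_records(n, seed, p_sig = 1, genome = genome)
  merge_loci(windows_from_points(pts[, c("chrom", "pos")], flank = 3e5))
}
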