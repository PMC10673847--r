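#' Configuration for the two-wave GWAS simulator
#'
#' The simulator emulates the structure the evaluation framework consumes:
#' two GWAS waves of the same trait on a shared variant set, where the
#' larger second wave reaches genome-wide significance at a superset of the
#' planted causal loci, and association signal decays with distance from
#' each planted lead. No linkage-disequilibrium matrix is simulated; the
#' exponential distance decay is a deliberate simplification sufficient to
#' exercise locus collapsing.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases
#'   (default: two chromosomes of 50 Mb, sized for tests).
#' @param n_variants Total number of variants across chromosomes.
#' @param n_causal_loci Number of planted causal loci.
#' @param effect_scale Lead-variant z-score magnitude at the wave-1 sample
#'   size; the wave-w lead z is `effect_scale * sqrt(n_w / n1)`.
#' @param n1,n2 Wave sample sizes, `n2 > n1`.
#' @param decay_bp Exponential distance-decay scale of the signal around
#'   each planted lead; variants beyond `3 * decay_bp` are pure null.
#' @param flank Locus half-width used to space planted leads (leads are
#'   kept more than `2 * flank` apart so planted loci stay unambiguous).
#' @param lead_positions Optional data frame with `chrom`, `pos` fixing the
#'   planted leads; spacing is validated.
#' @param seed Root RNG seed; all stage draws derive from it.
#' @return A named list.
#' @export
sim_config <- function(chrom_lengths = c("1" = 5e7, "2" = 5e7),
                       n_variants = 20000, n_causal_loci = 4,
                       effect_scale = 4.5, n1 = 20000, n2 = 80000,
                       decay_bp = 50000, flank = 500000,
                       lead_positions = NULL, seed = 1) {
  stopifnot(n2 > n1, n1 >= 1, decay_bp > 0, n_variants >= 1,
            all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  list(chrom_lengths = chrom_lengths, n_variants = n_variants,
       n_causal_loci = n_causal_loci, effect_scale = effect_scale,
       n1 = n1, n2 = n2, decay_bp = decay_bp, flank = flank,
       lead_positions = lead_positions, seed = seed)
}

#' Internal: stage seeds derived once from the root seed, by name, so
#' adding a stage never perturbs earlier draws.
#' @noRd
.stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 6L),
                  c("positions", "leads", "noise1", "noise2",
                    "annotations", "genes"))
}

#' Internal: validate planted-lead spacing (> 2 * flank within chromosome).
#' @noRd
.check_lead_spacing <- function(leads, flank) {
  for (chr in unique(leads$chrom)) {
    p <- sort(leads$pos[leads$chrom == chr])
    if (length(p) > 1L && any(diff(p) <= 2 * flank)) {
      stop("planted leads closer than 2 * flank on chromosome ", chr,
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Simulate two GWAS waves with planted causal loci
#'
#' Variant positions are uniform per chromosome (allocated proportionally
#' to chromosome length). Null variants draw independent standard-normal
#' z-scores per wave. Variants within `3 * decay_bp` of a planted lead
#' carry a shared deterministic signal
#' `mu = effect_scale * exp(-d / decay_bp)` scaled per wave by
#' `sqrt(n_wave / n1)`, plus independent standard-normal noise. P-values
#' are two-sided normal tails, floored at `7.41e-323` (see
#' [truncate_pvalues()]). Both waves share the same variant set, and output
#' is fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `wave1`, `wave2` (variant-record data frames) and
#'   `truth` (data frame of planted leads with `chrom`, `pos`).
#' @export
simulate_two_wave_gwas <- function(cfg = sim_config()) {
  seeds <- .stage_seeds(cfg$seed)
  chroms <- names(cfg$chrom_lengths)

  # positions: proportional allocation, sampled without replacement
  set.seed(seeds[["positions"]])
  alloc <- round(cfg$n_variants * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  alloc[length(alloc)] <- cfg$n_variants - sum(alloc[-length(alloc)])
  pos_list <- lapply(seq_along(chroms), function(i) {
    sort(sample.int(cfg$chrom_lengths[i], alloc[i], replace = FALSE))
  })
  variants <- data.frame(
    chrom = rep(chroms, times = vapply(pos_list, length, integer(1))),
    pos = as.numeric(unlist(pos_list)),
    stringsAsFactors = FALSE
  )

  # planted leads: rejection-sampled to respect > 2 * flank spacing
  if (!is.null(cfg$lead_positions)) {
    truth <- cfg$lead_positions
    .check_lead_spacing(truth, cfg$flank)
  } else if (cfg$n_causal_loci > 0L) {
    set.seed(seeds[["leads"]])
    truth <- NULL
    for (attempt in seq_len(1000L)) {
      chr_draw <- sample(chroms, cfg$n_causal_loci, replace = TRUE,
                         prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
      pos_draw <- vapply(chr_draw, function(chr) {
        len <- cfg$chrom_lengths[[chr]]
        cfg$flank + sample.int(max(1L, as.integer(len - 2 * cfg$flank)), 1L)
      }, numeric(1))
      cand <- data.frame(chrom = chr_draw, pos = pos_draw,
                         stringsAsFactors = FALSE)
      ok <- tryCatch({.check_lead_spacing(cand, cfg$flank); TRUE},
                     error = function(e) FALSE)
      if (ok) { truth <- cand; break }
    }
    if (is.null(truth)) {
      stop("could not place ", cfg$n_causal_loci, " planted leads more ",
           "than 2 * flank apart; enlarge the genome", call. = FALSE)
    }
    truth <- .order_by_position(truth)
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(chrom = character(0), pos = numeric(0))
  }

  # shared signal component: distance to nearest planted lead
  mu <- rep(0, nrow(variants))
  if (nrow(truth) > 0L) {
    for (i in seq_len(nrow(truth))) {
      same <- variants$chrom == truth$chrom[i]
      d <- abs(variants$pos - truth$pos[i])
      hit <- same & d <= 3 * cfg$decay_bp
      mu[hit] <- pmax(mu[hit], cfg$effect_scale * exp(-d[hit] / cfg$decay_bp))
    }
  }

  make_wave <- function(noise_seed, n_wave) {
    set.seed(noise_seed)
    z <- mu * sqrt(n_wave / cfg$n1) + stats::rnorm(nrow(variants))
    p <- 2 * stats::pnorm(-abs(z))
    df <- data.frame(
      chrom = variants$chrom, pos = variants$pos,
      rsid = sprintf("rs%d", seq_len(nrow(variants))),
      a1 = "A", a2 = "G", freq = 0.5, effect = z, pvalue = p,
      stringsAsFactors = FALSE
    )
    truncate_pvalues(df)
  }
  list(
    wave1 = make_wave(seeds[["noise1"]], cfg$n1),
    wave2 = make_wave(seeds[["noise2"]], cfg$n2),
    truth = truth
  )
}

#' Construct a nomination set of controlled composition
#'
#' Builds a variant-level nomination set whose locus-level classification
#' against `gold_loci` is exactly `TP = n_tp`, `FP = n_fp`,
#' `FN = |gold| - n_tp` by construction: `n_tp` points are placed at the
#' leads (or midpoints) of distinct gold loci whose windows cannot merge,
#' and `n_fp` decoy points are rejection-sampled so their windows overlap
#' no gold or avoided locus by `min_overlap` or more and stay clear of each
#' other. The construction is verified internally with
#' [classify_locus_level()] and errors if the genome is too crowded.
#'
#' @param gold_loci Locus data frame (the gold standard, post-exclusion).
#' @param n_tp,n_fp Planted true-positive and false-positive counts.
#' @param cfg A [sim_config()] supplying `chrom_lengths`, `flank`, `seed`.
#' @param avoid_loci Optional additional loci (e.g. earlier-wave hits) that
#'   decoys must stay clear of.
#' @param min_overlap Overlap rule the construction must satisfy
#'   (default 250000).
#' @param method Method name for the returned set.
#' @return A [nomination_set()] at variant level.
#' @export
make_nominations <- function(gold_loci, n_tp, n_fp, cfg = sim_config(),
                             avoid_loci = NULL, min_overlap = 250000,
                             method = "synthetic") {
  stopifnot(n_tp >= 0, n_fp >= 0, n_tp <= nrow(gold_loci))
  set.seed(cfg$seed)
  flank <- cfg$flank

  tp_points <- data.frame(chrom = character(0), pos = numeric(0))
  if (n_tp > 0L) {
    anchor <- ifelse(is.na(gold_loci$lead_pos),
                     floor((gold_loci$start + gold_loci$end) / 2),
                     gold_loci$lead_pos)
    cand <- data.frame(chrom = gold_loci$chrom, pos = anchor,
                       stringsAsFactors = FALSE)
    # greedily keep anchors whose windows cannot merge or cross-cover
    chosen <- integer(0)
    for (i in sample.int(nrow(cand))) {
      ok <- all(vapply(chosen, function(j) {
        cand$chrom[i] != cand$chrom[j] ||
          abs(cand$pos[i] - cand$pos[j]) > 2 * flank
      }, logical(1)))
      if (ok) chosen <- c(chosen, i)
      if (length(chosen) == n_tp) break
    }
    if (length(chosen) < n_tp) {
      stop("could not select ", n_tp, " gold loci with non-merging windows",
           call. = FALSE)
    }
    tp_points <- cand[chosen, , drop = FALSE]
  }

  avoid <- rbind(gold_loci[, c("chrom", "start", "end")],
                 if (!is.null(avoid_loci)) avoid_loci[, c("chrom", "start", "end")])
  fp_points <- data.frame(chrom = character(0), pos = numeric(0))
  if (n_fp > 0L) {
    placed <- list()
    tries <- 0L
    while (length(placed) < n_fp && tries < 10000L) {
      tries <- tries + 1L
      chr <- sample(names(cfg$chrom_lengths), 1L,
                    prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
      pos <- sample.int(cfg$chrom_lengths[[chr]], 1L)
      win <- data.frame(chrom = chr, pos - flank, pos + flank)
      names(win) <- c("chrom", "start", "end")
      clear_avoid <- nrow(avoid) == 0L ||
        .max_overlap(win, avoid) < min_overlap
      clear_tp <- nrow(tp_points) == 0L ||
        all(tp_points$chrom != chr | abs(tp_points$pos - pos) > 2 * flank)
      clear_fp <- length(placed) == 0L ||
        all(vapply(placed, function(q) {
          q$chrom != chr || abs(q$pos - pos) > 2 * flank
        }, logical(1)))
      if (clear_avoid && clear_tp && clear_fp) {
        placed[[length(placed) + 1L]] <- list(chrom = chr, pos = pos)
      }
    }
    if (length(placed) < n_fp) {
      stop("could not place ", n_fp, " decoy nominations; genome too small",
           call. = FALSE)
    }
    fp_points <- data.frame(
      chrom = vapply(placed, `[[`, character(1), "chrom"),
      pos = vapply(placed, `[[`, numeric(1), "pos"),
      stringsAsFactors = FALSE
    )
  }

  points <- .order_by_position(rbind(tp_points, fp_points))
  rownames(points) <- NULL
  out <- nomination_set(method, "variant", points)

  # the construction contract: classification must recover the plan exactly
  check <- classify_locus_level(
    windows_from_points(points, flank), gold_loci,
    eval_config(flank = flank, min_overlap_locus = min_overlap)
  )
  if (check$tp_nominated != n_tp || check$fp != n_fp ||
      check$gold_covered != n_tp) {
    stop("infeasible nomination placement (planted counts not recovered)",
         call. = FALSE)
  }
  out
}

#' Simulate a variant annotation table
#'
#' Draws one of the four impact categories per variant and flags a fraction
#' of variants as eSNPs; eSNP eQTL p-values are uniform on the log10 scale
#' in `[-20, -4]` (a left-skewed distribution typical of curated
#' significant-eQTL sets).
#'
#' @param records Variant-record data frame.
#' @param esnp_fraction Probability a variant is an eSNP, in (0, 1).
#' @param impact_probs Length-4 probability vector over
#'   `(loss_of_function, moderate, low, other)`; must sum to 1.
#' @param seed RNG seed.
#' @return Data frame with `chrom`, `pos`, `impact_category`, `is_esnp`,
#'   `eqtl_pvalue` (`NA` for non-eSNPs).
#' @export
simulate_annotations <- function(records, esnp_fraction = 0.1,
                                 impact_probs = c(0.002, 0.03, 0.12, 0.848),
                                 seed = 1) {
  if (length(impact_probs) != 4L || any(impact_probs < 0) ||
      abs(sum(impact_probs) - 1) > 1e-8) {
    stop("impact_probs must be a 4-vector of probabilities summing to 1",
         call. = FALSE)
  }
  stopifnot(esnp_fraction > 0, esnp_fraction < 1)
  set.seed(seed)
  n <- nrow(records)
  categories <- c("loss_of_function", "moderate", "low", "other")
  impact <- sample(categories, n, replace = TRUE, prob = impact_probs)
  is_esnp <- stats::runif(n) < esnp_fraction
  eqtl_p <- rep(NA_real_, n)
  eqtl_p[is_esnp] <- 10^stats::runif(sum(is_esnp), -20, -4)
  data.frame(chrom = records$chrom, pos = records$pos,
             impact_category = impact, is_esnp = is_esnp,
             eqtl_pvalue = eqtl_p, stringsAsFactors = FALSE)
}

#' Simulate a gene score table
#'
#' Places genes uniformly (lengths 5-200 kb, overlap permitted so the
#' gene-locus merge rule is exercised) and plants
#' `round(sig_fraction * n_genes)` genes with p-values safely below the
#' eventual Bonferroni threshold `0.05 / n_genes`; the rest draw uniform
#' p-values.
#'
#' @param cfg A [sim_config()] (supplies `chrom_lengths`).
#' @param n_genes Number of genes.
#' @param sig_fraction Fraction of genes planted significant.
#' @param seed RNG seed.
#' @return Gene-record data frame with `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`, `midpoint`, `pvalue`, and logical `planted_sig`.
#' @export
simulate_gene_table <- function(cfg = sim_config(), n_genes = 200,
                                sig_fraction = 0.1, seed = 1) {
  set.seed(seed)
  chroms <- names(cfg$chrom_lengths)
  chr <- sample(chroms, n_genes, replace = TRUE,
                prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
  len <- round(stats::runif(n_genes, 5000, 200000))
  start <- vapply(seq_len(n_genes), function(i) {
    sample.int(max(1L, as.integer(cfg$chrom_lengths[[chr[i]]] - len[i])), 1L)
  }, numeric(1))
  n_sig <- round(sig_fraction * n_genes)
  planted <- seq_len(n_genes) %in% sample.int(n_genes, n_sig)
  pvalue <- stats::runif(n_genes)
  pvalue[planted] <- stats::runif(n_sig, 0, 0.1 * 0.05 / n_genes)
  out <- data.frame(
    gene_id = sprintf("ENSG%08d", seq_len(n_genes)),
    symbol = sprintf("GENE%d", seq_len(n_genes)),
    chrom = chr, start = start, end = start + len - 1,
    pvalue = pvalue, planted_sig = planted,
    stringsAsFactors = FALSE
  )
  out$midpoint <- gene_midpoint(out)
  out <- out[order(.chrom_key(out$chrom), out$start), c("gene_id", "symbol",
                                                        "chrom", "start",
                                                        "end", "midpoint",
                                                        "pvalue",
                                                        "planted_sig")]
  rownames(out) <- NULL
  out
}
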