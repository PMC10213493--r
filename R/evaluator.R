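# Evaluation metrics: call rates against truth, masked-call concordance,
# recombination-segment statistics, and segregation distortion.

#' Call-rate metrics against a truth matrix
#'
#' Per offspring: the fractions of markers called correctly, called
#' incorrectly, and missing (`correct + miscall + missing = 1`), plus the
#' accuracy (correct over nonmissing; `NA` when everything is missing).
#'
#' @param est markers x samples matrix of estimated genotypes (0/1/2, `NA`
#'   missing).
#' @param truth matrix of the same dimensions with true genotypes.
#' @return list with `per_sample` (data frame of rates) and `mean`/`sd`
#'   summaries.
#' @export
call_metrics <- function(est, truth) {
  if (!identical(dim(est), dim(truth)))
    stop("estimate and truth dimensions differ", call. = FALSE)
  M <- nrow(est)
  miss <- colSums(is.na(est)) / M
  correct <- colSums(!is.na(est) & est == truth) / M
  miscall <- 1 - miss - correct
  acc <- ifelse(miss < 1, correct / (correct + miscall), NA_real_)
  per <- data.frame(sample = colnames(est) %||% seq_len(ncol(est)),
                    correct = correct, miscall = miscall, missing = miss,
                    accuracy = acc)
  list(per_sample = per,
       mean = vapply(per[, c("correct", "miscall", "missing", "accuracy")],
                     mean, 0, na.rm = TRUE),
       sd = vapply(per[, c("correct", "miscall", "missing", "accuracy")],
                   stats::sd, 0, na.rm = TRUE))
}

#' Naive read-based genotype calls
#'
#' The raw GBS call: homozygous when only one allele is observed,
#' heterozygous when both are, missing with no reads.
#'
#' @param ds an [hc_dataset].
#' @return markers x samples integer matrix with `NA` for no reads.
#' @export
naive_calls <- function(ds) {
  g <- matrix(NA_integer_, ds$n_markers, length(ds$samples))
  g[ds$y_ref > 0 & ds$y_alt == 0] <- 0L
  g[ds$y_ref > 0 & ds$y_alt > 0] <- 1L
  g[ds$y_ref == 0 & ds$y_alt > 0] <- 2L
  dimnames(g) <- dimnames(ds$y_ref)
  g
}

#' Masked-call concordance
#'
#' Emulates the reliability check used on real data: select offspring calls
#' supported by more than `depth_gt` reads at markers with a missing rate
#' below `miss_lt` and a minor allele frequency above `maf_gt` (both
#' computed from the naive read-based calls), zero those calls' reads, run
#' the estimator on the masked data, and report the fraction of masked cells
#' where the estimated genotype matches the pre-mask naive call. Cells the
#' estimator leaves missing count as discordant and are also reported
#' separately.
#'
#' @param ds an [hc_dataset].
#' @param est_fn closure taking a (masked) dataset and returning an
#'   `hc_estimate` (e.g. `function(d) run_ipo(d, design)$estimate`).
#' @param depth_gt mask calls with strictly more reads than this; default 6.
#' @param miss_lt marker missing-rate upper bound; default 0.20.
#' @param maf_gt marker minor-allele-frequency lower bound; default 0.40.
#' @return list with `concordance`, `n_masked`, `n_missing` (estimator-missing
#'   masked cells) per chromosome.
#' @export
mask_and_concordance <- function(ds, est_fn, depth_gt = 6, miss_lt = 0.20,
                                 maf_gt = 0.40) {
  oc <- offspring_cols(ds)
  naive <- naive_calls(ds)[, oc, drop = FALSE]
  miss_rate <- rowMeans(is.na(naive))
  af <- rowMeans(naive / 2, na.rm = TRUE)
  maf <- pmin(af, 1 - af)
  marker_ok <- miss_rate < miss_lt & !is.na(maf) & maf > maf_gt
  depth <- (ds$y_ref + ds$y_alt)[, oc, drop = FALSE]
  mask <- depth > depth_gt & marker_ok & !is.na(naive)
  if (!any(mask)) {
    message("mask_and_concordance: no eligible calls")
    return(list(concordance = NA_real_, n_masked = 0L, n_missing = 0L))
  }
  y_ref <- ds$y_ref
  y_alt <- ds$y_alt
  y_ref[, oc][mask] <- 0L
  y_alt[, oc][mask] <- 0L
  masked_ds <- hc_dataset(ds$marker_ids, ds$chrom, ds$pos, ds$ref, ds$alt,
                          y_ref, y_alt, ds$samples, ds$roles)
  est <- est_fn(masked_ds)
  eg <- est$offspring_geno
  per_chrom <- vapply(unique(ds$chrom), function(cc) {
    sel <- mask & (ds$chrom == cc)
    n <- sum(sel)
    conc <- sum(!is.na(eg[sel]) & eg[sel] == naive[sel]) / n
    c(concordance = conc, n_masked = n, n_missing = sum(is.na(eg[sel])))
  }, c(concordance = 0, n_masked = 0, n_missing = 0))
  list(concordance = unname(per_chrom["concordance", ]),
       n_masked = unname(as.integer(per_chrom["n_masked", ])),
       n_missing = unname(as.integer(per_chrom["n_missing", ])),
       chrom = unique(ds$chrom))
}

#' Recombination breakpoints, segments, and double crossovers
#'
#' Scans each offspring's nonmissing calls along the chromosome; a genotype
#' switch between adjacent nonmissing markers places a breakpoint at their
#' physical midpoint. Segments are the stretches between breakpoints
#' (terminal segments, bounded by the first and last nonmissing markers,
#' are included). Double crossovers are heterozygous segments flanked on
#' both sides by the same homozygous genotype. Segment and double-crossover
#' counts are tabulated in the 0-1 Mb and 1-2 Mb length bins.
#'
#' @param est markers x samples genotype matrix (`NA` missing).
#' @param pos increasing physical positions (bp).
#' @return list with `n_breakpoints` (per sample), `segments` (data frame:
#'   sample, start, end, length_bp, genotype), `seg_bins` and `dxo_bins`
#'   (counts in the two length bins), `n_double_crossovers`.
#' @export
breakpoints_and_segments <- function(est, pos) {
  stopifnot(nrow(est) == length(pos), !is.unsorted(pos, strictly = TRUE))
  segs <- vector("list", ncol(est))
  nbp <- integer(ncol(est))
  ndxo <- 0L
  for (i in seq_len(ncol(est))) {
    g <- est[, i]
    ok <- which(!is.na(g))
    if (length(ok) == 0L) {
      segs[[i]] <- data.frame(sample = integer(0), start = numeric(0),
                              end = numeric(0), genotype = integer(0))
      next
    }
    gg <- g[ok]
    pp <- pos[ok]
    switch_at <- which(diff(gg) != 0)
    bp <- (pp[switch_at] + pp[switch_at + 1L]) / 2
    nbp[i] <- length(bp)
    bounds <- c(pp[1L], bp, pp[length(pp)])
    seg_geno <- gg[c(switch_at, length(gg))]
    segs[[i]] <- data.frame(sample = i,
                            start = bounds[-length(bounds)],
                            end = bounds[-1L],
                            genotype = seg_geno)
  }
  segdf <- do.call(rbind, segs)
  segdf$length_bp <- segdf$end - segdf$start
  bin_of <- function(len) ifelse(len <= 1e6, "0-1Mb",
                                 ifelse(len <= 2e6, "1-2Mb", ">2Mb"))
  seg_bins <- c(`0-1Mb` = sum(segdf$length_bp <= 1e6),
                `1-2Mb` = sum(segdf$length_bp > 1e6 & segdf$length_bp <= 2e6))
  # double crossovers: het segment flanked by the same homozygous genotype
  dxo <- logical(nrow(segdf))
  if (nrow(segdf) > 0L) {
    for (r in seq_len(nrow(segdf))) {
      if (segdf$genotype[r] != 1L) next
      if (r == 1L || r == nrow(segdf)) next
      same_sample <- segdf$sample[r - 1L] == segdf$sample[r] &&
        segdf$sample[r + 1L] == segdf$sample[r]
      if (!same_sample) next
      gL <- segdf$genotype[r - 1L]
      gR <- segdf$genotype[r + 1L]
      dxo[r] <- gL == gR && gL %in% c(0L, 2L)
    }
  }
  dxo_len <- segdf$length_bp[dxo]
  dxo_bins <- c(`0-1Mb` = sum(dxo_len <= 1e6),
                `1-2Mb` = sum(dxo_len > 1e6 & dxo_len <= 2e6))
  list(n_breakpoints = nbp, segments = segdf, seg_bins = seg_bins,
       dxo_bins = dxo_bins, n_double_crossovers = sum(dxo),
       bin_of = bin_of)
}

#' Segregation distortion levels
#'
#' Per marker, the chi-square statistic against the 1:2:1 F2 expectation
#' over the `n` nonmissing calls, divided by `n`; markers with no calls
#' contribute 0. The chromosome-level distortion is the sum over its
#' markers.
#'
#' @param est markers x samples genotype matrix (`NA` missing).
#' @param chrom optional chromosome label per marker (single chromosome
#'   assumed when omitted).
#' @return list with `per_marker` distortion levels and `per_chrom` sums.
#' @export
segregation_distortion <- function(est, chrom = NULL) {
  counts <- cbind(rowSums(est == 0L, na.rm = TRUE),
                  rowSums(est == 1L, na.rm = TRUE),
                  rowSums(est == 2L, na.rm = TRUE))
  n <- rowSums(counts)
  expd <- cbind(n / 4, n / 2, n / 4)
  chi <- rowSums((counts - expd)^2 / expd)
  level <- ifelse(n > 0, chi / pmax(n, 1), 0)
  level[!is.finite(level)] <- 0
  if (is.null(chrom)) chrom <- rep("chr", nrow(est))
  list(per_marker = level,
       per_chrom = tapply(level, chrom, sum))
}

#' Expected double crossovers in a window under a Poisson crossover model
#'
#' With crossovers as a Poisson process along the genetic map, the
#' probability of two or more crossovers within a window of `d` Morgans is
#' `1 - exp(-d) * (1 + d)`; at 4 cM/Mb a 1-Mb window gives about 0.08%.
#'
#' @param map_cM_per_Mb genetic map density in cM per Mb; default 4.
#' @param window_Mb window size in Mb; default 1.
#' @param gametes number of gametes observed.
#' @return list with `probability` (per gamete per window) and
#'   `expectation` (`gametes * probability`).
#' @export
expected_double_crossovers <- function(map_cM_per_Mb = 4, window_Mb = 1,
                                       gametes = 1) {
  stopifnot(map_cM_per_Mb > 0, window_Mb >= 0, gametes >= 0)
  d <- map_cM_per_Mb / 100 * window_Mb
  p <- 1 - exp(-d) * (1 + d)
  list(probability = p, expectation = gametes * p)
}
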