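# Crossing-population simulator: true haplotypes and genotypes for the three
# supported designs, and read counts with marker-specific allele read bias
# and mismapping.

#' Simulation configuration
#'
#' Defaults emulate a single 50-Mb chromosome of genetic length 2 Morgans
#' carrying 620 evenly spaced markers, offspring sequenced at a chosen depth
#' and founders at 5x. A fraction of markers is error-prone: biased markers
#' draw their true alternative-read probability `w` from a heavy-tailed
#' Beta(0.3, 0.3) (mass near 0 and 1), mismap-prone markers draw their
#' mismap rates uniformly from `[0.05, 0.3]`.
#'
#' @param scenario `"homoP2_F2"`, `"hetP2_F1"` or `"homoP8_RIL"`.
#' @param n_offspring number of offspring to simulate.
#' @param n_markers number of markers; default 620.
#' @param chrom_len_bp physical chromosome length; default 50e6.
#' @param chrom_len_morgan genetic length in Morgans; default 2.
#' @param offspring_depth expected read depth per offspring cell.
#' @param founder_depth expected read depth per founder cell; default 5.
#' @param nonzero if `TRUE` (default) every founder cell is guaranteed at
#'   least one read of a true allele, mimicking the usual pipeline filter
#'   that discards markers unobserved in a founder.
#' @param bias_fraction fraction of markers that are bias-prone; default 0.3.
#' @param bias_shape two Beta shape parameters for the true `w` at
#'   bias-prone markers; default `c(0.3, 0.3)`.
#' @param mismap_fraction fraction of mismap-prone markers; default 0.1.
#' @param mismap_range range for uniform mismap rates; default
#'   `c(0.05, 0.3)`.
#' @param ril_selfing_gens selfing generations after the 8-way funnel cross
#'   for `"homoP8_RIL"`; default 5 (F1 selfed to F6).
#' @param seed optional integer seed recorded in the config and set before
#'   simulation.
#' @return list of class `hc_simconfig`.
#' @export
sim_config <- function(scenario = c("homoP2_F2", "hetP2_F1", "homoP8_RIL"),
                       n_offspring = 100, n_markers = 620,
                       chrom_len_bp = 50e6, chrom_len_morgan = 2,
                       offspring_depth = 3, founder_depth = 5,
                       nonzero = TRUE,
                       bias_fraction = 0.3, bias_shape = c(0.3, 0.3),
                       mismap_fraction = 0.1, mismap_range = c(0.05, 0.3),
                       ril_selfing_gens = 5, seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(n_offspring >= 1, n_markers >= 2, offspring_depth > 0,
            founder_depth > 0, bias_fraction >= 0, bias_fraction <= 1,
            mismap_fraction >= 0, mismap_fraction <= 1)
  structure(as.list(environment()), class = "hc_simconfig")
}

# one meiosis: parent is a list of two ancestry vectors over markers;
# gpos: genetic positions (Morgan); returns the gamete ancestry vector with
# crossover positions as an attribute
.gamete <- function(parent, gpos, L) {
  nco <- stats::rpois(1L, L)
  xo <- sort(stats::runif(nco, 0, L))
  hom <- (sample.int(2L, 1L) + findInterval(gpos, xo)) %% 2L + 1L
  g <- ifelse(hom == 1L, parent[[1L]], parent[[2L]])
  attr(g, "crossovers") <- xo
  g
}

#' Simulate true genotypes for a crossing population
#'
#' Founder alleles are assigned per scenario (opposite homozygotes for the
#' biparental inbred cross; random segregating assignments for the outbred
#' and 8-way designs), gametes carry Poisson(`chrom_len_morgan`) crossovers
#' placed uniformly on the genetic map (no interference), and the pedigree
#' is: F2 = one selfing of the F1; outbred F1 = direct cross of the two
#' founders; 8-way RIL = three rounds of pairwise funnel crossing followed
#' by five generations of selfing (to F6).
#'
#' True per-marker bias and mismap parameters are drawn here as well, so a
#' truth object fully determines the read simulation.
#'
#' @param cfg an `hc_simconfig`.
#' @return list of class `hc_simtruth`: marker map (`pos`, `gpos`),
#'   ancestral haplotype alleles (`anc_allele`, K x M), founder phased
#'   genotypes (`founder_phased`, M x Nf x 2), offspring ancestry
#'   (`hap1`, `hap2`, M x N), true genotypes (`founder_geno`,
#'   `offspring_geno`), true parameters (`w`, `e_ref`, `e_alt`), and
#'   crossover positions of the final-generation gametes (`crossovers`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "hc_simconfig"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  M <- cfg$n_markers
  L <- cfg$chrom_len_morgan
  pos <- round(seq(1, cfg$chrom_len_bp, length.out = M))
  gpos <- pos / cfg$chrom_len_bp * L
  design <- mating_design(cfg$scenario)
  K <- design$K
  nf <- design$n_founders

  # ancestral haplotype alleles per marker, every marker segregating
  anc <- switch(cfg$scenario,
    homoP2_F2 = rbind(rep(0L, M), rep(1L, M)),
    hetP2_F1 = ,
    homoP8_RIL = {
      a <- matrix(0L, K, M)
      for (m in seq_len(M)) {
        repeat {
          v <- stats::rbinom(K, 1L, 0.5)
          if (any(v == 0L) && any(v == 1L)) break
        }
        a[, m] <- v
      }
      a
    })

  founder_phased <- array(0L, c(M, nf, 2L))
  for (j in seq_len(nf)) {
    if (design$inbred) {
      founder_phased[, j, 1L] <- anc[j, ]
      founder_phased[, j, 2L] <- anc[j, ]
    } else {
      founder_phased[, j, 1L] <- anc[2L * j - 1L, ]
      founder_phased[, j, 2L] <- anc[2L * j, ]
    }
  }

  n <- cfg$n_offspring
  hap1 <- matrix(0L, M, n)
  hap2 <- matrix(0L, M, n)
  crossovers <- vector("list", n)
  const <- function(k) rep.int(as.integer(k), M)

  for (i in seq_len(n)) {
    pair <- switch(cfg$scenario,
      homoP2_F2 = {
        f1 <- list(const(1L), const(2L))
        list(.gamete(f1, gpos, L), .gamete(f1, gpos, L))
      },
      hetP2_F1 = {
        p1 <- list(const(1L), const(2L))
        p2 <- list(const(3L), const(4L))
        list(.gamete(p1, gpos, L), .gamete(p2, gpos, L))
      },
      homoP8_RIL = {
        hyb <- lapply(c(1L, 3L, 5L, 7L),
                      function(k) list(const(k), const(k + 1L)))
        h12 <- list(.gamete(hyb[[1L]], gpos, L), .gamete(hyb[[2L]], gpos, L))
        h34 <- list(.gamete(hyb[[3L]], gpos, L), .gamete(hyb[[4L]], gpos, L))
        ind <- list(.gamete(h12, gpos, L), .gamete(h34, gpos, L))
        for (gen in seq_len(cfg$ril_selfing_gens))  # default: F1 selfed to F6
          ind <- list(.gamete(ind, gpos, L), .gamete(ind, gpos, L))
        ind
      })
    hap1[, i] <- pair[[1L]]
    hap2[, i] <- pair[[2L]]
    crossovers[[i]] <- list(attr(pair[[1L]], "crossovers"),
                            attr(pair[[2L]], "crossovers"))
  }

  allele_of <- function(hap) anc[cbind(as.vector(hap), rep(seq_len(M),
                                                           ncol(hap)))]
  offspring_geno <- matrix(allele_of(hap1) + allele_of(hap2), M, n)
  founder_geno <- founder_phased[, , 1L] + founder_phased[, , 2L]

  w <- rep(0.5, M)
  e_ref <- rep(0, M)
  e_alt <- rep(0, M)
  if (cfg$bias_fraction > 0) {
    nb <- round(cfg$bias_fraction * M)
    bm <- sample.int(M, nb)
    w[bm] <- stats::rbeta(nb, cfg$bias_shape[1L], cfg$bias_shape[2L])
  }
  if (cfg$mismap_fraction > 0) {
    nm <- round(cfg$mismap_fraction * M)
    mm <- sample.int(M, nm)
    e_ref[mm] <- stats::runif(nm, cfg$mismap_range[1L], cfg$mismap_range[2L])
    e_alt[mm] <- stats::runif(nm, cfg$mismap_range[1L], cfg$mismap_range[2L])
  }

  structure(list(cfg = cfg, design = design, pos = pos, gpos = gpos,
                 anc_allele = anc, founder_phased = founder_phased,
                 founder_geno = founder_geno,
                 hap1 = hap1, hap2 = hap2, offspring_geno = offspring_geno,
                 w = w, e_ref = e_ref, e_alt = e_alt,
                 crossovers = crossovers),
            class = "hc_simtruth")
}

#' Simulate read counts from a truth object
#'
#' Reads are emitted per allele copy: at a marker with bias `w`, each
#' reference allele copy yields `Poisson(depth * (1 - w))` reference reads
#' and each alternative copy `Poisson(depth * w)` alternative reads, so that
#' an unbiased marker produces `Poisson(depth)` total reads at any genotype
#' and the alternative-read fraction at a heterozygote is `w`. This models
#' allele-specific amplification efficiency: the disfavored allele's
#' homozygotes are also under-covered, which is what makes the bias
#' estimable from homozygote coverage. Mismapping then flips each read to
#' the opposite allele with the marker's rate. Under `nonzero`, every
#' founder cell receives one guaranteed true-allele read plus
#' `Poisson(max(rate - 1, 0))` extras.
#'
#' @param truth an `hc_simtruth` from [simulate_genotypes()].
#' @param cfg the `hc_simconfig` (defaults to `truth$cfg`).
#' @return An [hc_dataset] with founders first, named `F1..Fnf`,
#'   `O1..On`.
#' @export
simulate_reads <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "hc_simtruth"))
  M <- cfg$n_markers
  nf <- truth$design$n_founders
  n <- cfg$n_offspring

  draw_cell_rates <- function(geno, depth) {
    cr <- 2 - geno          # reference allele copies, M x N
    ca <- geno
    rr <- depth * (1 - truth$w) * cr   # w recycles down rows
    ra <- depth * truth$w * ca
    list(rr = rr, ra = ra)
  }

  sample_reads <- function(rates, guarantee) {
    rr <- rates$rr
    ra <- rates$ra
    if (!guarantee) {
      yr <- matrix(stats::rpois(length(rr), rr), nrow(rr))
      ya <- matrix(stats::rpois(length(ra), ra), nrow(ra))
    } else {
      tot <- rr + ra
      pref <- ifelse(tot > 0, rr / pmax(tot, .Machine$double.eps), 0.5)
      # cells with a zero total rate get their guaranteed read assigned from
      # the true genotype after mismapping (see caller)
      first <- as.integer(tot > 0)
      first_ref <- stats::rbinom(length(tot), 1L, pref) * first
      extra <- stats::rpois(length(tot), pmax(tot - 1, 0))
      extra_ref <- stats::rbinom(length(tot), extra, pref)
      yr <- matrix(first_ref + extra_ref, nrow(rr))
      ya <- matrix((first - first_ref) + (extra - extra_ref), nrow(rr))
    }
    list(yr = yr, ya = ya)
  }

  apply_mismap <- function(reads) {
    er <- truth$e_ref
    ea <- truth$e_alt
    fl_ra <- matrix(stats::rbinom(length(reads$yr), reads$yr,
                                  rep(er, ncol(reads$yr))), nrow(reads$yr))
    fl_ar <- matrix(stats::rbinom(length(reads$ya), reads$ya,
                                  rep(ea, ncol(reads$ya))), nrow(reads$ya))
    list(yr = reads$yr - fl_ra + fl_ar, ya = reads$ya - fl_ar + fl_ra)
  }

  fr <- sample_reads(draw_cell_rates(truth$founder_geno, cfg$founder_depth),
                     guarantee = isTRUE(cfg$nonzero))
  orr <- sample_reads(draw_cell_rates(truth$offspring_geno,
                                      cfg$offspring_depth),
                      guarantee = FALSE)
  fr <- apply_mismap(fr)
  orr <- apply_mismap(orr)

  # degenerate founder cells under nonzero: extreme w can zero both rates;
  # the guaranteed read is then a true-allele read
  if (isTRUE(cfg$nonzero)) {
    zero <- (fr$yr + fr$ya) == 0
    if (any(zero)) {
      idx <- which(zero, arr.ind = TRUE)
      g <- truth$founder_geno[idx]
      ref_first <- ifelse(g == 0, TRUE, ifelse(g == 2, FALSE,
                                               stats::runif(length(g)) < 0.5))
      fr$yr[idx[ref_first, , drop = FALSE]] <- 1L
      fr$ya[idx[!ref_first, , drop = FALSE]] <- 1L
    }
  }

  samples <- c(paste0("F", seq_len(nf)), paste0("O", seq_len(n)))
  roles <- c(rep("founder", nf), rep("offspring", n))
  hc_dataset(paste0("M", seq_len(M)), rep("chr1", M), truth$pos,
             rep("A", M), rep("T", M),
             cbind(fr$yr, orr$yr), cbind(fr$ya, orr$ya),
             samples, roles)
}

#' Simulate a complete crossing-population dataset
#'
#' Convenience wrapper: [sim_config()] + [simulate_genotypes()] +
#' [simulate_reads()].
#'
#' @param ... passed to [sim_config()].
#' @return list with `truth` (`hc_simtruth`) and `ds` ([hc_dataset]).
#' @export
simulate_cross <- function(...) {
  cfg <- sim_config(...)
  truth <- simulate_genotypes(cfg)
  list(truth = truth, ds = simulate_reads(truth, cfg))
}

#' Write a simulated dataset and its truth files
#'
#' Writes the read counts as a VCF plus plain-text truth tables: true
#' genotypes, offspring ancestry haplotypes, and the per-marker simulation
#' parameters (with the seed recorded in the parameter file header).
#'
#' @param truth an `hc_simtruth`.
#' @param ds the matching [hc_dataset].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(truth, ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(ds, file.path(dir, "reads.vcf"))
  geno <- cbind(truth$founder_geno, truth$offspring_geno)
  colnames(geno) <- ds$samples
  utils::write.table(
    data.frame(marker = ds$marker_ids, pos = ds$pos, geno,
               check.names = FALSE),
    file.path(dir, "truth_genotypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  hap <- cbind(truth$hap1, truth$hap2)
  colnames(hap) <- c(paste0("O", seq_len(ncol(truth$hap1)), "_h1"),
                     paste0("O", seq_len(ncol(truth$hap2)), "_h2"))
  utils::write.table(
    data.frame(marker = ds$marker_ids, hap, check.names = FALSE),
    file.path(dir, "truth_haplotypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "truth_params.tsv"), "w")
  writeLines(sprintf("# scenario=%s seed=%s", truth$cfg$scenario,
                     truth$cfg$seed %||% "NA"), con)
  utils::write.table(
    data.frame(marker = ds$marker_ids, pos = ds$pos, w = truth$w,
               e_ref = truth$e_ref, e_alt = truth$e_alt),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(dir)
}
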