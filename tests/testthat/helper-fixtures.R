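# In-code fixtures and independent oracles shared across test files.

# a tiny dataset built directly from read-count matrices
tiny_dataset <- function(y_ref, y_alt, pos = NULL, n_founders = 2) {
  M <- nrow(y_ref)
  n <- ncol(y_ref)
  if (is.null(pos)) pos <- seq(1e6, by = 1e6, length.out = M)
  roles <- c(rep("founder", n_founders), rep("offspring", n - n_founders))
  hc_dataset(paste0("M", seq_len(M)), rep("chr1", M), pos,
             rep("A", M), rep("T", M), y_ref, y_alt,
             c(paste0("F", seq_len(n_founders)),
               paste0("O", seq_len(n - n_founders))), roles)
}

# a random tiny biparental instance for oracle comparisons
random_tiny_instance <- function() {
  M <- sample(1:3, 1)
  No <- sample(1:2, 1)
  pos <- sort(sample.int(5e7, M))
  while (M > 1 && any(diff(pos) == 0)) pos <- sort(sample.int(5e7, M))
  yr <- matrix(rpois((No + 2) * M, 1.5), M)
  ya <- matrix(rpois((No + 2) * M, 1.5), M)
  ds <- tiny_dataset(yr, ya, pos = pos)
  params <- model_params(M, e_seq = runif(1, 0.001, 0.02),
                         w = runif(M, 0.1, 0.9),
                         e_ref = runif(M, 0, 0.2), e_alt = runif(M, 0, 0.2))
  list(ds = ds, params = params)
}

# Exhaustive maximization of the joint probability over every founder
# sequence and every per-offspring haplotype path: the independent oracle
# for the integrated Viterbi algorithm. Feasible for M <= 3 and small K.
# With `fixed_combo`, maximizes only over haplotype paths (conditional max).
brute_force_max <- function(ds, design, params, fixed_combo = NULL) {
  space <- state_space(design)
  trans <- hapclean:::transition_set(design, ds$pos, params$Ed)
  emis <- hapclean:::build_emissions(ds, space, params)
  oc <- which(ds$roles == "offspring")
  M <- ds$n_markers
  S <- space$n_states
  C <- space$n_combos
  combos <- if (is.null(fixed_combo))
    as.matrix(expand.grid(rep(list(seq_len(C)), M))) else
      matrix(fixed_combo, 1L, M)
  haps <- as.matrix(expand.grid(rep(list(seq_len(S)), M)))

  path_score <- function(hp, cb, col) {
    s <- log(trans$pi[hp[1L]])
    for (m in seq_len(M)) {
      Pm <- hapclean:::.pm_slice(emis$pyx, m, col)
      s <- s + log(Pm[space$geno[hp[m], cb[m]] + 1L, 1L])
      if (m >= 2L) s <- s + log(trans$T[[m - 1L]][hp[m - 1L], hp[m]])
    }
    s
  }

  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    cb <- combos[r, ]
    ll <- sum(log(emis$lf[cbind(seq_len(M), cb)])) - M * log(C)
    for (col in oc) {
      besti <- -Inf
      for (hrow in seq_len(nrow(haps)))
        besti <- max(besti, path_score(haps[hrow, ], cb, col))
      ll <- ll + besti
    }
    best <- max(best, ll)
  }
  best
}

# state index from an (h1, h2) pair, matching state_space ordering
hap_state_index <- function(h1, h2, K) (h1 - 1L) * K + h2

# joint log-probability of the sequences a Viterbi pass returned
pass_log_prob <- function(ds, design, params, pass) {
  joint_log_probability(ds, design, params, pass$combo, pass$hap)
}

# write a small VCF text fixture; records are complete tab-joined lines
write_vcf_fixture <- function(path, samples, records,
                              ad_header = TRUE) {
  lines <- c(
    "##fileformat=VCFv4.3",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (ad_header)
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
  writeLines(lines, path)
  path
}
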