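# Integrated Viterbi over founder-genotype combinations and offspring
# haplotype pairs, plus forward-backward marginals and genotype calling.
#
# All dynamic programming is carried out in linear space with one scaling
# constant per offspring per marker (argmax-invariant); founder scores are
# accumulated in log space across offspring.

# slice the three P(y|x) matrices at marker m for the given sample columns
.pm_slice <- function(pyx, m, cols) {
  rbind(pyx[[1L]][m, cols], pyx[[2L]][m, cols], pyx[[3L]][m, cols],
        deparse.level = 0)
}

# core pass over markers 1..M in the order given by the inputs.
# pyx: list of three M x N matrices (all samples); lf: M x C; Ts: list of
# M-1 transition matrices; log_prior1: optional log-prior over combos at the
# first marker of this pass (point mass for the constrained reverse round).
viterbi_core <- function(pyx, lf, Ts, pi0, space, off_cols,
                         log_prior1 = NULL) {
  M <- nrow(lf)
  C <- space$n_combos
  S <- space$n_states
  No <- length(off_cols)
  lunif <- -log(C)
  if (is.null(log_prior1)) log_prior1 <- rep(lunif, C)

  geno1 <- space$geno + 1L  # S x C

  Pm <- .pm_slice(pyx, 1L, off_cols)
  V <- lapply(seq_len(C), function(cb)
    matrix(Pm[geno1[, cb], ], S, No) * pi0)
  sc <- do.call(pmax, lapply(V, function(v) apply(v, 2, max)))
  if (any(sc <= 0))
    stop("all-zero Viterbi column at marker 1; chromosome aborted",
         call. = FALSE)
  V <- lapply(V, function(v) sweep(v, 2, sc, "/"))

  psif <- matrix(NA_integer_, M, C)
  psio <- vector("list", M)

  if (M >= 2L) {
    for (m in 2:M) {
      Tm <- Ts[[m - 1L]]
      prior_prev <- if (m == 2L) log_prior1 else rep(lunif, C)
      llf_prev <- log(lf[m - 1L, ])
      ok_prev <- which(is.finite(llf_prev + prior_prev))
      if (length(ok_prev) == 0L) ok_prev <- which(is.finite(prior_prev))

      maxt <- vector("list", C)
      argm <- vector("list", C)
      for (cp in ok_prev) {
        mt <- matrix(0, S, No)
        am <- matrix(0L, S, No)
        Vp <- V[[cp]]
        for (s in seq_len(S)) {
          vals <- Vp * Tm[, s]
          rm <- rowmax_random(t(vals))
          mt[s, ] <- rm$val
          am[s, ] <- rm$idx
        }
        maxt[[cp]] <- mt
        argm[[cp]] <- am
      }

      Pm <- .pm_slice(pyx, m, off_cols)
      Lms <- lapply(seq_len(C), function(cb) matrix(Pm[geno1[, cb], ], S, No))

      vf <- matrix(-Inf, C, length(ok_prev))
      for (k in seq_along(ok_prev)) {
        cp <- ok_prev[k]
        base <- prior_prev[cp] + llf_prev[cp]
        for (cb in seq_len(C)) {
          D <- colSums(Lms[[cb]] * maxt[[cp]])
          vf[cb, k] <- base + sum(log(D))
        }
      }
      po <- array(0L, c(S, C, No))
      Vnew <- vector("list", C)
      for (cb in seq_len(C)) {
        k <- argmax_random(vf[cb, ])
        cp <- ok_prev[k]
        psif[m, cb] <- cp
        Vnew[[cb]] <- Lms[[cb]] * maxt[[cp]]
        po[, cb, ] <- argm[[cp]]
      }
      psio[[m]] <- po
      sc <- do.call(pmax, lapply(Vnew, function(v) apply(v, 2, max)))
      if (any(sc <= 0))
        stop(sprintf("all-zero Viterbi column at marker %d; chromosome aborted", m),
             call. = FALSE)
      V <- lapply(Vnew, function(v) sweep(v, 2, sc, "/"))
    }
  }

  prior_M <- if (M == 1L) log_prior1 else rep(lunif, C)
  vfin <- prior_M + log(lf[M, ]) +
    vapply(seq_len(C), function(cb) sum(log(colSums(V[[cb]]))), 0)
  vfin[!is.finite(vfin)] <- -Inf
  cM <- argmax_random(vfin)

  combo <- integer(M)
  hap <- matrix(NA_integer_, M, No)
  combo[M] <- cM
  rmM <- rowmax_random(t(V[[cM]]))
  hap[M, ] <- rmM$idx
  if (M >= 2L) {
    for (m in (M - 1L):1L) {
      combo[m] <- psif[m + 1L, combo[m + 1L]]
      hap[m, ] <- psio[[m + 1L]][cbind(hap[m + 1L, ], combo[m + 1L],
                                       seq_len(No))]
    }
  }
  list(combo = combo, hap = hap)
}

#' One Viterbi round over a chromosome
#'
#' Runs the integrated Viterbi algorithm that jointly scores offspring
#' haplotype pairs and founder-genotype combinations, in the forward
#' (marker 1 to M) or reverse (M to 1) direction. In the reverse direction
#' the marker order and inter-marker distances are reversed; a founder
#' combination can be imposed on the pass's starting marker via a point-mass
#' prior (used by [two_round_estimate()] to carry the forward round's last
#' founder estimate into the reverse round). Ties in any argmax are broken
#' uniformly at random using the session RNG.
#'
#' @param ds a single-chromosome [hc_dataset].
#' @param space an `hc_space` from [state_space()].
#' @param trans transition model from `transition_set()` (or built
#'   internally if `NULL`).
#' @param params an `hc_params`.
#' @param direction `"forward"` or `"reverse"`.
#' @param fixed_first optional founder-combination index imposed at the
#'   pass's first marker (marker M for the reverse direction).
#' @param design the `hc_design` (needed when `trans` is `NULL`).
#' @return list with `combo` (founder-combination index per marker, in
#'   original marker order) and `hap` (markers x offspring matrix of
#'   haplotype-pair state indices).
#' @export
viterbi_pass <- function(ds, space, params, trans = NULL, design = NULL,
                         direction = c("forward", "reverse"),
                         fixed_first = NULL) {
  direction <- match.arg(direction)
  if (length(unique(ds$chrom)) != 1L)
    stop("viterbi_pass operates on a single chromosome", call. = FALSE)
  if (is.null(trans)) trans <- transition_set(design, ds$pos, params$Ed)
  emis <- build_emissions(ds, space, params)
  .viterbi_dir(emis, trans, space, offspring_cols(ds), direction, fixed_first)
}

.viterbi_dir <- function(emis, trans, space, off_cols, direction,
                         fixed_first = NULL) {
  M <- nrow(emis$lf)
  lp1 <- NULL
  if (!is.null(fixed_first)) {
    lp1 <- rep(-Inf, space$n_combos)
    lp1[fixed_first] <- 0
  }
  if (direction == "forward") {
    viterbi_core(emis$pyx, emis$lf, trans$T, trans$pi, space, off_cols, lp1)
  } else {
    rev_idx <- M:1
    pyx_r <- lapply(emis$pyx, function(p) p[rev_idx, , drop = FALSE])
    lf_r <- emis$lf[rev_idx, , drop = FALSE]
    Ts_r <- rev(trans$T)  # Q is symmetric: T is its own reversal
    res <- viterbi_core(pyx_r, lf_r, Ts_r, trans$pi, space, off_cols, lp1)
    list(combo = rev(res$combo),
         hap = res$hap[rev_idx, , drop = FALSE])
  }
}

#' Two-round haplotype and founder-genotype estimation
#'
#' Runs a forward Viterbi round, then a reverse round with the forward
#' round's founder estimate at the last marker imposed, and merges the two:
#' markers `1..floor(M/2)` are taken from the reverse round (which has seen
#' the whole chromosome by the time it reaches them) and the remainder from
#' the forward round. Marginal genotype posteriors are then computed by the
#' forward-backward algorithm conditional on the merged founder genotypes,
#' and offspring genotypes are called, masking calls whose posterior falls
#' below `p_call`.
#'
#' @param ds an [hc_dataset] (any number of chromosomes; each is processed
#'   independently).
#' @param design an `hc_design`.
#' @param params an `hc_params`.
#' @return An object of class `hc_estimate`: list with
#'   `founder_phased` (markers x founders x 2 allele array),
#'   `founder_geno` (markers x founders genotype classes),
#'   `offspring_hap` (markers x offspring x 2 ancestral haplotypes),
#'   `offspring_geno_raw` (Viterbi-implied genotypes, no masking),
#'   `offspring_geno` (called genotypes, `NA` where masked),
#'   `marginal` (posterior probability of each called genotype), and
#'   `posterior` (markers x 3 x offspring genotype posterior array).
#' @export
two_round_estimate <- function(ds, design, params) {
  space <- state_space(design)
  chroms <- unique(ds$chrom)
  pieces <- lapply(chroms, function(cc) {
    dsc <- if (length(chroms) == 1L) ds else subset_chrom(ds, cc)
    .estimate_chrom(dsc, design, space, params)
  })
  out <- list(
    founder_phased = do.call(abind3, lapply(pieces, `[[`, "founder_phased")),
    founder_geno = do.call(rbind, lapply(pieces, `[[`, "founder_geno")),
    offspring_hap = do.call(abind3, lapply(pieces, `[[`, "offspring_hap")),
    offspring_geno_raw = do.call(rbind, lapply(pieces, `[[`, "offspring_geno_raw")),
    offspring_geno = do.call(rbind, lapply(pieces, `[[`, "offspring_geno")),
    marginal = do.call(rbind, lapply(pieces, `[[`, "marginal")),
    posterior = do.call(abind3, lapply(pieces, `[[`, "posterior")),
    combo = unlist(lapply(pieces, `[[`, "combo")))
  class(out) <- "hc_estimate"
  out
}

# bind 3-d arrays along the first (marker) dimension
abind3 <- function(...) {
  args <- list(...)
  if (length(args) == 1L) return(args[[1L]])
  d <- dim(args[[1L]])
  out <- array(args[[1L]][1L],
               c(sum(vapply(args, function(a) dim(a)[1L], 0L)), d[2L], d[3L]))
  at <- 0L
  for (a in args) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

.estimate_chrom <- function(ds, design, space, params) {
  M <- ds$n_markers
  trans <- transition_set(design, ds$pos, params$Ed)
  emis <- build_emissions(ds, space, params)
  oc <- offspring_cols(ds)

  fwd <- .viterbi_dir(emis, trans, space, oc, "forward")
  if (M >= 2L) {
    rev_ <- .viterbi_dir(emis, trans, space, oc, "reverse",
                         fixed_first = fwd$combo[M])
    half <- seq_len(M %/% 2L)
    combo <- fwd$combo
    hap <- fwd$hap
    combo[half] <- rev_$combo[half]
    hap[half, ] <- rev_$hap[half, , drop = FALSE]
  } else {
    combo <- fwd$combo
    hap <- fwd$hap
  }

  post <- marginal_probabilities(ds, space, params, combo,
                                 trans = trans, emis = emis)
  geno_raw <- matrix(space$geno[cbind(as.vector(hap),
                                      rep(combo, times = ncol(hap)))],
                     M, ncol(hap))
  called <- call_genotypes(post, geno_raw, params$p_call)

  list(founder_phased = space$founder_allele[, , combo, drop = FALSE] |>
         aperm(c(3L, 1L, 2L)),
       founder_geno = t(space$founder_class[, combo, drop = FALSE]),
       offspring_hap = {
         h <- array(0L, c(M, length(oc), 2L))
         h[, , 1L] <- space$h1[hap]
         h[, , 2L] <- space$h2[hap]
         h
       },
       offspring_geno_raw = geno_raw,
       offspring_geno = called$geno,
       marginal = called$marginal,
       posterior = post,
       combo = combo)
}

#' Posterior genotype probabilities given estimated founder genotypes
#'
#' Forward-backward algorithm over the haplotype-pair states of each
#' offspring, conditional on a fixed founder-genotype combination sequence.
#' The genotype posterior at a cell is the total posterior mass of the
#' haplotype pairs implying that genotype.
#'
#' @param ds a single-chromosome [hc_dataset].
#' @param space an `hc_space`.
#' @param params an `hc_params`.
#' @param combo integer vector, founder-combination index per marker.
#' @param trans,emis optional precomputed transition set and emissions.
#' @param design `hc_design`, needed when `trans` is `NULL`.
#' @return `markers x 3 x offspring` array; each `[m, , i]` sums to 1.
#' @export
marginal_probabilities <- function(ds, space, params, combo, trans = NULL,
                                   emis = NULL, design = NULL) {
  if (is.null(trans)) trans <- transition_set(design, ds$pos, params$Ed)
  if (is.null(emis)) emis <- build_emissions(ds, space, params)
  oc <- offspring_cols(ds)
  M <- ds$n_markers
  No <- length(oc)
  S <- space$n_states
  geno1 <- space$geno + 1L

  Lm <- function(m) {
    Pm <- .pm_slice(emis$pyx, m, oc)
    matrix(Pm[geno1[, combo[m]], ], S, No)
  }

  alpha <- vector("list", M)
  a <- trans$pi * Lm(1L)
  alpha[[1L]] <- sweep(a, 2, colSums(a), "/")
  if (M >= 2L) for (m in 2:M) {
    a <- crossprod(trans$T[[m - 1L]], alpha[[m - 1L]]) * Lm(m)
    cs <- colSums(a)
    if (any(cs <= 0)) stop("forward-backward underflow at marker ", m,
                           call. = FALSE)
    alpha[[m]] <- sweep(a, 2, cs, "/")
  }

  post <- array(0, c(M, 3L, No))
  b <- matrix(1, S, No)
  for (m in M:1L) {
    g <- alpha[[m]] * b
    g <- sweep(g, 2, colSums(g), "/")
    gm <- geno1[, combo[m]]
    for (x in 1:3)
      post[m, x, ] <- colSums(g[gm == x, , drop = FALSE])
    if (m >= 2L)  {
      bl <- b * Lm(m)
      b <- trans$T[[m - 1L]] %*% bl
      b <- sweep(b, 2, apply(b, 2, max), "/")
    }
  }
  post
}

#' Call genotypes with a posterior threshold
#'
#' Calls the Viterbi-implied genotype per cell and masks the call as missing
#' when its posterior probability is below `p_call`.
#'
#' @param posterior `markers x 3 x offspring` array from
#'   [marginal_probabilities()].
#' @param geno_raw markers x offspring matrix of Viterbi-implied genotypes.
#' @param p_call threshold in (0, 1]; default 0.9. `p_call = 0` masks
#'   nothing.
#' @return list with `geno` (called genotypes, `NA` where masked) and
#'   `marginal` (posterior of the called genotype).
#' @export
call_genotypes <- function(posterior, geno_raw, p_call = 0.9) {
  M <- nrow(geno_raw)
  No <- ncol(geno_raw)
  marg <- matrix(posterior[cbind(rep(seq_len(M), No),
                                 as.vector(geno_raw) + 1L,
                                 rep(seq_len(No), each = M))], M, No)
  geno <- geno_raw
  geno[marg < p_call] <- NA_integer_
  list(geno = geno, marginal = marg)
}

#' Joint log-probability of given haplotype and founder sequences
#'
#' Scores a complete assignment of founder-genotype combinations and
#' offspring haplotype-pair sequences under the model: founder emissions and
#' the uniform founder prior at every marker, plus each offspring's initial
#' distribution, transition and emission terms. Used as the objective that
#' the integrated Viterbi algorithm seeks to maximize (and, in tests, as the
#' yardstick for exhaustive enumeration).
#'
#' @param ds a single-chromosome [hc_dataset].
#' @param design an `hc_design`.
#' @param params an `hc_params`.
#' @param combo integer vector of founder-combination indices per marker.
#' @param hap markers x offspring matrix of haplotype-pair state indices.
#' @return The joint log-probability (a single number).
#' @export
joint_log_probability <- function(ds, design, params, combo, hap) {
  space <- state_space(design)
  trans <- transition_set(design, ds$pos, params$Ed)
  emis <- build_emissions(ds, space, params)
  oc <- offspring_cols(ds)
  M <- ds$n_markers
  ll <- sum(log(emis$lf[cbind(seq_len(M), combo)])) - M * log(space$n_combos)
  for (i in seq_along(oc)) {
    ll <- ll + log(trans$pi[hap[1L, i]])
    for (m in seq_len(M)) {
      Pm <- .pm_slice(emis$pyx, m, oc[i])
      ll <- ll + log(Pm[space$geno[hap[m, i], combo[m]] + 1L, 1L])
      if (m >= 2L)
        ll <- ll + log(trans$T[[m - 1L]][hap[m - 1L, i], hap[m, i]])
    }
  }
  ll
}
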