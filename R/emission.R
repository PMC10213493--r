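#' Model parameters
#'
#' Global and per-marker parameters of the observation model.
#'
#' @param n_markers number of markers M.
#' @param e_seq global sequencing-error probability in (0, 0.5); default
#'   0.0025, a typical short-read substitution rate.
#' @param Ed expected genetic distance in Morgans per megabase; default 0.04.
#' @param p_call posterior-probability threshold below which a call is
#'   reported missing; default 0.9.
#' @param w per-marker alternative-allele read probability at heterozygotes
#'   (allele read bias); 0.5 when unbiased. Scalar or length-M vector.
#' @param e_ref,e_alt per-marker mismapping rates: the probability that a
#'   homozygous reference (resp. alternative) site is observable as
#'   heterozygous because of mismapped reads. Scalar or length-M vectors;
#'   default 0.005.
#' @return An object of class `hc_params`.
#' @export
model_params <- function(n_markers, e_seq = 0.0025, Ed = 0.04, p_call = 0.9,
                         w = 0.5, e_ref = 0.005, e_alt = 0.005) {
  stopifnot_scalar_prob(e_seq, "e_seq", lo = 0, hi = 0.5,
                        lo_open = TRUE, hi_open = TRUE)
  stopifnot_scalar_prob(p_call, "p_call", lo = 0, hi = 1, lo_open = TRUE)
  if (Ed <= 0) stop("`Ed` must be > 0", call. = FALSE)
  rep_m <- function(x, name, lo, hi) {
    x <- rep_len(as.numeric(x), n_markers)
    if (any(x <= lo) || any(x >= hi))
      stop(sprintf("`%s` must lie in (%g, %g)", name, lo, hi), call. = FALSE)
    x
  }
  structure(list(n_markers = as.integer(n_markers), e_seq = e_seq, Ed = Ed,
                 p_call = p_call,
                 w = rep_m(w, "w", 0, 1),
                 e_ref = rep_m(e_ref, "e_ref", -1e-12, 1),
                 e_alt = rep_m(e_alt, "e_alt", -1e-12, 1)),
            class = "hc_params")
}

#' Mismapping probability matrix
#'
#' Probability of the observable genotype given the true genotype when reads
#' can mismap: a homozygote can be observed as a heterozygote (rate `e_ref`
#' for reference homozygotes, `e_alt` for alternative homozygotes), a true
#' heterozygote stays observable as heterozygous, and no mismapping turns a
#' homozygote into the opposite homozygote.
#'
#' @param e_ref,e_alt mismapping rates in `[0, 1)`.
#' @return A 3x3 row-stochastic matrix; rows index the true genotype
#'   (0, 1, 2), columns the observable genotype.
#' @export
mismap_matrix <- function(e_ref, e_alt) {
  stopifnot(e_ref >= 0, e_ref < 1, e_alt >= 0, e_alt < 1)
  matrix(c(1 - e_ref, e_ref,     0,
           0,         1,         0,
           0,         e_alt,     1 - e_alt),
         nrow = 3, byrow = TRUE,
         dimnames = list(true = 0:2, observable = 0:2))
}

#' Read-count likelihood over observable genotypes
#'
#' Given read counts `y = (y_ref, y_alt)`, the three observable genotypes
#' have unnormalized likelihoods
#' `(1-e_seq)^y_ref * e_seq^y_alt`, `(1-w)^y_ref * w^y_alt`, and
#' `e_seq^y_ref * (1-e_seq)^y_alt` (binomial kernels; the binomial
#' coefficient is common and omitted). If any of the three evaluates to
#' exactly 0 (including numerical underflow), 0.005 is added to all three
#' before normalizing, so that no genotype is ever ruled out absolutely by
#' over-represented reads.
#'
#' @param y_ref,y_alt nonnegative read counts (vectors are allowed and are
#'   processed elementwise).
#' @param e_seq sequencing error probability.
#' @param w alternative-read probability at a heterozygote (scalar or vector
#'   matching `y_ref`).
#' @return A matrix with 3 columns (observable genotype 0, 1, 2), one row per
#'   input element, each row summing to 1.
#' @export
read_likelihood <- function(y_ref, y_alt, e_seq, w) {
  stopifnot(all(y_ref >= 0), all(y_alt >= 0))
  p0 <- (1 - e_seq)^y_ref * e_seq^y_alt
  p1 <- (1 - w)^y_ref * w^y_alt
  p2 <- e_seq^y_ref * (1 - e_seq)^y_alt
  p <- cbind(p0, p1, p2, deparse.level = 0)
  zero <- rowSums(p == 0) > 0
  p[zero, ] <- p[zero, , drop = FALSE] + 0.005
  p / rowSums(p)
}

# mismap mixture: P(y | true genotype x) = sum_x' P(y|x') P(x'|x)
# rl: n x 3 normalized read likelihoods; e_ref, e_alt scalars or vectors
mismap_mixture <- function(rl, e_ref, e_alt) {
  cbind((1 - e_ref) * rl[, 1L] + e_ref * rl[, 2L],
        rl[, 2L],
        e_alt * rl[, 2L] + (1 - e_alt) * rl[, 3L], deparse.level = 0)
}

#' Offspring emission probabilities
#'
#' Likelihood of observing reads `y` for every hidden state, i.e. every
#' (haplotype pair, founder combination) cell of the state space. The
#' haplotype pair and the founder combination determine the offspring
#' genotype; the likelihood of that genotype is the read likelihood mixed
#' over observable genotypes with the marker's mismapping rates.
#'
#' @param y_ref,y_alt scalar read counts for one offspring at one marker.
#' @param space an `hc_space`.
#' @param params an `hc_params`.
#' @param m marker index (selects `w`, `e_ref`, `e_alt`).
#' @return A `K^2 x n_combos` matrix of likelihoods.
#' @export
offspring_emission <- function(y_ref, y_alt, space, params, m) {
  rl <- read_likelihood(y_ref, y_alt, params$e_seq, params$w[m])
  px <- mismap_mixture(rl, params$e_ref[m], params$e_alt[m])  # 1 x 3
  matrix(px[1L, space$geno + 1L], space$n_states, space$n_combos)
}

#' Founder emission probabilities
#'
#' Likelihood of the founders' reads at one marker for every founder-genotype
#' combination. Per founder, the three (two for inbred founders) genotype
#' classes get mismap-mixed read likelihoods which are normalized over that
#' founder's classes; any class probability below 0.01 is set to exactly 0 to
#' prune clearly unsupported founder genotypes. The combination likelihood is
#' the product over founders, normalized over combinations. If pruning kills
#' every combination at a marker, the marker falls back to a uniform founder
#' likelihood (no founder information).
#'
#' @param y_ref,y_alt length-`n_founders` read counts at one marker.
#' @param space an `hc_space`.
#' @param params an `hc_params`.
#' @param m marker index.
#' @param prune pruning threshold on the per-founder class probability;
#'   default 0.01.
#' @return Numeric vector over combinations, summing to 1.
#' @export
founder_emission <- function(y_ref, y_alt, space, params, m, prune = 0.01) {
  rl <- read_likelihood(y_ref, y_alt, params$e_seq, params$w[m])
  px <- mismap_mixture(rl, params$e_ref[m], params$e_alt[m])  # nf x 3
  if (space$inbred) px[, 2L] <- 0  # inbred founders cannot be heterozygous
  px <- px / rowSums(px)
  px[px < prune] <- 0
  lf <- rep(1, space$n_combos)
  for (j in seq_len(space$n_founders))
    lf <- lf * px[j, space$founder_class[j, ] + 1L]
  if (all(lf == 0)) {
    lf <- rep(1 / space$n_combos, space$n_combos)
    attr(lf, "fallback") <- TRUE
    return(lf)
  }
  lf / sum(lf)
}

# Vectorized emission tables for a whole chromosome.
# Returns:
#   pyx : list of three M x N matrices, P(y | true genotype 0/1/2) for every
#         cell (offspring and founders alike), normalized over observable
#         genotypes before mixing
#   lf  : M x n_combos founder combination likelihoods (rows sum to 1)
build_emissions <- function(ds, space, params, prune = 0.01) {
  M <- ds$n_markers
  e <- params$e_seq
  w <- params$w  # per-marker, recycles down rows (column-major)
  yr <- ds$y_ref
  ya <- ds$y_alt
  p0 <- (1 - e)^yr * e^ya
  p1 <- (1 - w)^yr * w^ya
  p2 <- e^yr * (1 - e)^ya
  zero <- (p0 == 0) | (p1 == 0) | (p2 == 0)
  p0[zero] <- p0[zero] + 0.005
  p1[zero] <- p1[zero] + 0.005
  p2[zero] <- p2[zero] + 0.005
  s <- p0 + p1 + p2
  p0 <- p0 / s; p1 <- p1 / s; p2 <- p2 / s
  er <- params$e_ref
  ea <- params$e_alt
  pyx <- list(`0` = (1 - er) * p0 + er * p1,
              `1` = p1,
              `2` = ea * p1 + (1 - ea) * p2)

  fc <- founder_cols(ds)
  f0 <- pyx[[1L]][, fc, drop = FALSE]
  f1 <- pyx[[2L]][, fc, drop = FALSE]
  f2 <- pyx[[3L]][, fc, drop = FALSE]
  if (space$inbred) f1[] <- 0
  fs <- f0 + f1 + f2
  f0 <- f0 / fs; f1 <- f1 / fs; f2 <- f2 / fs
  f0[f0 < prune] <- 0; f1[f1 < prune] <- 0; f2[f2 < prune] <- 0
  fcls <- list(f0, f1, f2)
  lf <- matrix(1, M, space$n_combos)
  for (cb in seq_len(space$n_combos))
    for (j in seq_len(space$n_founders))
      lf[, cb] <- lf[, cb] * fcls[[space$founder_class[j, cb] + 1L]][, j]
  dead <- rowSums(lf) == 0
  lf[dead, ] <- 1
  lf <- lf / rowSums(lf)
  list(pyx = pyx, lf = lf, lf_fallback = which(dead))
}
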