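#' Describe the mating design of a population
#'
#' The design fixes the number of founders, whether they are inbred, and the
#' per-Morgan ancestor-switch rate of the hidden haplotype process. The
#' number of distinct ancestral haplotypes is `K = n_founders` when all
#' founders are inbred (each founder contributes one haplotype) and
#' `K = 2 * n_founders` when outbred (each founder chromosome is its own
#' ancestor).
#'
#' @param scenario one of `"homoP2_F2"` (biparental F2 from inbred founders),
#'   `"hetP2_F1"` (F1 from two outbred founders), `"homoP8_RIL"` (8-way
#'   recombinant inbred lines), or `"custom"`.
#' @param n_founders number of founders (required for `"custom"`).
#' @param inbred logical; are the founders fully inbred? (required for
#'   `"custom"`).
#' @param rho ancestor-switch rate per Morgan for each haplotype lineage.
#'   Defaults: 1 for the biparental designs, 1.5 for the 8-way RIL (map
#'   expansion from the accumulated meioses).
#' @return An object of class `hc_design`.
#' @export
mating_design <- function(scenario = c("homoP2_F2", "hetP2_F1", "homoP8_RIL",
                                       "custom"),
                          n_founders = NULL, inbred = NULL, rho = NULL) {
  scenario <- match.arg(scenario)
  preset <- switch(scenario,
    homoP2_F2  = list(n_founders = 2L, inbred = TRUE,  rho = 1),
    hetP2_F1   = list(n_founders = 2L, inbred = FALSE, rho = 1),
    homoP8_RIL = list(n_founders = 8L, inbred = TRUE,  rho = 1.5),
    custom     = list(n_founders = n_founders, inbred = inbred, rho = rho %||% 1)
  )
  n_founders <- n_founders %||% preset$n_founders
  inbred <- inbred %||% preset$inbred
  rho <- rho %||% preset$rho
  if (is.null(n_founders) || is.null(inbred))
    stop("custom designs need `n_founders` and `inbred`", call. = FALSE)
  stopifnot(n_founders >= 2, is.logical(inbred), length(inbred) == 1L)
  if (!is.numeric(rho) || rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  K <- if (inbred) as.integer(n_founders) else 2L * as.integer(n_founders)
  structure(list(scenario = scenario, n_founders = as.integer(n_founders),
                 inbred = inbred, rho = rho, K = K),
            class = "hc_design")
}

#' Enumerate the hidden-state space of a design
#'
#' Hidden states are (i) ordered ancestral-haplotype pairs `(h1, h2)` with
#' `h1, h2 in 1..K` (`K^2` states, ordered with `h1` varying slowest) and
#' (ii) founder-genotype combinations: one phased genotype per founder,
#' restricted to the homozygotes `(0,0)`/`(1,1)` for inbred founders,
#' excluding combinations in which every founder carries the same genotype
#' (such markers are non-segregating and carry no linkage information).
#'
#' @param design an `hc_design`.
#' @return An object of class `hc_space` with elements
#'   \describe{
#'     \item{K, n_states}{ancestral haplotype count and `K^2`.}
#'     \item{h1, h2}{the haplotype pair of each state.}
#'     \item{n_combos}{number of retained founder combinations.}
#'     \item{founder_allele}{`n_founders x 2 x n_combos` array of phased
#'       founder alleles.}
#'     \item{founder_class}{`n_founders x n_combos` matrix of unphased
#'       founder genotype classes (0/1/2).}
#'     \item{anc_allele}{`K x n_combos` matrix: the allele carried by each
#'       ancestral haplotype under each combination.}
#'     \item{geno}{`K^2 x n_combos` matrix: the offspring genotype (0/1/2)
#'       implied by each haplotype pair under each combination.}
#'   }
#' @export
state_space <- function(design) {
  stopifnot(inherits(design, "hc_design"))
  K <- design$K
  nf <- design$n_founders
  h1 <- rep(seq_len(K), each = K)
  h2 <- rep(seq_len(K), times = K)

  per_founder <- if (design$inbred) list(c(0L, 0L), c(1L, 1L)) else
    list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  ng <- length(per_founder)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ng)), nf)))  # combos x nf
  same <- apply(grid, 1, function(r) all(r == r[1L]))
  grid <- grid[!same, , drop = FALSE]
  nc <- nrow(grid)

  founder_allele <- array(0L, c(nf, 2L, nc))
  for (j in seq_len(nf))
    for (c2 in 1:2)
      founder_allele[j, c2, ] <- vapply(grid[, j],
                                        function(g) per_founder[[g]][c2], 0L)
  founder_class <- founder_allele[, 1L, , drop = FALSE][, 1L, ] +
    founder_allele[, 2L, , drop = FALSE][, 1L, ]
  dim(founder_class) <- c(nf, nc)

  # allele carried by ancestral haplotype k: inbred founders contribute one
  # ancestor each; outbred founders contribute both chromosomes
  anc_allele <- matrix(0L, K, nc)
  for (k in seq_len(K)) {
    if (design$inbred) {
      anc_allele[k, ] <- founder_allele[k, 1L, ]
    } else {
      j <- (k + 1L) %/% 2L
      cc <- 2L - (k %% 2L)
      anc_allele[k, ] <- founder_allele[j, cc, ]
    }
  }
  geno <- anc_allele[h1, , drop = FALSE] + anc_allele[h2, , drop = FALSE]

  structure(list(K = K, n_states = K * K, h1 = h1, h2 = h2, n_combos = nc,
                 founder_allele = founder_allele,
                 founder_class = founder_class,
                 anc_allele = anc_allele, geno = geno,
                 inbred = design$inbred, n_founders = nf),
            class = "hc_space")
}

#' Genetic distances between adjacent markers
#'
#' Converts physical inter-marker distances to Morgans using a constant
#' expected genetic distance per megabase: `d_m = 1e-6 * (p_m - p_{m-1}) * Ed`.
#'
#' @param pos strictly increasing integer vector of physical positions (bp).
#' @param Ed expected genetic distance in Morgans per megabase; default 0.04
#'   (1 Mb = 4 cM).
#' @return Numeric vector of length `length(pos) - 1` in Morgans.
#' @export
genetic_distances <- function(pos, Ed = 0.04) {
  if (!is.numeric(Ed) || length(Ed) != 1L || Ed <= 0)
    stop("`Ed` must be a single positive number", call. = FALSE)
  if (any(diff(pos) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  1e-6 * diff(as.numeric(pos)) * Ed
}

#' Transition-rate matrix of the haplotype process
#'
#' The hidden haplotype pair follows a continuous-time Markov chain in which
#' each of the two lineages independently leaves its current ancestor at rate
#' `rho` per Morgan and jumps uniformly to one of the other `K - 1` ancestors.
#' Off-diagonal rates are `rho / (K - 1)` for state pairs differing in exactly
#' one lineage, 0 for pairs differing in both (no simultaneous double jumps),
#' and the diagonal is `-2 * rho`.
#'
#' @param design an `hc_design`.
#' @return A `K^2 x K^2` rate matrix with zero row sums.
#' @export
build_rate_matrix <- function(design) {
  stopifnot(inherits(design, "hc_design"))
  K <- design$K
  rho <- design$rho
  h1 <- rep(seq_len(K), each = K)
  h2 <- rep(seq_len(K), times = K)
  d1 <- outer(h1, h1, "!=")
  d2 <- outer(h2, h2, "!=")
  Q <- matrix(0, K * K, K * K)
  Q[xor(d1, d2)] <- rho / (K - 1)
  diag(Q) <- -2 * rho
  Q
}

#' Transition probability matrix over a genetic distance
#'
#' `T = expm(Q * d)`, computed by scaling-and-squaring with Pade
#' approximants. Entries are clipped at 0 and rows renormalized to guard
#' against roundoff at the 1e-15 level.
#'
#' @param Q rate matrix from [build_rate_matrix()].
#' @param d genetic distance in Morgans (`d >= 0`).
#' @return A row-stochastic matrix; rows sum to 1 within 1e-10.
#' @export
transition_matrix <- function(Q, d) {
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0)
  TT <- as.matrix(Matrix::expm(Q * d))
  TT[TT < 0] <- 0
  TT / rowSums(TT)
}

#' Stationary distribution of a transition matrix
#'
#' Normalizes the leading eigenvector of the transposed transition matrix.
#' For the exchangeable rate matrix of [build_rate_matrix()] this is the
#' uniform distribution over the `K^2` haplotype-pair states.
#'
#' @param TT a row-stochastic, irreducible matrix.
#' @return Probability vector `pi` with `pi %*% TT == pi`.
#' @export
initial_distribution <- function(TT) {
  e <- eigen(t(TT))
  i <- which.min(abs(e$values - 1))
  if (abs(e$values[i] - 1) > 1e-8)
    stop("transition matrix has no unit eigenvalue; chain not irreducible?",
         call. = FALSE)
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10))
    stop("stationary vector has negative entries; chain degenerate",
         call. = FALSE)
  v[v < 0] <- 0
  v / sum(v)
}

# per-interval transition matrices for a marker map, caching duplicates
transition_set <- function(design, pos, Ed = 0.04) {
  Q <- build_rate_matrix(design)
  d <- if (length(pos) > 1L) genetic_distances(pos, Ed) else numeric(0)
  key <- as.character(signif(d, 12))
  uniq <- !duplicated(key)
  cache <- lapply(d[uniq], function(dd) transition_matrix(Q, dd))
  names(cache) <- key[uniq]
  Ts <- lapply(key, function(k) cache[[k]])
  T0 <- if (length(Ts) > 0L) Ts[[1L]] else transition_matrix(Q, 1)
  list(Q = Q, d = d, T = Ts, pi = initial_distribution(T0))
}
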