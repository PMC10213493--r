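# Iterative parameter optimization: re-estimate per-marker allele read bias
# and mismapping rates from the current genotype estimates, then re-run the
# genotype estimation.

#' Estimate per-marker allele read bias from genotype estimates
#'
#' The bias `w_m` is the probability that a read at a heterozygous site
#' carries the alternative allele. It is estimated from the expected number
#' of reads per allele copy: with `r^x(g)` the summed reads of allele `x`
#' over samples (offspring and founders) whose estimated genotype is `g`,
#' and allele-copy counts of 2 per homozygote and 1 per heterozygote,
#' \deqn{E^{ref} = \frac{r^{ref}(0)+r^{ref}(1)}{2 n_0 + n_1},\quad
#'       E^{alt} = \frac{r^{alt}(2)+r^{alt}(1)}{2 n_2 + n_1},\quad
#'       \hat w = \frac{E^{alt}}{E^{ref}+E^{alt}}.}
#' Markers whose denominators are undefined (no informative allele copies,
#' or no reads) keep their previous value. Estimates are clamped to
#' `[0.02, 0.98]` so that no genotype class ever becomes unobservable in
#' later cycles.
#'
#' @param ds an [hc_dataset].
#' @param geno markers x samples matrix of estimated genotypes (0/1/2, `NA`
#'   for missing), covering every sample in `ds` (founders included).
#' @param w_prev previous per-marker bias vector (carry-forward values).
#' @param clamp two-element numeric range to clamp the estimate to.
#' @return list with `w` (updated bias vector) and `informative` (number of
#'   informative allele copies per marker, `2*n_0 + 2*n_2 + 2*n_1`).
#' @export
estimate_bias <- function(ds, geno, w_prev, clamp = c(0.02, 0.98)) {
  stopifnot(identical(dim(geno), dim(ds$y_ref)))
  I0 <- !is.na(geno) & geno == 0L
  I1 <- !is.na(geno) & geno == 1L
  I2 <- !is.na(geno) & geno == 2L
  rref0 <- rowSums(ds$y_ref * I0)
  rref1 <- rowSums(ds$y_ref * I1)
  ralt1 <- rowSums(ds$y_alt * I1)
  ralt2 <- rowSums(ds$y_alt * I2)
  n0 <- rowSums(I0); n1 <- rowSums(I1); n2 <- rowSums(I2)
  den_ref <- 2 * n0 + n1
  den_alt <- 2 * n2 + n1
  Eref <- ifelse(den_ref > 0, (rref0 + rref1) / pmax(den_ref, 1), NA_real_)
  Ealt <- ifelse(den_alt > 0, (ralt2 + ralt1) / pmax(den_alt, 1), NA_real_)
  w <- Ealt / (Eref + Ealt)
  w[!is.finite(w)] <- NA_real_
  w <- ifelse(is.na(w), w_prev, pmin(pmax(w, clamp[1L]), clamp[2L]))
  list(w = w, informative = 2 * (n0 + n1 + n2))
}

#' Estimate per-marker mismapping rates from genotype estimates
#'
#' A cell whose reads alone give a heterozygote probability above 0.99 but
#' whose HMM-estimated genotype is homozygous is taken as a mismapping-induced
#' erroneous call. `e_ref` is the fraction of such cells among cells
#' estimated homozygous reference; `e_alt` analogously for homozygous
#' alternative. The heterozygote probability uses the current cycle's `w_m`
#' and `e_seq`, normalized over the three observable genotypes. Markers with
#' an empty denominator keep their previous rate.
#'
#' @param ds an [hc_dataset].
#' @param geno markers x samples genotype matrix (as in [estimate_bias()]).
#' @param params an `hc_params` (supplies `w` and `e_seq`).
#' @param e_ref_prev,e_alt_prev previous rate vectors (carry-forward).
#' @return list with `e_ref` and `e_alt` vectors.
#' @export
estimate_mismap <- function(ds, geno, params, e_ref_prev, e_alt_prev) {
  stopifnot(identical(dim(geno), dim(ds$y_ref)))
  e <- params$e_seq
  w <- params$w
  p0 <- (1 - e)^ds$y_ref * e^ds$y_alt
  p1 <- (1 - w)^ds$y_ref * w^ds$y_alt
  p2 <- e^ds$y_ref * (1 - e)^ds$y_alt
  zero <- (p0 == 0) | (p1 == 0) | (p2 == 0)
  p0[zero] <- p0[zero] + 0.005
  p1[zero] <- p1[zero] + 0.005
  p2[zero] <- p2[zero] + 0.005
  het <- p1 / (p0 + p1 + p2) > 0.99
  hom0 <- !is.na(geno) & geno == 0L
  hom2 <- !is.na(geno) & geno == 2L
  n0 <- rowSums(hom0)
  n2 <- rowSums(hom2)
  er <- ifelse(n0 > 0, rowSums(het & hom0) / pmax(n0, 1), e_ref_prev)
  ea <- ifelse(n2 > 0, rowSums(het & hom2) / pmax(n2, 1), e_alt_prev)
  list(e_ref = er, e_alt = ea)
}

#' Genotype estimation with iterative parameter optimization
#'
#' Alternates genotype estimation ([two_round_estimate()]) with re-estimation
#' of the per-marker allele read bias and mismapping rates from the estimated
#' genotypes. The first cycle runs with the initial parameters
#' (`w = 0.5`, `e_ref = e_alt = 0.005` unless overridden), so `cycles = 1`
#' is estimation without parameter optimization.
#'
#' @param ds an [hc_dataset].
#' @param design an `hc_design`.
#' @param params optional `hc_params`; defaults to `model_params(M)`.
#' @param cycles number of estimation cycles; default 4.
#' @param fix_bias,fix_mismap freeze the bias / mismap updates.
#' @param keep_history keep each cycle's called genotype matrix (for
#'   comparing cycle counts without re-running).
#' @return list with `estimate` (final `hc_estimate`), `params` (final
#'   `hc_params`), `bias_informative` (informative allele-copy counts from
#'   the last update, or `NULL` when `cycles = 1` or `fix_bias`), and
#'   `history` (when requested, a list of per-cycle called genotype
#'   matrices).
#' @export
run_ipo <- function(ds, design, params = NULL, cycles = 4,
                    fix_bias = FALSE, fix_mismap = FALSE,
                    keep_history = FALSE) {
  stopifnot(cycles >= 1)
  if (is.null(params)) params <- model_params(ds$n_markers)
  history <- if (keep_history) vector("list", cycles) else NULL
  fc <- founder_cols(ds)
  oc <- offspring_cols(ds)
  informative <- NULL
  est <- NULL
  for (cy in seq_len(cycles)) {
    est <- two_round_estimate(ds, design, params)
    if (keep_history) history[[cy]] <- est$offspring_geno
    if (cy == cycles) break
    geno <- matrix(NA_integer_, ds$n_markers, length(ds$samples))
    geno[, fc] <- est$founder_geno
    geno[, oc] <- est$offspring_geno
    if (!fix_mismap) {
      mm <- estimate_mismap(ds, geno, params, params$e_ref, params$e_alt)
      params$e_ref <- mm$e_ref
      params$e_alt <- mm$e_alt
    }
    if (!fix_bias) {
      bb <- estimate_bias(ds, geno, params$w)
      params$w <- bb$w
      informative <- bb$informative
    }
  }
  list(estimate = est, params = params, bias_informative = informative,
       history = history)
}
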