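#' End-to-end genotype error correction on a VCF
#'
#' Reads a VCF with allele depths, optionally filters over-represented
#' reads, runs iterative-parameter-optimization genotype estimation, and
#' writes the corrected VCF plus a run report. All randomness (argmax
#' tie-breaking) is governed by `seed`, so a run is reproducible
#' bit-for-bit.
#'
#' @param vcf_in input VCF path.
#' @param vcf_out output VCF path.
#' @param founders character vector of founder sample names (or supply
#'   `config`).
#' @param scenario mating-design scenario (see [mating_design()]).
#' @param config optional YAML file with keys `scenario`, `founders`,
#'   `e_seq`, `Ed`, `p_call`, `cycles`, `seed`, `filter_quantile`;
#'   explicit arguments override the file.
#' @param cycles IPO cycles; default 4.
#' @param e_seq,Ed,p_call model parameters (see [model_params()]).
#' @param filter_quantile if non-`NULL`, apply
#'   [filter_overrepresented_reads()] with this quantile first.
#' @param seed integer RNG seed; default 1.
#' @return Invisibly, a list with the resolved configuration, the
#'   `hc_estimate`, and a per-chromosome report (marker count, missing
#'   rate).
#' @export
correct_genotypes <- function(vcf_in, vcf_out, founders = NULL,
                              scenario = NULL, config = NULL, cycles = NULL,
                              e_seq = NULL, Ed = NULL, p_call = NULL,
                              filter_quantile = NULL, seed = NULL) {
  cfg <- if (!is.null(config)) yaml::read_yaml(config) else list()
  founders <- founders %||% cfg$founders
  scenario <- scenario %||% cfg$scenario
  cycles <- cycles %||% cfg$cycles %||% 4
  e_seq <- e_seq %||% cfg$e_seq %||% 0.0025
  Ed <- Ed %||% cfg$Ed %||% 0.04
  p_call <- p_call %||% cfg$p_call %||% 0.9
  filter_quantile <- filter_quantile %||% cfg$filter_quantile
  seed <- seed %||% cfg$seed %||% 1
  if (is.null(founders) || is.null(scenario))
    stop("`founders` and `scenario` are required (directly or via config)",
         call. = FALSE)
  set.seed(as.integer(seed))
  ds <- read_vcf(vcf_in, founders)
  if (!is.null(filter_quantile))
    ds <- filter_overrepresented_reads(ds, filter_quantile)
  design <- mating_design(scenario)
  params <- model_params(ds$n_markers, e_seq = e_seq, Ed = Ed,
                         p_call = p_call)
  fit <- run_ipo(ds, design, params, cycles = cycles)
  write_vcf(ds, vcf_out, fit$estimate)
  report <- list(
    config = list(scenario = scenario, founders = founders, cycles = cycles,
                  e_seq = e_seq, Ed = Ed, p_call = p_call, seed = seed),
    per_chrom = data.frame(
      chrom = unique(ds$chrom),
      n_markers = as.vector(table(ds$chrom)[unique(ds$chrom)]),
      missing_rate = vapply(unique(ds$chrom), function(cc)
        mean(is.na(fit$estimate$offspring_geno[ds$chrom == cc, ])), 0)),
    estimate = fit$estimate, params = fit$params)
  invisible(report)
}
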