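#' Read a VCF file with allele depths into a dataset
#'
#' Reads biallelic SNP records with a per-sample `AD` FORMAT field and
#' assembles an [hc_dataset]. Genotype calls (`GT`) in the input are ignored:
#' the model works from read counts alone. Records with more than one
#' alternative allele are dropped (a message reports how many); records where
#' a sample lacks `AD` (or has `AD = "."`) yield `(0, 0)` reads for that cell,
#' i.e. the model's native missing state.
#'
#' @param path path to a VCF (optionally bgzip/gzip compressed).
#' @param founder_names character vector of sample names to treat as
#'   founders; all other samples become offspring. Must all be present in the
#'   VCF header.
#' @return An [hc_dataset].
#' @export
read_vcf <- function(path, founder_names) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt_meta <- grep("^##FORMAT=<ID=AD[,>]", vcf@meta, value = TRUE)
  if (length(fmt_meta) == 0L)
    stop("VCF has no AD FORMAT definition; allele depths are required",
         call. = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  missing_f <- setdiff(founder_names, samples)
  if (length(missing_f) > 0L)
    stop("founder name(s) absent from VCF header: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  fix <- vcf@fix
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) & alt != "." &
    nchar(alt) == 1L & nchar(ref) == 1L
  n_drop <- sum(!biallelic)
  if (n_drop > 0L)
    message(sprintf("read_vcf: dropped %d non-biallelic-SNP record(s)", n_drop))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad <- ad[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic SNP records in VCF", call. = FALSE)

  parse_allele <- function(k) {
    out <- matrix(0L, nrow(ad), ncol(ad))
    val <- suppressWarnings(
      as.integer(vapply(strsplit(ifelse(is.na(ad) | ad == ".", "0,0", ad), ",",
                                 fixed = TRUE),
                        function(p) if (length(p) >= k) p[k] else "0",
                        character(1))))
    val[is.na(val)] <- 0L
    out[] <- val
    out
  }
  y_ref <- parse_allele(1L)
  y_alt <- parse_allele(2L)

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[is.na(ids) | ids == ".", "CHROM"], "_",
           fix[is.na(ids) | ids == ".", "POS"])
  roles <- ifelse(samples %in% founder_names, "founder", "offspring")
  # founders first keeps downstream indexing stable but we preserve VCF order
  hc_dataset(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
             fix[, "REF"], fix[, "ALT"], y_ref, y_alt, samples, roles)
}

#' Zero out over-represented read counts
#'
#' Reads mapped far in excess of a sample's typical coverage usually come
#' from paralogous or repetitive sequence and masquerade as heterozygote
#' evidence. For each sample and each allele a threshold is set at the given
#' quantile of that sample's counts for that allele across all markers
#' (zeros included); every genotype call where either allele's count exceeds
#' its threshold has *both* counts of the call set to 0.
#'
#' @param ds an [hc_dataset].
#' @param quantile quantile in (0, 1] defining the per-sample, per-allele
#'   threshold; default 0.90.
#' @param type quantile estimator type passed to [stats::quantile()];
#'   default 7 (linear interpolation).
#' @return A new [hc_dataset] with the offending calls zeroed.
#' @export
filter_overrepresented_reads <- function(ds, quantile = 0.90, type = 7) {
  stopifnot_scalar_prob(quantile, "quantile", lo = 0, hi = 1, lo_open = TRUE)
  thr_ref <- apply(ds$y_ref, 2, stats::quantile, probs = quantile,
                   type = type, names = FALSE)
  thr_alt <- apply(ds$y_alt, 2, stats::quantile, probs = quantile,
                   type = type, names = FALSE)
  over <- sweep(ds$y_ref, 2, thr_ref, ">") | sweep(ds$y_alt, 2, thr_alt, ">")
  y_ref <- ds$y_ref
  y_alt <- ds$y_alt
  y_ref[over] <- 0L
  y_alt[over] <- 0L
  hc_dataset(ds$marker_ids, ds$chrom, ds$pos, ds$ref, ds$alt,
             y_ref, y_alt, ds$samples, ds$roles)
}

#' Write a dataset (and optionally an estimation result) as VCF
#'
#' Emits an uncompressed VCF 4.3 file with the original sites and `AD`
#' values. When `result` is supplied, offspring `GT` is set from the called
#' genotypes (`./.` for masked calls) with the posterior probability of the
#' call in the `PC` FORMAT field; founder `GT` is the estimated phased
#' genotype.
#'
#' @param ds an [hc_dataset].
#' @param path output file path.
#' @param result optional `hc_estimate` as returned by [two_round_estimate()]
#'   or [run_ipo()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path, result = NULL) {
  m <- ds$n_markers
  n <- length(ds$samples)
  gt <- matrix("./.", m, n)
  pc <- matrix(".", m, n)
  if (!is.null(result)) {
    if (!identical(dim(result$offspring_geno), c(m, ds$n_offspring)))
      stop("result dimensions do not match dataset", call. = FALSE)
    gcode <- c("0/0", "0/1", "1/1")
    og <- result$offspring_geno
    oc <- offspring_cols(ds)
    gt[, oc] <- ifelse(is.na(og), "./.", gcode[og + 1L])
    pc[, oc] <- ifelse(is.na(result$marginal), ".",
                       sprintf("%.4g", result$marginal))
    fc <- founder_cols(ds)
    fg <- result$founder_phased  # m x nf x 2 allele array
    gt[, fc] <- paste0(fg[, , 1L], "|", fg[, , 2L])
  }
  body <- paste0(gt, ":", ds$y_ref, ",", ds$y_alt, ":", pc)
  dim(body) <- c(m, n)
  lines <- c(
    "##fileformat=VCFv4.3",
    "##source=hapclean",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    '##FORMAT=<ID=PC,Number=1,Type=Float,Description="Posterior probability of the called genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples), collapse = "\t"),
    paste(ds$chrom, ds$pos, ds$marker_ids, ds$ref, ds$alt, ".", ".", ".",
          "GT:AD:PC",
          apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
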