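#' Read-count dataset for a crossing population
#'
#' The central data container of hapclean: a markers-by-samples table of
#' per-allele read counts together with marker coordinates and the role
#' (founder or offspring) of every sample. All downstream modelling uses only
#' these read counts; any genotype calls present in the source VCF are
#' ignored.
#'
#' @param marker_ids character vector of marker identifiers.
#' @param chrom character vector, chromosome of each marker.
#' @param pos integer vector, 1-based physical position (bp) of each marker;
#'   must be strictly increasing within each chromosome.
#' @param ref,alt single-character reference / alternative alleles per marker.
#' @param y_ref,y_alt integer matrices (markers x samples) of reference and
#'   alternative allele read counts; missing data is encoded as 0 reads.
#' @param samples character vector of sample names (columns).
#' @param roles character vector, one of `"founder"` or `"offspring"` per
#'   sample; at least 2 founders and 1 offspring are required.
#'
#' @return An object of class `hc_dataset`: a list with the fields above plus
#'   `n_founders`, `n_offspring` and `n_markers`.
#' @export
hc_dataset <- function(marker_ids, chrom, pos, ref, alt, y_ref, y_alt,
                       samples, roles) {
  m <- length(marker_ids)
  n <- length(samples)
  stopifnot(
    length(chrom) == m, length(pos) == m, length(ref) == m, length(alt) == m,
    is.matrix(y_ref), is.matrix(y_alt),
    nrow(y_ref) == m, ncol(y_ref) == n,
    nrow(y_alt) == m, ncol(y_alt) == n,
    length(roles) == n
  )
  if (any(y_ref < 0) || any(y_alt < 0))
    stop("read counts must be nonnegative", call. = FALSE)
  if (!all(roles %in% c("founder", "offspring")))
    stop("roles must be 'founder' or 'offspring'", call. = FALSE)
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within a chromosome",
           call. = FALSE)
  }
  nf <- sum(roles == "founder")
  no <- sum(roles == "offspring")
  if (nf < 2L) stop("at least 2 founders are required", call. = FALSE)
  if (no < 1L) stop("at least 1 offspring is required", call. = FALSE)
  storage.mode(y_ref) <- "integer"
  storage.mode(y_alt) <- "integer"
  dimnames(y_ref) <- dimnames(y_alt) <- list(marker_ids, samples)
  structure(
    list(marker_ids = as.character(marker_ids), chrom = as.character(chrom),
         pos = as.integer(pos), ref = as.character(ref),
         alt = as.character(alt), y_ref = y_ref, y_alt = y_alt,
         samples = as.character(samples), roles = as.character(roles),
         n_founders = nf, n_offspring = no, n_markers = m),
    class = "hc_dataset")
}

#' @export
print.hc_dataset <- function(x, ...) {
  cat(sprintf("<hc_dataset> %d markers on %d chromosome(s); %d founders, %d offspring\n",
              x$n_markers, length(unique(x$chrom)), x$n_founders, x$n_offspring))
  dp <- mean(x$y_ref + x$y_alt)
  cat(sprintf("  mean read depth per cell: %.2f\n", dp))
  invisible(x)
}

# column indices of founders / offspring
founder_cols <- function(ds) which(ds$roles == "founder")
offspring_cols <- function(ds) which(ds$roles == "offspring")

# subset a dataset to one chromosome, keeping all samples
subset_chrom <- function(ds, cc) {
  keep <- ds$chrom == cc
  hc_dataset(ds$marker_ids[keep], ds$chrom[keep], ds$pos[keep],
             ds$ref[keep], ds$alt[keep],
             ds$y_ref[keep, , drop = FALSE], ds$y_alt[keep, , drop = FALSE],
             ds$samples, ds$roles)
}
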