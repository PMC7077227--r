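#' TPM per thousand (TPM/1000)
#'
#' Length-normalized relative abundance: per-contig count rates
#' `count/length` are scaled so that a dataset's transcripts-per-million
#' values sum to 1e6, then divided by `tpm_divisor` (1000 by default, so a
#' dataset's values sum to 1000). A column with all-zero counts yields
#' all zeros.
#'
#' @param counts Non-negative counts: a vector (one dataset) or a
#'   contig x dataset matrix.
#' @param lengths Per-contig nucleotide lengths (> 0), aligned with the
#'   rows of `counts`.
#' @param config A [pipeline_config()].
#' @return Numeric vector or matrix of the same shape, with attribute
#'   `unit = "tpm_k"`.
#' @export
tpm_thousand <- function(counts, lengths, config = pipeline_config()) {
  config <- as_config(config)
  if (any(lengths <= 0)) stop("contig lengths must be > 0", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  one <- function(v) {
    rate <- v / lengths
    s <- sum(rate)
    if (s == 0) return(rep(0, length(v)))
    (1e6 * rate / s) / config$tpm_divisor
  }
  out <- if (is.matrix(counts)) {
    m <- apply(counts, 2L, one)
    dimnames(m) <- dimnames(counts)
    m
  } else {
    one(counts)
  }
  attr(out, "unit") <- "tpm_k"
  out
}

#' Log2 transform of a TPM/1000 matrix
#'
#' Per-cell log base 2; zeros are masked as missing (`NA`) rather than
#' mapped to minus infinity, since a zero here means "not detected", not
#' "infinitely rare".
#'
#' @param m A matrix or vector with attribute `unit = "tpm_k"` (see
#'   [tpm_thousand()]).
#' @return Same shape, attribute `unit = "log2_tpm_k"`.
#' @export
log2_matrix <- function(m) {
  if (!identical(attr(m, "unit"), "tpm_k")) {
    stop("input must carry unit 'tpm_k'", call. = FALSE)
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative abundance value", call. = FALSE)
  out <- log2(ifelse(m == 0, NA, m))
  if (is.matrix(m)) dimnames(out) <- dimnames(m)
  attr(out, "unit") <- "log2_tpm_k"
  out
}

#' Depth-normalized reads per million (RPM)
#'
#' Aligned-read counts normalized to sequencing depth, expressed per
#' million raw read pairs: `1e6 * aligned / raw_read_pairs`. The raw
#' read-pair count of the library — not the post-filter retained count —
#' is the depth denominator.
#'
#' @param aligned_reads Number of reads aligned (vectorized).
#' @param library A dataset-library row (list or data.frame with a
#'   `raw_read_pairs` field), or a numeric vector of raw read-pair counts.
#' @return Numeric RPM value(s).
#' @export
depth_normalized_rpm <- function(aligned_reads, library) {
  raw <- if (is.numeric(library)) library else library$raw_read_pairs
  if (is.null(raw)) stop("library must supply raw_read_pairs", call. = FALSE)
  if (any(raw <= 0)) stop("raw_read_pairs must be > 0", call. = FALSE)
  if (any(aligned_reads < 0)) stop("aligned_reads must be >= 0", call. = FALSE)
  1e6 * aligned_reads / raw
}

#' Standard deviations from the mean (z-scores)
#'
#' `z_i = (v_i - mean(v)) / sd(v)` with the sample (n-1) standard
#' deviation. The resulting vector has mean 0 and sample SD 1.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Numeric vector of z-scores.
#' @export
sds_from_mean <- function(values) {
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation: degenerate input", call. = FALSE)
  (values - mean(values)) / s
}

#' Food-derived fraction of the viral load
#'
#' Per dataset, the percentage of virus-mapped reads that map to
#' food-source-derived viral contigs, plus the unweighted group mean over
#' the polyA-side libraries (enrichment `polyA` or `unknown`;
#' rRNA-depleted libraries are excluded from the mean because their viral
#' capture differs systematically).
#'
#' @param total_counts Named numeric vector: per-dataset reads aligned to
#'   all viral contigs.
#' @param food_subset_counts Named numeric vector: per-dataset reads
#'   aligned to the food-derived subset. Must not exceed `total_counts`.
#' @param libraries Dataset metadata (see [read_dataset_metadata()]).
#' @return A list: `fraction` (named percent vector) and `polyA_mean`
#'   (scalar percent).
#' @export
food_fraction_stats <- function(total_counts, food_subset_counts,
                                libraries) {
  ds <- names(total_counts)
  stopifnot(!is.null(ds), identical(ds, names(food_subset_counts)))
  if (any(food_subset_counts > total_counts)) {
    stop("food-subset counts exceed totals", call. = FALSE)
  }
  if (any(total_counts == 0 & food_subset_counts > 0)) {
    stop("zero total with nonzero food count", call. = FALSE)
  }
  frac <- ifelse(total_counts == 0, 0,
                 100 * food_subset_counts / total_counts)
  names(frac) <- ds
  enr <- libraries$enrichment[match(ds, libraries$dataset_id)]
  if (anyNA(enr)) {
    stop("dataset(s) missing from library metadata: ",
         paste(ds[is.na(enr)], collapse = ", "), call. = FALSE)
  }
  grp <- enr %in% c("polyA", "unknown")
  list(fraction = frac, polyA_mean = mean(frac[grp]))
}

#' Collapse an abundance matrix by viral species
#'
#' Rows whose contigs share a species label are merged by summing raw
#' counts, so that fragments of one virus appear as one entry. Collapse is
#' performed on raw counts; normalize after collapsing when TPM values are
#' wanted.
#'
#' @param m Count matrix (contigs x datasets).
#' @param annotations Annotation data.frame covering every row of `m`.
#' @return Collapsed matrix, rows named by species label, column sums
#'   preserved.
#' @export
collapse_by_species <- function(m, annotations) {
  sp <- annotations$species_label[match(rownames(m), annotations$contig_id)]
  if (anyNA(sp)) {
    stop("unannotated contig(s): ",
         paste(utils::head(rownames(m)[is.na(sp)], 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- rowsum(m, group = sp, reorder = FALSE)
  out
}
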