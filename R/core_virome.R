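#' Presence/absence matrix from read counts
#'
#' A contig is present in a dataset when at least `presence_min_reads`
#' reads from that dataset mapped to it (default 1: any remapped read
#' counts as detection).
#'
#' @param counts Count matrix (contigs x datasets).
#' @param config A [pipeline_config()].
#' @return Logical matrix of the same shape with attribute `threshold`.
#' @export
presence_matrix <- function(counts, config = pipeline_config()) {
  config <- as_config(config)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- counts >= config$presence_min_reads
  attr(p, "threshold") <- config$presence_min_reads
  p
}

#' Core set, unique sets and Venn regions
#'
#' Over the included datasets: the core is the set of contigs present in
#' every dataset; each dataset's unique set holds contigs present only
#' there; and every non-empty dataset combination (a Venn region) is
#' counted. Regions partition the contigs present in at least one
#' included dataset. Datasets to exclude (e.g. an embryonic library with
#' negligible viral load) are simply left off `include_datasets`.
#'
#' @param p Presence matrix (see [presence_matrix()]).
#' @param include_datasets Ordered character vector of dataset (column)
#'   names to intersect.
#' @return A list: `core` (contig ids), `unique` (named list of contig id
#'   vectors), `regions` (named integer vector; names are membership
#'   bitmasks over `include_datasets`, e.g. `"101"`), and
#'   `region_members` (named list of contig ids per region).
#' @export
core_and_unique_sets <- function(p, include_datasets) {
  if (length(include_datasets) == 0L) {
    stop("include_datasets must be non-empty", call. = FALSE)
  }
  missing <- setdiff(include_datasets, colnames(p))
  if (length(missing)) {
    stop("dataset(s) not in presence matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- p[, include_datasets, drop = FALSE]
  anywhere <- rownames(sub)[rowSums(sub) > 0L]
  mask <- apply(sub[anywhere, , drop = FALSE], 1L, function(r) {
    paste(as.integer(r), collapse = "")
  })
  region_members <- split(anywhere, mask)
  regions <- vapply(region_members, length, 0L)
  core <- rownames(sub)[rowSums(sub) == length(include_datasets)]
  uniq <- lapply(seq_along(include_datasets), function(j) {
    rownames(sub)[sub[, j] & rowSums(sub) == 1L]
  })
  names(uniq) <- include_datasets
  list(core = core, unique = uniq, regions = regions,
       region_members = region_members)
}

#' Flag contigs shared with the food source
#'
#' A contig is food-shared only when present in BOTH sequencing
#' replicates of the food source — a single-replicate detection is not
#' accepted.
#'
#' @param p Presence matrix.
#' @param food_replicates Character vector of exactly two food-replicate
#'   dataset names.
#' @return Character vector of flagged contig ids.
#' @export
flag_food_shared <- function(p, food_replicates) {
  if (length(food_replicates) != 2L) {
    stop("food_replicates must name exactly two datasets", call. = FALSE)
  }
  missing <- setdiff(food_replicates, colnames(p))
  if (length(missing)) {
    stop("food replicate(s) not in presence matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rownames(p)[p[, food_replicates[1L]] & p[, food_replicates[2L]]]
}
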