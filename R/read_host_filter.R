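#' Best host-genome e-value per read
#'
#' Reduces a read-versus-host-genome hit table to one row per read carrying
#' the minimum e-value over that read's hits. This is the per-read summary
#' on which the host-subtraction decision is made.
#'
#' @param hits A homology hit data.frame (see [read_homology_table()]);
#'   `qid` is the read id.
#' @return A data.frame with columns `read_id` and `best_host_evalue`,
#'   one row per distinct read, in first-appearance order.
#' @export
best_evalue_per_read <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(read_id = character(0),
                      best_host_evalue = numeric(0)))
  }
  best <- tapply(hits$evalue, hits$qid, min)
  ids <- unique(hits$qid)
  data.frame(read_id = ids,
             best_host_evalue = as.numeric(best[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Host subtraction: remove host-like reads by e-value cutoff
#'
#' A read is removed if and only if its best host-genome hit has an
#' e-value at or below `cutoff` (default 1e-15), i.e. the read is
#' significantly host-like. Reads with no host hit, or only hits weaker
#' than the cutoff, are retained.
#'
#' @param screens Output of [best_evalue_per_read()].
#' @param all_read_ids Character vector: the full read-id universe.
#' @param cutoff Removal cutoff (inclusive boundary).
#' @return Character vector of retained read ids (a subset of
#'   `all_read_ids`, in the universe's order), with attribute `log`, a
#'   one-row data.frame of input/removed/retained counts.
#' @export
filter_reads_by_host_evalue <- function(screens, all_read_ids,
                                        cutoff = 1e-15) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  all_read_ids <- as.character(all_read_ids)
  unknown <- setdiff(screens$read_id, all_read_ids)
  if (length(unknown)) {
    stop("screened read id(s) not in the read universe: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  hostlike <- screens$read_id[!is.na(screens$best_host_evalue) &
                                screens$best_host_evalue <= cutoff]
  retained <- all_read_ids[!(all_read_ids %in% hostlike)]
  attr(retained, "log") <- data.frame(
    input = length(all_read_ids),
    removed = length(all_read_ids) - length(retained),
    retained = length(retained))
  retained
}
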