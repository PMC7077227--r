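#' Project homology hits onto contig intervals
#'
#' Converts each hit's 1-based inclusive query coordinates to a 0-based
#' half-open interval (reversed / minus-frame coordinates are normalized so
#' start < end), then merges overlapping or abutting intervals into a
#' disjoint sorted union. No flanking sequence is added: the union covers
#' exactly the nucleotides with reported homology.
#'
#' @param hits Hit data.frame, all rows sharing one `qid`.
#' @param contig_len Length of the contig in nt.
#' @return A two-column matrix (`start`, `end`) of disjoint, sorted,
#'   0-based half-open intervals; zero rows when `hits` is empty.
#' @export
project_hits_to_intervals <- function(hits, contig_len) {
  stopifnot(length(contig_len) == 1L, contig_len >= 1)
  if (nrow(hits) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (length(unique(hits$qid)) > 1L) {
    stop("hits must share a single query id", call. = FALSE)
  }
  lo <- pmin(hits$qstart, hits$qend) - 1L
  hi <- pmax(hits$qstart, hits$qend)
  if (any(hi > contig_len)) {
    stop("hit coordinate beyond contig length (", contig_len, ") for query ",
         hits$qid[1L], call. = FALSE)
  }
  merge_intervals(cbind(start = lo, end = hi))
}

# union of 0-based half-open intervals; overlapping or abutting merge
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  o <- order(iv[, 1L], iv[, 2L])
  iv <- iv[o, , drop = FALSE]
  out_s <- iv[1L, 1L]; out_e <- iv[1L, 2L]
  res <- list()
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] <= out_e) {
      out_e <- max(out_e, iv[i, 2L])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- iv[i, 1L]; out_e <- iv[i, 2L]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' Triage one contig against three simultaneous homology searches
#'
#' Implements the first identification step: each assembled contig is
#' classified from the results of three searches run against it — host
#' genome (nucleotide), viral proteins, and prokaryote proteins. Rules, in
#' order: a contig shorter than `min_contig_len` is `too_short`; with no
#' viral hit at `e <= viral_evalue` it is `host` (any host hit),
#' `prokaryotic` (any prokaryote hit at `e <= prok_evalue`) or `no_hit`;
#' with a viral hit it is `viral_candidate` only when the best viral
#' e-value is strictly smaller than both the best host and best
#' (gated) prokaryote e-values — otherwise `ambiguous`.
#'
#' @param contig One-row contig data.frame (columns `id`, `sequence`).
#' @param host_hits,viral_hits,prok_hits Hit data.frames restricted to this
#'   contig's id (zero-row data.frames when a search found nothing).
#' @param config A [pipeline_config()].
#' @return A list of class `triage_result`: `contig_id`, `status`,
#'   `best_viral_hit` (one-row data.frame or `NULL`) and `viral_intervals`
#'   (matrix from [project_hits_to_intervals()]).
#' @export
classify_contig <- function(contig, host_hits, viral_hits, prok_hits,
                            config = pipeline_config()) {
  config <- as_config(config)
  contig_len <- nchar(contig$sequence)
  res <- list(contig_id = contig$id, status = NA_character_,
              best_viral_hit = NULL,
              viral_intervals = matrix(integer(0), ncol = 2L,
                                       dimnames = list(NULL, c("start", "end"))))
  class(res) <- "triage_result"
  if (contig_len < config$min_contig_len) {
    res$status <- "too_short"
    return(res)
  }
  vh <- viral_hits[viral_hits$evalue <= config$viral_evalue, , drop = FALSE]
  ph <- prok_hits[prok_hits$evalue <= config$prok_evalue, , drop = FALSE]
  if (nrow(vh) == 0L) {
    res$status <- if (nrow(host_hits) > 0L) "host"
                  else if (nrow(ph) > 0L) "prokaryotic"
                  else "no_hit"
    return(res)
  }
  best_v <- min(vh$evalue)
  best_h <- if (nrow(host_hits)) min(host_hits$evalue) else Inf
  best_p <- if (nrow(ph)) min(ph$evalue) else Inf
  if (best_v < best_h && best_v < best_p) {
    res$status <- "viral_candidate"
    res$best_viral_hit <- best_hit(vh)
    res$viral_intervals <- project_hits_to_intervals(vh, contig_len)
  } else {
    res$status <- "ambiguous"
  }
  res
}

#' Trim a viral candidate to its regions of viral homology
#'
#' Slices the contig at each merged viral-homology interval and keeps only
#' fragments of at least `min_contig_len` nt, so that no published fragment
#' falls below the contig length gate. Fragment ids are the parent id
#' suffixed with the 1-based inclusive span.
#'
#' @param contig One-row contig data.frame.
#' @param result The contig's `triage_result`; must be a `viral_candidate`.
#' @param config A [pipeline_config()].
#' @return A data.frame with columns `id`, `parent_id`, `start`, `end`
#'   (0-based half-open) and `sequence`; zero rows when every interval is
#'   too short, with the excluded spans in attribute `excluded`.
#' @export
trim_to_viral_homology <- function(contig, result,
                                   config = pipeline_config()) {
  config <- as_config(config)
  if (!identical(result$status, "viral_candidate")) {
    stop("trim_to_viral_homology() requires a viral_candidate (got status '",
         result$status, "')", call. = FALSE)
  }
  contig_len <- nchar(contig$sequence)
  iv <- result$viral_intervals
  len <- iv[, "end"] - iv[, "start"]
  keep <- len >= config$min_contig_len
  kept <- iv[keep, , drop = FALSE]
  # a fragment spanning the whole contig IS the contig; keep its id stable
  whole <- nrow(kept) == 1L && kept[1L, "start"] == 0L &&
    kept[1L, "end"] == contig_len
  if (nrow(kept) == 0L) {
    out <- data.frame(id = character(0), parent_id = character(0),
                      start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  } else {
    ids <- if (whole) contig$id else
      sprintf("%s_%d-%d", contig$id, kept[, "start"] + 1L, kept[, "end"])
    out <- data.frame(
      id = ids,
      parent_id = rep(contig$id, nrow(kept)),
      start = kept[, "start"], end = kept[, "end"],
      sequence = substring(contig$sequence, kept[, "start"] + 1L,
                           kept[, "end"]),
      stringsAsFactors = FALSE)
  }
  attr(out, "excluded") <- iv[!keep, , drop = FALSE]
  out
}

#' Remove duplicate and nested sequences
#'
#' Collapses exact duplicate sequences (first id kept) and removes any
#' sequence that is an exact substring of a longer retained sequence —
#' the clearing step applied after per-dataset assemblies are merged,
#' where nested fragments are common.
#'
#' @param contigs Data.frame with columns `id` and `sequence` (trimmed
#'   fragments or whole contigs).
#' @return The de-duplicated data.frame, original order preserved.
#' @export
dedupe_contigs <- function(contigs) {
  if (nrow(contigs) <= 1L) return(contigs)
  first <- !duplicated(contigs$sequence)
  contigs <- contigs[first, , drop = FALSE]
  sq <- contigs$sequence
  n <- length(sq)
  contained <- logical(n)
  o <- order(nchar(sq), decreasing = TRUE)
  for (i in seq_len(n)) {
    si <- o[i]
    if (contained[si]) next
    for (j in seq_len(n)) {
      sj <- o[j]
      if (sj == si || contained[sj]) next
      if (nchar(sq[sj]) <= nchar(sq[si]) && sj != si &&
          grepl(sq[sj], sq[si], fixed = TRUE) && sq[sj] != sq[si]) {
        contained[sj] <- TRUE
      }
    }
  }
  contigs[!contained, , drop = FALSE]
}

#' Triage a whole contig set
#'
#' Applies [classify_contig()] to every contig and
#' [trim_to_viral_homology()] + [dedupe_contigs()] to the candidates.
#'
#' @param contigs Contig data.frame (`id`, `sequence`).
#' @param host_hits,viral_hits,prok_hits Full hit tables (all contigs).
#' @param config A [pipeline_config()].
#' @return A list: `summary` (data.frame contig_id, status,
#'   best_viral_evalue), `results` (list of `triage_result`), `trimmed`
#'   (de-duplicated trimmed-fragment data.frame) and `untrimmed_candidates`
#'   (the candidates' full sequences, kept separately as mixed-homology
#'   records).
#' @export
triage_contigs <- function(contigs, host_hits, viral_hits, prok_hits,
                           config = pipeline_config()) {
  config <- as_config(config)
  results <- vector("list", nrow(contigs))
  trimmed <- list()
  for (i in seq_len(nrow(contigs))) {
    id <- contigs$id[i]
    r <- classify_contig(
      contigs[i, , drop = FALSE],
      host_hits[host_hits$qid == id, , drop = FALSE],
      viral_hits[viral_hits$qid == id, , drop = FALSE],
      prok_hits[prok_hits$qid == id, , drop = FALSE],
      config)
    results[[i]] <- r
    if (r$status == "viral_candidate") {
      tr <- trim_to_viral_homology(contigs[i, , drop = FALSE], r, config)
      if (nrow(tr)) trimmed[[length(trimmed) + 1L]] <- tr
    }
  }
  summary <- data.frame(
    contig_id = contigs$id,
    status = vapply(results, `[[`, "", "status"),
    best_viral_evalue = vapply(results, function(r) {
      if (is.null(r$best_viral_hit)) NA_real_ else r$best_viral_hit$evalue
    }, 0.0),
    stringsAsFactors = FALSE)
  trimmed <- if (length(trimmed)) do.call(rbind, trimmed) else
    data.frame(id = character(0), parent_id = character(0),
               start = integer(0), end = integer(0),
               sequence = character(0))
  cand_ids <- summary$contig_id[summary$status == "viral_candidate"]
  list(summary = summary,
       results = results,
       trimmed = dedupe_contigs(trimmed),
       untrimmed_candidates = contigs[contigs$id %in% cand_ids, ,
                                      drop = FALSE])
}
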