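#' Best hit among a contig's homology hits
#'
#' Deterministic ranking: minimum e-value wins; ties are broken by maximum
#' bitscore, then by lexicographically smallest subject id, so the result
#' never depends on input order.
#'
#' @param hits Hit data.frame sharing one `qid`.
#' @return A one-row data.frame, or `NULL` for an empty input.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  o <- order(hits$evalue, -hits$bitscore, hits$sid)
  hits[o[1L], , drop = FALSE]
}

#' Screen candidates against an all-proteins database
#'
#' Second identification step: remove candidates of clear non-viral
#' origin. After gating hits at `e <= screen_evalue`, a candidate is kept
#' when its best gated hit is a viral protein, or when it has no gated hit
#' at all (no clear homology to any protein is not evidence against viral
#' origin). Candidates whose best hit is cellular are dropped.
#'
#' @param candidates Data.frame of candidate sequences (`id`, `sequence`).
#' @param hits Hit table over all candidates (`qid` = candidate id).
#' @param subjects Data.frame classifying subjects: columns `sid`,
#'   `taxid` (optional) and `class_label` in `{virus, cellular, unknown}`.
#' @param config A [pipeline_config()].
#' @return A list: `kept` (data.frame subset of `candidates`) and
#'   `drop_log` (data.frame contig, step, reason, subject, evalue).
#' @export
screen_against_all_proteins <- function(candidates, hits, subjects,
                                        config = pipeline_config()) {
  config <- as_config(config)
  missing_sid <- setdiff(unique(hits$sid), subjects$sid)
  if (length(missing_sid)) {
    stop("subject id(s) in hits absent from subjects table: ",
         paste(utils::head(missing_sid, 5L), collapse = ", "), call. = FALSE)
  }
  gated <- hits[hits$evalue <= config$screen_evalue, , drop = FALSE]
  keep <- logical(nrow(candidates))
  drops <- list()
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$id[i]
    b <- best_hit(gated[gated$qid == id, , drop = FALSE])
    if (is.null(b)) {
      keep[i] <- TRUE          # no clear homology to any protein
      next
    }
    cls <- subjects$class_label[match(b$sid, subjects$sid)]
    if (identical(cls, "virus")) {
      keep[i] <- TRUE
    } else {
      drops[[length(drops) + 1L]] <- data.frame(
        contig = id, step = "all_proteins_screen",
        reason = paste0("best hit ", cls), subject = b$sid,
        evalue = b$evalue, stringsAsFactors = FALSE)
    }
  }
  drop_log <- if (length(drops)) do.call(rbind, drops) else
    data.frame(contig = character(0), step = character(0),
               reason = character(0), subject = character(0),
               evalue = numeric(0))
  list(kept = candidates[keep, , drop = FALSE], drop_log = drop_log)
}

#' Is a taxon a eukaryotic virus?
#'
#' Climbs the lineage from `taxid` to the root and reports `TRUE` when the
#' lineage passes through the virus root node and no lineage name belongs
#' to the prokaryote-infecting-virus exclusion set (phage families and
#' their ancestors).
#'
#' @param taxid Integer taxon id.
#' @param taxonomy A `taxonomy` table (see [read_taxdump()]).
#' @param prokaryotic_virus_families Character vector of excluded lineage
#'   names.
#' @param virus_root_name Name of the virus superkingdom node.
#' @return Logical scalar.
#' @export
lineage_is_eukaryotic_virus <- function(taxid, taxonomy,
                                        prokaryotic_virus_families = character(0),
                                        virus_root_name = "Viruses") {
  lin <- lineage_names(taxid, taxonomy)
  if (!(virus_root_name %in% lin)) return(FALSE)
  !any(lin %in% prokaryotic_virus_families)
}

# all scientific names on the path taxid -> root (inclusive)
lineage_names <- function(taxid, taxonomy) {
  idx <- match(taxid, taxonomy$taxid)
  if (is.na(idx)) stop("unknown taxid: ", taxid, call. = FALSE)
  root <- attr(taxonomy, "root_taxid")
  out <- character(0)
  steps <- 0L
  cur <- idx
  repeat {
    out <- c(out, taxonomy$name[cur])
    tid <- taxonomy$taxid[cur]
    if (tid == root || taxonomy$parent_taxid[cur] == tid) break
    steps <- steps + 1L
    if (steps > nrow(taxonomy)) {
      stop("cycle detected in taxonomy while climbing from taxid ", taxid,
           call. = FALSE)
    }
    cur <- match(taxonomy$parent_taxid[cur], taxonomy$taxid)
  }
  out
}

#' Confirm candidates as eukaryotic viruses
#'
#' Final identification step. Hits are gated at `e <= confirm_evalue`;
#' a candidate is kept only when its best gated hit exists and that hit's
#' subject taxon lies in a eukaryotic-virus lineage. Unlike the
#' all-proteins screen, candidates with no gated hit are dropped here:
#' without identifiable homology to a known eukaryotic virus a sequence
#' cannot be confirmed (novel viruses with no homology are knowingly
#' overlooked).
#'
#' @param candidates Data.frame of screened candidates (`id`, `sequence`).
#' @param hits Hit table with an `staxid` column.
#' @param taxonomy A `taxonomy` table.
#' @param config A [pipeline_config()].
#' @param prokaryotic_virus_families Excluded lineage names (see
#'   [lineage_is_eukaryotic_virus()]).
#' @return A list: `kept` (confirmed candidates, with `best_taxid` column
#'   appended), and `drop_log` as in [screen_against_all_proteins()].
#' @export
confirm_eukaryotic_viral <- function(candidates, hits, taxonomy,
                                     config = pipeline_config(),
                                     prokaryotic_virus_families = character(0)) {
  config <- as_config(config)
  if (!"staxid" %in% names(hits)) {
    stop("confirmation hits must carry an 'staxid' column", call. = FALSE)
  }
  gated <- hits[hits$evalue <= config$confirm_evalue, , drop = FALSE]
  keep <- logical(nrow(candidates))
  best_taxid <- rep(NA_integer_, nrow(candidates))
  drops <- list()
  add_drop <- function(id, reason, subject = NA_character_,
                       evalue = NA_real_) {
    drops[[length(drops) + 1L]] <<- data.frame(
      contig = id, step = "eukaryotic_virus_confirmation", reason = reason,
      subject = subject, evalue = evalue, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$id[i]
    b <- best_hit(gated[gated$qid == id, , drop = FALSE])
    if (is.null(b)) {
      add_drop(id, "no gated hit")
      next
    }
    if (is.na(b$staxid)) {
      stop("gated hit without subject taxid for contig ", id, call. = FALSE)
    }
    if (lineage_is_eukaryotic_virus(b$staxid, taxonomy,
                                    prokaryotic_virus_families)) {
      keep[i] <- TRUE
      best_taxid[i] <- b$staxid
    } else {
      add_drop(id, "best hit not a eukaryotic virus", b$sid, b$evalue)
    }
  }
  kept <- candidates[keep, , drop = FALSE]
  kept$best_taxid <- best_taxid[keep]
  drop_log <- if (length(drops)) do.call(rbind, drops) else
    data.frame(contig = character(0), step = character(0),
               reason = character(0), subject = character(0),
               evalue = numeric(0))
  list(kept = kept, drop_log = drop_log)
}
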