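#' Climb a taxonomy to the family rank
#'
#' Follows parent links from `taxid` upward and returns the first node
#' whose rank is `family`. A taxid that is itself of family rank returns
#' itself. When the root is reached without meeting a family node the
#' climb is unresolved. The walk is bounded by the number of nodes, so a
#' malformed (cyclic) table raises an error instead of looping.
#'
#' @param taxid Integer taxon id.
#' @param taxonomy A `taxonomy` table (see [read_taxdump()]).
#' @return The family taxid, or `NA_integer_` when unresolved.
#' @export
climb_to_family <- function(taxid, taxonomy) {
  idx <- match(taxid, taxonomy$taxid)
  if (is.na(idx)) stop("unknown taxid: ", taxid, call. = FALSE)
  root <- attr(taxonomy, "root_taxid")
  steps <- 0L
  visited <- integer(0)
  cur <- idx
  repeat {
    tid <- taxonomy$taxid[cur]
    if (taxonomy$rank[cur] == "family") return(tid)
    if (tid == root || taxonomy$parent_taxid[cur] == tid) {
      return(NA_integer_)
    }
    visited <- c(visited, tid)
    steps <- steps + 1L
    if (steps > nrow(taxonomy)) {
      stop("cycle detected while climbing from taxid ", taxid,
           " (visited: ", paste(utils::tail(visited, 5L), collapse = " -> "),
           ")", call. = FALSE)
    }
    cur <- match(taxonomy$parent_taxid[cur], taxonomy$taxid)
  }
}

#' Genome-composition groups
#'
#' The closed set of genome-composition labels a confirmed viral contig
#' can receive.
#' @export
GENOME_GROUPS <- c("dsDNA", "ssRNA_positive", "ssRNA_negative", "dsRNA",
                   "ssDNA", "retro", "unclassified_RNA", "unclassified")

#' Annotate a confirmed viral contig at the family level
#'
#' Assigns a species label (the best hit's organism name), a family label
#' obtained by taxonomy climbing — with ordered fallback rules for taxa
#' whose lineage carries no family rank (unassigned orders, unclassified
#' groups) — a genome-composition group, and a flag for consistency with a
#' user-supplied reference family list (e.g. an ICTV master species list
#' rendered as one family name per line).
#'
#' @param contig_id Contig identifier.
#' @param best_hit_taxid Taxid of the contig's best confirmation hit.
#' @param taxonomy A `taxonomy` table.
#' @param ictv_families Character vector of accepted family names.
#' @param group_rules Ordered data.frame of fallback rules with columns
#'   `node_name`, `label`, `genome_group`: the first rule whose
#'   `node_name` occurs in the lineage supplies the family label and
#'   genome group when no family rank is found.
#' @param genome_table Data.frame mapping `family` name to `genome_group`.
#' @return A one-row data.frame: `contig_id`, `species_label`,
#'   `family_label`, `genome_group`, `ictv_consistent`.
#' @export
annotate_contig <- function(contig_id, best_hit_taxid, taxonomy,
                            ictv_families = character(0),
                            group_rules = NULL,
                            genome_table = NULL) {
  species <- taxonomy$name[match(best_hit_taxid, taxonomy$taxid)]
  if (is.na(species)) stop("unknown taxid: ", best_hit_taxid, call. = FALSE)
  fam_taxid <- climb_to_family(best_hit_taxid, taxonomy)
  lin <- lineage_names(best_hit_taxid, taxonomy)
  family_label <- NA_character_
  genome_group <- "unclassified"
  ictv <- FALSE
  if (!is.na(fam_taxid)) {
    family_label <- taxonomy$name[match(fam_taxid, taxonomy$taxid)]
    ictv <- family_label %in% ictv_families
    if (!is.null(genome_table)) {
      g <- genome_table$genome_group[match(family_label, genome_table$family)]
      if (!is.na(g)) genome_group <- g
    }
  } else if (!is.null(group_rules) && nrow(group_rules)) {
    for (r in seq_len(nrow(group_rules))) {
      if (group_rules$node_name[r] %in% lin) {
        family_label <- group_rules$label[r]
        genome_group <- group_rules$genome_group[r]
        break
      }
    }
  }
  if (is.na(family_label)) family_label <- "unclassified"
  if (!genome_group %in% GENOME_GROUPS) {
    stop("genome group '", genome_group, "' not in the closed set",
         call. = FALSE)
  }
  data.frame(contig_id = contig_id, species_label = species,
             family_label = family_label, genome_group = genome_group,
             ictv_consistent = ictv, stringsAsFactors = FALSE)
}

#' Annotate a set of confirmed contigs
#'
#' Vectorized driver for [annotate_contig()]; every confirmed contig gets
#' exactly one family label and one genome group.
#'
#' @param confirmed Data.frame with columns `id` and `best_taxid`
#'   (as produced by [confirm_eukaryotic_viral()]).
#' @inheritParams annotate_contig
#' @return A data.frame, one annotation row per contig.
#' @export
annotate_contigs <- function(confirmed, taxonomy,
                             ictv_families = character(0),
                             group_rules = NULL, genome_table = NULL) {
  rows <- lapply(seq_len(nrow(confirmed)), function(i) {
    annotate_contig(confirmed$id[i], confirmed$best_taxid[i], taxonomy,
                    ictv_families, group_rules, genome_table)
  })
  if (!length(rows)) {
    return(data.frame(contig_id = character(0), species_label = character(0),
                      family_label = character(0), genome_group = character(0),
                      ictv_consistent = logical(0)))
  }
  do.call(rbind, rows)
}

#' Family composition of an annotation set
#'
#' Percentage of annotated entries per family label, optionally after
#' collapsing contigs of the same species to one entry. Percentages sum
#' to 100.
#'
#' @param annotations Annotation data.frame (see [annotate_contigs()]).
#' @param collapse_species Collapse same-species contigs before counting?
#' @return A data.frame `family_label`, `n`, `percent`, sorted by
#'   decreasing percentage.
#' @export
family_composition <- function(annotations, collapse_species = TRUE) {
  a <- annotations
  if (collapse_species) a <- a[!duplicated(a$species_label), , drop = FALSE]
  tab <- table(a$family_label)
  out <- data.frame(family_label = names(tab), n = as.integer(tab),
                    percent = 100 * as.integer(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$percent, out$family_label), , drop = FALSE]
}
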