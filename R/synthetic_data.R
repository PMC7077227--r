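#' Generate a synthetic viral community with known ground truth
#'
#' Builds the stand-in world for offline testing of every pipeline stage:
#' a host genome, planted viral species with known family lineages, a
#' taxonomy table containing the virus root plus cellular and phage decoy
#' lineages, per-dataset abundance profiles and the planted core /
#' unique / food-shared structure. Defaults echo the study system the
#' pipeline was designed for: 21 viral species (the size of a typical
#' anemone core virome), seven host datasets of which the first is an
#' embryonic library with zero expected viral load, two food-source
#' sequencing replicates, one rRNA-depleted library among the adult
#' datasets, and contig lengths in the 300-8000 nt range.
#'
#' @param n_species Number of planted viral species.
#' @param n_datasets Number of host datasets (the first is embryonic).
#' @param fraction_core Fraction of species planted in every non-embryonic
#'   dataset (the always-present set); count = `round(fraction * n)`.
#' @param fraction_food Fraction of species also present in both food
#'   replicates.
#' @param seed Integer seed; the truth is deterministic given the seed.
#' @return A list of class `synthetic_truth`; see Details.
#' @details Fields: `host_genome` (one-row contig data.frame), `species`
#'   (data.frame: species, taxid, family, genome_group, length, sequence,
#'   n_fragments), `contigs` (contig data.frame with `species` column),
#'   `always_present`, `food_shared`, `unique_species` (named by
#'   dataset), `abundance` (species x dataset expected relative weights),
#'   `datasets` (metadata data.frame), `taxonomy`, `subjects`,
#'   `prokaryotic_virus_families`, `group_rules`, `genome_table`,
#'   `ictv_families`, `seed`.
#' @export
generate_community <- function(n_species = 21L, n_datasets = 7L,
                               fraction_core = 0.33, fraction_food = 0.29,
                               seed = 1L) {
  if (n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  if (n_datasets < 2L) stop("need >= 2 datasets (one embryonic)", call. = FALSE)
  if (fraction_core < 0 || fraction_core > 1 ||
      fraction_food < 0 || fraction_food > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  withr_seed(seed)

  ds_host <- c("embryonic",
               sprintf("adult_%02d", seq_len(n_datasets - 1L)))
  ds_food <- c("food_rep1", "food_rep2")
  enrichment <- c("polyA",
                  if (n_datasets >= 2L) "rRNA_depleted",
                  if (n_datasets >= 3L) "unknown",
                  rep("polyA", max(0L, n_datasets - 3L)))
  md <- data.frame(
    dataset_id = c(ds_host, ds_food),
    raw_read_pairs = 0L, retained_reads = 0L,
    enrichment = c(enrichment, "polyA", "polyA"),
    role = c("embryonic", rep("non_embryonic", n_datasets - 1L),
             "food", "food"),
    stringsAsFactors = FALSE)

  fam_pool <- data.frame(
    family = c("Iridoviridae", "Rhabdoviridae", "Yueviridae",
               "Baculoviridae", "Reoviridae", "Phycodnaviridae",
               "Mimiviridae", "Marseilleviridae", "Retroviridae",
               "Picornaviridae"),
    genome_group = c("dsDNA", "ssRNA_negative", "ssRNA_negative",
                     "dsDNA", "dsRNA", "dsDNA", "dsDNA", "dsDNA",
                     "retro", "ssRNA_positive"),
    stringsAsFactors = FALSE)

  # roughly one species in five sits in a clade with no family rank
  sp_names <- sprintf("synthetic virus %02d", seq_len(n_species))
  unclassified <- seq_len(n_species) %% 5L == 0L
  fam_idx <- ((seq_len(n_species) - 1L) %% nrow(fam_pool)) + 1L
  family <- ifelse(unclassified, NA_character_, fam_pool$family[fam_idx])
  genome_group <- ifelse(unclassified, "unclassified_RNA",
                         fam_pool$genome_group[fam_idx])
  lens <- sample(300:8000, n_species, replace = TRUE)
  n_fragments <- ifelse(lens >= 2000L & stats::runif(n_species) < 0.3, 2L, 1L)
  sequences <- vapply(lens, random_dna, "")

  taxonomy <- build_synthetic_taxonomy(sp_names, family, fam_pool$family)
  sp_taxid <- taxonomy$taxid[match(sp_names, taxonomy$name)]
  species <- data.frame(
    species = sp_names, taxid = sp_taxid, family = family,
    genome_group = genome_group, length = lens, sequence = sequences,
    n_fragments = n_fragments, stringsAsFactors = FALSE)

  contigs <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    if (species$n_fragments[i] == 1L) {
      data.frame(id = sprintf("ctg_sp%02d_1", i),
                 sequence = species$sequence[i],
                 species = species$species[i], stringsAsFactors = FALSE)
    } else {
      L <- species$length[i]
      a <- floor(L * 0.45); b <- floor(L * 0.55)
      data.frame(id = sprintf("ctg_sp%02d_%d", i, 1:2),
                 sequence = c(substr(species$sequence[i], 1L, a),
                              substr(species$sequence[i], b, L)),
                 species = species$species[i], stringsAsFactors = FALSE)
    }
  }))

  n_core <- round(fraction_core * n_species)
  n_food <- round(fraction_food * n_species)
  core <- sort(sample(sp_names, n_core))
  non_core <- setdiff(sp_names, core)
  incl <- ds_host[-1L]
  n_unique <- min(length(non_core), length(incl))
  uniq_sp <- if (n_unique) sample(non_core, n_unique) else character(0)
  unique_species <- stats::setNames(as.list(uniq_sp), incl[seq_len(n_unique)])
  food <- sort(sample(sp_names, n_food))

  # expected relative weights, log-uniform in [1, 6]: bounded away from
  # zero so realized multinomial counts of planted species are never
  # silently absent, and bounded above so no species starves the rest
  all_ds <- c(ds_host, ds_food)
  ab <- matrix(0, n_species, length(all_ds),
               dimnames = list(sp_names, all_ds))
  w <- function(n) exp(stats::runif(n, 0, log(6)))
  for (sp in sp_names) {
    present_in <- if (sp %in% core) {
      incl
    } else if (sp %in% uniq_sp) {
      names(unique_species)[vapply(unique_species, identical, TRUE, sp)]
    } else if (length(incl) >= 3L) {
      # 2..(n-1) datasets: never unique to one, never present in all,
      # so planted unique and core sets are recoverable exactly
      sample(incl, sample(2:(length(incl) - 1L), 1L))
    } else if (length(incl) >= 1L) {
      sample(incl, 1L)   # degenerate small worlds: clash unavoidable
    } else {
      character(0)
    }
    ab[sp, present_in] <- w(length(present_in))
  }
  ab[food, ds_food] <- w(2L * length(food))

  truth <- list(
    host_genome = data.frame(id = "host_genome",
                             sequence = random_dna(20000L),
                             stringsAsFactors = FALSE),
    species = species, contigs = contigs,
    always_present = core, food_shared = food,
    unique_species = unique_species,
    abundance = ab, datasets = md, taxonomy = taxonomy,
    subjects = build_synthetic_subjects(species, taxonomy),
    prokaryotic_virus_families = "Siphoviridae",
    group_rules = data.frame(
      node_name = "unclassified RNA viruses",
      label = "unclassified RNA viruses",
      genome_group = "unclassified_RNA", stringsAsFactors = FALSE),
    genome_table = fam_pool,
    ictv_families = fam_pool$family,
    seed = as.integer(seed))
  class(truth) <- "synthetic_truth"
  truth
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# save/restore the global RNG around generator calls
withr_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
    # register restoration in the caller's frame
    do.call(on.exit, list(expr, add = TRUE), envir = parent.frame())
  }
  set.seed(seed)
  invisible(NULL)
}

build_synthetic_taxonomy <- function(sp_names, family, fam_pool_names) {
  rows <- list(
    c(1L, 1L, "no rank", "root"),
    c(2L, 1L, "superkingdom", "Viruses"),
    c(3L, 1L, "superkingdom", "Bacteria"),
    c(4L, 1L, "superkingdom", "Eukaryota"),
    c(5L, 2L, "order", "Caudovirales"),
    c(6L, 5L, "family", "Siphoviridae"),
    c(7L, 6L, "species", "synthetic phage 1"),
    c(8L, 3L, "species", "synthetic bacterium 1"),
    c(9L, 4L, "species", "synthetic metazoan 1"),
    c(10L, 2L, "clade", "unclassified RNA viruses"))
  fam_taxid <- stats::setNames(100L + seq_along(fam_pool_names),
                               fam_pool_names)
  for (f in fam_pool_names) {
    rows[[length(rows) + 1L]] <- c(fam_taxid[[f]], 2L, "family", f)
  }
  for (i in seq_along(sp_names)) {
    parent <- if (is.na(family[i])) 10L else fam_taxid[[family[i]]]
    rows[[length(rows) + 1L]] <- c(200L + i, parent, "species", sp_names[i])
  }
  tax <- data.frame(
    taxid = as.integer(vapply(rows, `[[`, "", 1L)),
    parent_taxid = as.integer(vapply(rows, `[[`, "", 2L)),
    rank = vapply(rows, `[[`, "", 3L),
    name = vapply(rows, `[[`, "", 4L), stringsAsFactors = FALSE)
  attr(tax, "root_taxid") <- 1L
  class(tax) <- c("taxonomy", "data.frame")
  tax
}

build_synthetic_subjects <- function(species, taxonomy) {
  viral <- data.frame(
    sid = sprintf("vp_%s", gsub(" ", "_", species$species)),
    taxid = species$taxid, class_label = "virus", stringsAsFactors = FALSE)
  phage_taxid <- taxonomy$taxid[taxonomy$name == "synthetic phage 1"]
  cell_taxid <- taxonomy$taxid[taxonomy$name == "synthetic bacterium 1"]
  rbind(viral,
        data.frame(sid = "vp_phage", taxid = phage_taxid,
                   class_label = "virus", stringsAsFactors = FALSE),
        data.frame(sid = sprintf("cell_prot_%d", 1:3), taxid = cell_taxid,
                   class_label = "cellular", stringsAsFactors = FALSE))
}

#' Emit homology-hit tables and contig FASTA for a synthetic community
#'
#' Writes every file the identification stages read, consistent with the
#' planted truth: viral contigs receive full-span viral-protein hits below
#' the triage cutoff and confirmation hits carrying their species taxid;
#' host-genome fragments receive strong host hits; prokaryote decoys
#' receive prokaryote-protein hits; a phage decoy passes triage and the
#' protein screen but fails eukaryotic-virus confirmation; a cellular
#' look-alike passes triage but is dropped by the all-proteins screen.
#' E-values are drawn log-uniformly within strata placed relative to the
#' pipeline cutoffs, so decision outcomes are deterministic.
#'
#' @param truth A `synthetic_truth` object.
#' @param noise Probability that a viral contig also receives a decoy
#'   cellular screen hit with an e-value above the screen cutoff
#'   (harmless by construction; exercises the gating).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
emit_hit_tables <- function(truth, noise = 0, seed = truth$seed,
                            dir = tempfile("synth_")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  withr_seed(seed + 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loge <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

  vc <- truth$contigs
  host_frag <- function(i) {
    start <- (i - 1L) * 1500L + 1L
    substr(truth$host_genome$sequence, start, start + 999L)
  }
  decoys <- data.frame(
    id = c(sprintf("ctg_host_%d", 1:3), sprintf("ctg_prok_%d", 1:2),
           "ctg_phage_1", "ctg_celllike_1", "ctg_nohit_1"),
    sequence = c(vapply(1:3, host_frag, ""),
                 vapply(rep(900L, 2L), random_dna, ""),
                 random_dna(1200L), random_dna(800L), random_dna(500L)),
    stringsAsFactors = FALSE)
  contigs <- rbind(vc[, c("id", "sequence")], decoys)

  hit_row <- function(qid, sid, e, qlen, staxid = NULL) {
    r <- data.frame(qid = qid, sid = sid, pident = 90, aln_len = qlen,
                    mismatch = 10L, gapopen = 1L, qstart = 1L, qend = qlen,
                    sstart = 1L, send = qlen, evalue = e, bitscore = 200,
                    stringsAsFactors = FALSE)
    if (!is.null(staxid)) r$staxid <- staxid
    r
  }
  qlen <- nchar(vc$sequence)
  vp_sid <- sprintf("vp_%s", gsub(" ", "_", vc$species))
  sp_taxid <- truth$species$taxid[match(vc$species, truth$species$species)]

  host_hits <- do.call(rbind, lapply(1:3, function(i) {
    hit_row(sprintf("ctg_host_%d", i), "host_genome",
            loge(1L, 1e-60, 1e-30), 1000L)
  }))
  viral_hits <- rbind(
    hit_row(vc$id, vp_sid, loge(nrow(vc), 1e-30, 1e-8), qlen),
    hit_row("ctg_phage_1", "vp_phage", 1e-20, 1200L),
    hit_row("ctg_celllike_1", "vp_synthetic_virus_01", 1e-6, 800L))
  prok_hits <- do.call(rbind, lapply(1:2, function(i) {
    hit_row(sprintf("ctg_prok_%d", i), sprintf("cell_prot_%d", i),
            loge(1L, 1e-30, 1e-12), 900L)
  }))
  screen_hits <- rbind(
    hit_row(vc$id, vp_sid, loge(nrow(vc), 1e-30, 1e-12), qlen),
    hit_row("ctg_phage_1", "vp_phage", 1e-20, 1200L),
    hit_row("ctg_celllike_1", "cell_prot_3", 1e-40, 800L),
    hit_row("ctg_celllike_1", "vp_synthetic_virus_01", 1e-6, 800L))
  if (noise > 0) {
    noisy <- vc$id[stats::runif(nrow(vc)) < noise]
    if (length(noisy)) {
      screen_hits <- rbind(
        screen_hits,
        hit_row(noisy, "cell_prot_1",
                loge(length(noisy), 1e-9, 1e-2),
                qlen[match(noisy, vc$id)]))
    }
  }
  phage_taxid <- truth$taxonomy$taxid[truth$taxonomy$name ==
                                        "synthetic phage 1"]
  confirm_hits <- rbind(
    hit_row(vc$id, sprintf("refseq_%s", gsub(" ", "_", vc$species)),
            loge(nrow(vc), 1e-30, 1e-12), qlen, staxid = sp_taxid),
    hit_row("ctg_phage_1", "refseq_phage", 1e-20, 1200L,
            staxid = phage_taxid))

  paths <- list(
    contigs = file.path(dir, "contigs.fasta"),
    host_hits = file.path(dir, "host_hits.tsv"),
    viral_hits = file.path(dir, "viral_hits.tsv"),
    prok_hits = file.path(dir, "prok_hits.tsv"),
    screen_hits = file.path(dir, "screen_hits.tsv"),
    screen_subjects = file.path(dir, "screen_subjects.tsv"),
    confirm_hits = file.path(dir, "confirm_hits.tsv"),
    nodes = file.path(dir, "nodes.dmp"),
    names = file.path(dir, "names.dmp"),
    exclusion_list = file.path(dir, "prok_virus_families.txt"),
    ictv_families = file.path(dir, "ictv_families.txt"),
    genome_groups = file.path(dir, "genome_groups.tsv"),
    group_rules = file.path(dir, "group_rules.tsv"),
    truth_manifest = file.path(dir, "truth.json"))
  write_fasta(contigs, paths$contigs)
  write_homology_table(host_hits, paths$host_hits)
  write_homology_table(viral_hits, paths$viral_hits)
  write_homology_table(prok_hits, paths$prok_hits)
  write_homology_table(screen_hits, paths$screen_hits)
  write_homology_table(confirm_hits, paths$confirm_hits)
  utils::write.table(truth$subjects, paths$screen_subjects, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_taxdump(truth$taxonomy, paths$nodes, paths$names)
  writeLines(truth$prokaryotic_virus_families, paths$exclusion_list)
  writeLines(truth$ictv_families, paths$ictv_families)
  utils::write.table(truth$genome_table, paths$genome_groups, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$group_rules, paths$group_rules, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(truth_manifest(truth), auto_unbox = TRUE,
                              pretty = TRUE), paths$truth_manifest)
  invisible(paths)
}

truth_manifest <- function(truth) {
  sp2ctg <- split(truth$contigs$id, truth$contigs$species)
  incl <- truth$datasets$dataset_id[truth$datasets$role == "non_embryonic"]
  list(
    seed = truth$seed,
    species = truth$species$species,
    contigs = stats::setNames(sp2ctg[truth$species$species],
                              truth$species$species),
    viral_contigs = truth$contigs$id,
    always_present = truth$always_present,
    core_contigs = sort(unlist(sp2ctg[truth$always_present],
                               use.names = FALSE)),
    food_shared = truth$food_shared,
    food_shared_contigs = sort(unlist(sp2ctg[truth$food_shared],
                                      use.names = FALSE)),
    unique_species = truth$unique_species,
    included_datasets = incl,
    food_replicates = truth$datasets$dataset_id[truth$datasets$role == "food"])
}

#' Emit remapping count tables for a synthetic community
#'
#' Draws per-dataset contig counts multinomially from the planted
#' abundance profile scaled to a viral read total derived from the
#' dataset depth: the embryonic dataset has zero viral expectation, the
#' rRNA-depleted library captures viral reads at several times the polyA
#' rate, and species weights are split across a species' contig
#' fragments.
#'
#' @param truth A `synthetic_truth` object.
#' @param depth_per_dataset Raw read pairs per dataset: scalar or vector
#'   named by dataset id.
#' @param viral_rate Expected fraction of reads that are viral in a polyA
#'   library.
#' @param rrna_boost Multiplier on `viral_rate` for rRNA-depleted
#'   libraries.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Named list with `counts` (path), `metadata` (path),
#'   `count_matrix` and `metadata_table`, invisibly.
#' @export
emit_count_tables <- function(truth, depth_per_dataset = 1e6,
                              viral_rate = 0.01, rrna_boost = 8,
                              seed = truth$seed, dir = tempfile("synth_")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  withr_seed(seed + 2L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- truth$datasets
  depth <- if (length(depth_per_dataset) == 1L) {
    stats::setNames(rep(depth_per_dataset, nrow(md)), md$dataset_id)
  } else depth_per_dataset[md$dataset_id]
  if (any(depth <= 0)) stop("depths must be > 0", call. = FALSE)
  md$raw_read_pairs <- as.integer(round(depth))
  md$retained_reads <- as.integer(round(0.6 * depth))

  # species weights split over fragments 60/40
  ctg <- truth$contigs
  frag_w <- stats::setNames(rep(1, nrow(ctg)), ctg$id)
  for (sp in unique(ctg$species[duplicated(ctg$species)])) {
    frag_w[ctg$species == sp] <- c(0.6, 0.4)
  }
  counts <- matrix(0L, nrow(ctg), nrow(md),
                   dimnames = list(ctg$id, md$dataset_id))
  for (d in md$dataset_id) {
    wsp <- truth$abundance[, d]
    wct <- wsp[ctg$species] * frag_w[ctg$id]
    tot_w <- sum(wct)
    if (tot_w == 0) next
    rate <- viral_rate *
      if (md$enrichment[md$dataset_id == d] == "rRNA_depleted") rrna_boost else 1
    size <- as.integer(round(rate * depth[[d]]))
    counts[, d] <- as.integer(stats::rmultinom(1L, size, wct / tot_w))
  }
  paths <- list(counts = file.path(dir, "counts.tsv"),
                metadata = file.path(dir, "metadata.tsv"))
  write_count_table(counts, paths$counts)
  utils::write.table(md, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(count_matrix = counts, metadata_table = md)))
}
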