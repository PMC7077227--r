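#' Read a subject-classification table
#'
#' TSV with columns `sid`, `taxid`, `class_label` (virus / cellular /
#' unknown), classifying the subjects of the all-proteins screen.
#'
#' @param path Path to the TSV.
#' @return A validated data.frame.
#' @export
read_subject_classes <- function(path) {
  if (!file.exists(path)) stop("subjects table not found: ", path, call. = FALSE)
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sid", "taxid", "class_label")
  miss <- setdiff(req, names(s))
  if (length(miss)) {
    stop("subjects table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(s$class_label, c("virus", "cellular", "unknown"))
  if (length(bad)) {
    stop("unknown class_label value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s
}

read_group_rules <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("node_name", "label", "genome_group") %in% names(r)))
  r
}

#' Run the full virome-characterization pipeline
#'
#' Executes the stages in order on the files named by a JSON
#' configuration: contig triage against the three simultaneous searches,
#' homology trimming and duplicate clearing, the all-proteins screen,
#' eukaryotic-virus confirmation, family-level annotation, abundance
#' quantification (TPM/1000, species collapsing, per-dataset RPM and
#' z-scores), and the presence/absence core-virome analysis with Venn
#' regions and food-shared flagging. All referenced inputs are checked
#' before any stage runs; outputs are deterministic, so an identical
#' rerun reproduces them byte for byte.
#'
#' @param config_path Path to a JSON run configuration with members
#'   `inputs` (file paths: contigs, host_hits, viral_hits, prok_hits,
#'   screen_hits, screen_subjects, confirm_hits, nodes, names,
#'   exclusion_list; optional: ictv_families, genome_groups, group_rules,
#'   counts, metadata, food_replicates), optional `thresholds`
#'   (overrides of [pipeline_config()] fields) and `outdir`.
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   written as `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("config not found: ", config_path, call. = FALSE)
  }
  rc <- jsonlite::fromJSON(config_path, simplifyVector = TRUE)
  if (is.null(rc$inputs)) stop("config must have an 'inputs' member", call. = FALSE)
  known_thresholds <- names(formals(pipeline_config))
  extra <- setdiff(names(rc$thresholds), known_thresholds)
  if (length(extra)) {
    stop("unknown threshold key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  config <- do.call(pipeline_config, as.list(rc$thresholds))
  outdir <- if (is.null(rc$outdir)) dirname(config_path) else rc$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  req <- c("contigs", "host_hits", "viral_hits", "prok_hits",
           "screen_hits", "screen_subjects", "confirm_hits",
           "nodes", "names", "exclusion_list")
  inp <- rc$inputs
  miss <- setdiff(req, names(inp))
  if (length(miss)) {
    stop("config missing required input(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  file_keys <- setdiff(names(inp), "food_replicates")
  for (k in file_keys) {
    if (!file.exists(inp[[k]])) {
      stop("input file for '", k, "' not found: ", inp[[k]], call. = FALSE)
    }
  }

  contigs <- read_fasta(inp$contigs)
  host_hits <- read_homology_table(inp$host_hits)
  viral_hits <- read_homology_table(inp$viral_hits)
  prok_hits <- read_homology_table(inp$prok_hits)
  screen_hits <- read_homology_table(inp$screen_hits)
  subjects <- read_subject_classes(inp$screen_subjects)
  confirm_hits <- read_homology_table(inp$confirm_hits, has_taxid = TRUE)
  taxonomy <- read_taxdump(inp$nodes, inp$names)
  excl <- readLines(inp$exclusion_list)
  ictv <- if (!is.null(inp$ictv_families)) readLines(inp$ictv_families)
          else character(0)
  genome_table <- if (!is.null(inp$genome_groups)) {
    g <- utils::read.delim(inp$genome_groups, stringsAsFactors = FALSE)
    stopifnot(all(c("family", "genome_group") %in% names(g)))
    g
  } else NULL
  group_rules <- if (!is.null(inp$group_rules))
    read_group_rules(inp$group_rules) else NULL

  stage <- list()

  tri <- triage_contigs(contigs, host_hits, viral_hits, prok_hits, config)
  stage$triage <- c(list(input = nrow(contigs)),
                    as.list(table(tri$summary$status)))
  scr <- screen_against_all_proteins(tri$trimmed, screen_hits, subjects,
                                     config)
  stage$screen <- list(input = nrow(tri$trimmed), kept = nrow(scr$kept),
                       dropped = nrow(scr$drop_log))
  conf <- confirm_eukaryotic_viral(scr$kept, confirm_hits, taxonomy,
                                   config, excl)
  stage$confirm <- list(input = nrow(scr$kept), kept = nrow(conf$kept),
                        dropped = nrow(conf$drop_log))
  ann <- annotate_contigs(conf$kept, taxonomy, ictv, group_rules,
                          genome_table)

  out <- list(
    trimmed_fasta = file.path(outdir, "viral_trimmed.fasta"),
    mixed_fasta = file.path(outdir, "viral_untrimmed.fasta"),
    triage_summary = file.path(outdir, "triage_summary.tsv"),
    drop_log = file.path(outdir, "drop_log.tsv"),
    confirmed_fasta = file.path(outdir, "viral_confirmed.fasta"),
    annotations = file.path(outdir, "annotations.tsv"))
  write_fasta(tri$trimmed, out$trimmed_fasta)
  write_fasta(tri$untrimmed_candidates, out$mixed_fasta)
  utils::write.table(tri$summary, out$triage_summary, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rbind(scr$drop_log, conf$drop_log), out$drop_log,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(conf$kept, out$confirmed_fasta)
  utils::write.table(ann, out$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  datasets <- NULL
  if (!is.null(inp$counts) && !is.null(inp$metadata)) {
    counts <- read_count_table(inp$counts)
    datasets <- read_dataset_metadata(inp$metadata)
    keep_rows <- intersect(rownames(counts), conf$kept$id)
    counts <- counts[keep_rows, , drop = FALSE]
    lens <- nchar(conf$kept$sequence[match(keep_rows, conf$kept$id)])

    tpm <- tpm_thousand(counts, lens, config)
    collapsed <- collapse_by_species(counts, ann)
    pres <- presence_matrix(counts, config)
    incl <- datasets$dataset_id[datasets$role == "non_embryonic"]
    sets <- core_and_unique_sets(pres, incl)
    food_flagged <- character(0)
    food_reps <- inp$food_replicates
    if (!is.null(food_reps) && length(food_reps) == 2L) {
      food_flagged <- flag_food_shared(pres, food_reps)
    }
    host_ds <- datasets$dataset_id[datasets$role != "food"]
    aligned <- colSums(counts[, host_ds, drop = FALSE])
    rpm <- depth_normalized_rpm(
      aligned, datasets$raw_read_pairs[match(host_ds, datasets$dataset_id)])
    z <- if (length(rpm) >= 2L && stats::sd(rpm) > 0) sds_from_mean(rpm)
         else rep(NA_real_, length(rpm))
    load_stats <- data.frame(dataset_id = host_ds, aligned_reads = aligned,
                             rpm = rpm, sds_from_mean = z,
                             row.names = NULL)

    out$tpm_k <- file.path(outdir, "abundance_tpm_k.tsv")
    out$collapsed_counts <- file.path(outdir, "counts_by_species.tsv")
    out$core <- file.path(outdir, "core_virome.tsv")
    out$unique <- file.path(outdir, "unique_sets.tsv")
    out$venn = file.path(outdir, "venn_regions.json")
    out$food_shared <- file.path(outdir, "food_shared.tsv")
    out$load_stats <- file.path(outdir, "load_stats.tsv")
    write_count_table(round(tpm, 6), out$tpm_k)
    write_count_table(collapsed, out$collapsed_counts, id_col = "species")
    writeLines(sets$core, out$core)
    uq <- data.frame(
      dataset = rep(names(sets$unique), lengths(sets$unique)),
      contig = unlist(sets$unique, use.names = FALSE))
    utils::write.table(uq, out$unique, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(jsonlite::toJSON(
      list(datasets = incl, regions = as.list(sets$regions)),
      auto_unbox = TRUE, pretty = TRUE), out$venn)
    writeLines(food_flagged, out$food_shared)
    utils::write.table(load_stats, out$load_stats, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage$quantification <- list(
      contigs_quantified = nrow(counts), datasets = ncol(counts),
      core = length(sets$core), food_shared = length(food_flagged))
  }

  manifest <- structure(list(
    config = unclass(config),
    inputs = inp,
    outdir = outdir,
    stages = stage,
    outputs = out,
    datasets = datasets,
    confirmed = conf$kept$id,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
  json <- jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, null = "null")
  writeLines(json, file.path(outdir, "manifest.json"))
  invisible(manifest)
}

#' Bookkeeping summary of a pipeline run
#'
#' One row per dataset — raw read pairs, retained reads, viral reads
#' mapped, identified viral sequences (contigs with any mapped read) —
#' plus a merged "all datasets" row whose raw-pair and retained totals
#' are the column sums.
#'
#' @param manifest A `run_manifest` (from [run_pipeline()]) or the path
#'   to a written `manifest.json`.
#' @return A data.frame, last row "all_datasets".
#' @export
summarize_run <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::fromJSON(manifest, simplifyVector = TRUE)
  }
  md <- manifest$datasets
  if (is.null(md) || !nrow(md)) {
    stop("manifest has no dataset metadata; was quantification run?",
         call. = FALSE)
  }
  counts <- read_count_table(manifest$inputs$counts)
  counts <- counts[intersect(rownames(counts), manifest$confirmed), ,
                   drop = FALSE]
  viral_reads <- colSums(counts)[md$dataset_id]
  identified <- colSums(counts >= 1L)[md$dataset_id]
  tab <- data.frame(
    dataset_id = md$dataset_id,
    raw_read_pairs = md$raw_read_pairs,
    retained_reads = md$retained_reads,
    viral_reads_mapped = as.integer(viral_reads),
    identified_viral_sequences = as.integer(identified),
    stringsAsFactors = FALSE)
  merged <- data.frame(
    dataset_id = "all_datasets",
    raw_read_pairs = sum(as.numeric(tab$raw_read_pairs)),
    retained_reads = sum(as.numeric(tab$retained_reads)),
    viral_reads_mapped = sum(as.numeric(tab$viral_reads_mapped)),
    identified_viral_sequences = sum(rowSums(counts) >= 1L),
    stringsAsFactors = FALSE)
  rbind(tab, merged)
}
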