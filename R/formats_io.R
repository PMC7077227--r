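#' Read assembled contigs from a FASTA file
#'
#' Parses a nucleotide FASTA file into a contig table. Sequence case is
#' normalized to upper and IUPAC ambiguity codes outside `{A,C,G,T,N}` are
#' mapped to `N` with a warning, since downstream trimming operates on a
#' plain four-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, one row per
#'   record, in file order. An empty file yields a zero-row data.frame.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "AC", "GT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate contig id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("empty contig id in ", path, call. = FALSE)
  sq <- toupper(as.character(seqs))
  if (any(nchar(sq) == 0L)) {
    stop("zero-length sequence for contig(s): ",
         paste(ids[nchar(sq) == 0L], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", sq)
  if (any(bad)) {
    warning("non-ACGTN characters mapped to N in ",
            sum(bad), " sequence(s)", call. = FALSE)
    sq[bad] <- gsub("[^ACGTN]", "N", sq[bad])
  }
  data.frame(id = unname(ids), sequence = unname(sq),
             stringsAsFactors = FALSE)
}

#' Write contigs to a FASTA file
#'
#' @param contigs A data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  stopifnot(is.data.frame(contigs), all(c("id", "sequence") %in% names(contigs)))
  set <- Biostrings::BStringSet(contigs$sequence)
  names(set) <- contigs$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a tabular homology-search result
#'
#' Reads the standard 12-column tab-separated local-alignment table
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, e-value, bitscore), with an
#' optional 13th subject-taxon column used by the eukaryotic-virus
#' confirmation step.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param has_taxid Logical; `TRUE` when a 13th subject-taxid column is
#'   present.
#' @return A data.frame of hits with columns `qid`, `sid`, `pident`,
#'   `aln_len`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore` (and `staxid` when `has_taxid`), in file order.
#' @export
read_homology_table <- function(path, has_taxid = FALSE) {
  if (!file.exists(path)) stop("hit table not found: ", path, call. = FALSE)
  ncol_expected <- if (has_taxid) 13L else 12L
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("qid", "sid", "pident", "aln_len", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (has_taxid) cols <- c(cols, "staxid")
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    return(coerce_hit_types(out, path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != ncol_expected)) {
    bad <- which(nf != ncol_expected)[1L]
    stop("line ", bad, " of ", path, " has ", nf[bad],
         " columns, expected ", ncol_expected, call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  coerce_hit_types(out, path)
}

coerce_hit_types <- function(hits, path = "<hits>") {
  num_cols <- c("pident", "evalue", "bitscore")
  int_cols <- c("aln_len", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send")
  if ("staxid" %in% names(hits)) int_cols <- c(int_cols, "staxid")
  for (nm in c(num_cols, int_cols)) {
    v <- suppressWarnings(as.numeric(hits[[nm]]))
    if (anyNA(v) && !all(is.na(hits[[nm]]) | nzchar(as.character(hits[[nm]])) == FALSE)) {
      bad <- which(is.na(v) & nzchar(as.character(hits[[nm]])))[1L]
      if (length(bad)) {
        stop("unparsable number in column '", nm, "' of ", path,
             " (row ", bad, "): ", hits[[nm]][bad], call. = FALSE)
      }
    }
    hits[[nm]] <- if (nm %in% int_cols) as.integer(round(v)) else v
  }
  if (any(hits$evalue < 0, na.rm = TRUE)) {
    stop("negative e-value in ", path, call. = FALSE)
  }
  if (nrow(hits) &&
      (any(hits$pident < 0 | hits$pident > 100, na.rm = TRUE))) {
    stop("percent identity outside [0,100] in ", path, call. = FALSE)
  }
  if (any(hits$qstart < 1L | hits$qend < 1L, na.rm = TRUE)) {
    stop("query coordinates must be >= 1 in ", path, call. = FALSE)
  }
  hits
}

#' Write a homology hit table
#'
#' Inverse of [read_homology_table()]; e-values are written in scientific
#' notation.
#'
#' @param hits A hit data.frame (12 or 13 columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(hits, path) {
  out <- hits
  out$evalue <- formatC(out$evalue, format = "e", digits = 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a taxonomy from nodes/names dump tables
#'
#' Parses the pipe-delimited `nodes.dmp`/`names.dmp` dialect
#' (`taxid | parent | rank |` and `taxid | name | unique | class |`)
#' into a single taxonomy table carrying each node's rank and scientific
#' name. Exactly one root (a node that is its own parent) must exist.
#'
#' @param nodes_path Path to the nodes table.
#' @param names_path Path to the names table.
#' @return A data.frame of class `taxonomy` with columns `taxid`,
#'   `parent_taxid`, `rank`, `name` and attribute `root_taxid`.
#' @export
read_taxdump <- function(nodes_path, names_path) {
  nodes_raw <- parse_dmp(nodes_path)
  if (any(lengths(nodes_raw) < 3L)) {
    stop("nodes table row with fewer than 3 fields in ", nodes_path,
         call. = FALSE)
  }
  taxid <- as.integer(vapply(nodes_raw, `[[`, "", 1L))
  parent <- as.integer(vapply(nodes_raw, `[[`, "", 2L))
  rank <- vapply(nodes_raw, `[[`, "", 3L)
  if (anyNA(taxid) || anyNA(parent)) {
    stop("non-integer taxid in ", nodes_path, call. = FALSE)
  }
  if (anyDuplicated(taxid)) {
    stop("duplicate taxid(s) in ", nodes_path, ": ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "),
         call. = FALSE)
  }
  undef <- setdiff(parent, taxid)
  if (length(undef)) {
    stop("parent taxid(s) not defined as nodes: ",
         paste(undef, collapse = ", "), call. = FALSE)
  }
  root <- taxid[taxid == parent]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (parent == self); found ",
         length(root), call. = FALSE)
  }

  names_raw <- parse_dmp(names_path)
  if (any(lengths(names_raw) < 2L)) {
    stop("names table row with fewer than 2 fields in ", names_path,
         call. = FALSE)
  }
  ntax <- as.integer(vapply(names_raw, `[[`, "", 1L))
  nname <- vapply(names_raw, `[[`, "", 2L)
  nclass <- vapply(names_raw, function(f) {
    if (length(f) >= 4L) f[[4L]] else "scientific name"
  }, "")
  sci <- nclass == "scientific name"
  ntax <- ntax[sci]; nname <- nname[sci]
  if (anyDuplicated(ntax)) {
    stop("multiple scientific names for taxid(s): ",
         paste(unique(ntax[duplicated(ntax)]), collapse = ", "),
         call. = FALSE)
  }
  missing_name <- setdiff(taxid, ntax)
  if (length(missing_name)) {
    stop("taxid(s) with no scientific name: ",
         paste(missing_name, collapse = ", "), call. = FALSE)
  }
  tax <- data.frame(
    taxid = taxid, parent_taxid = parent, rank = rank,
    name = nname[match(taxid, ntax)], stringsAsFactors = FALSE)
  attr(tax, "root_taxid") <- root
  class(tax) <- c("taxonomy", "data.frame")
  tax
}

parse_dmp <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(strsplit(lines, "|", fixed = TRUE), function(f) {
    f <- trimws(f)
    # a terminal delimiter leaves one empty trailing field; internal empty
    # fields (e.g. the unique-name slot) must be kept in position
    if (length(f) > 1L && !nzchar(f[length(f)])) f <- f[-length(f)]
    f
  })
}

#' Write a taxonomy as nodes/names dump tables
#'
#' @param taxonomy A `taxonomy` data.frame (see [read_taxdump()]).
#' @param nodes_path,names_path Output paths.
#' @return Paths, invisibly.
#' @export
write_taxdump <- function(taxonomy, nodes_path, names_path) {
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|",
                     taxonomy$taxid, taxonomy$parent_taxid, taxonomy$rank),
             nodes_path)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     taxonomy$taxid, taxonomy$name),
             names_path)
  invisible(c(nodes_path, names_path))
}

#' Read a contig-by-dataset read-count table
#'
#' TSV with a header row of dataset ids and a first column of contig ids.
#' Blank cells are zeros; counts must be non-negative integers.
#'
#' @param path Path to the TSV count table.
#' @return An integer matrix, contigs in rows, datasets in columns.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("count table needs >= 1 dataset column", call. = FALSE)
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate contig row(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  vals[is.na(vals) | vals == ""] <- "0"
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) stop("non-numeric count in ", path, call. = FALSE)
  if (any(num < 0)) stop("negative count in ", path, call. = FALSE)
  if (any(num != round(num))) stop("non-integer count in ", path, call. = FALSE)
  m <- matrix(as.integer(num), nrow = nrow(vals),
              dimnames = list(ids, colnames(tab)[-1L]))
  m
}

#' Write a count matrix as TSV
#'
#' @param counts Integer matrix (contigs x datasets).
#' @param path Output path.
#' @param id_col Name for the contig-id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, id_col = "contig") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset-metadata table
#'
#' TSV with columns `dataset_id`, `raw_read_pairs`, `retained_reads`,
#' `enrichment` (one of polyA, rRNA_depleted, unknown) and `role` (one of
#' host, food, embryonic, non_embryonic). Since a read pair can yield at
#' most two retained reads, `retained_reads <= 2 * raw_read_pairs` is
#' enforced.
#'
#' @param path Path to the metadata TSV.
#' @return A validated data.frame.
#' @export
read_dataset_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata table not found: ", path, call. = FALSE)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_dataset_metadata(md)
}

validate_dataset_metadata <- function(md) {
  req <- c("dataset_id", "raw_read_pairs", "retained_reads",
           "enrichment", "role")
  miss <- setdiff(req, names(md))
  if (length(miss)) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(md$dataset_id)) stop("duplicate dataset_id", call. = FALSE)
  if (any(md$raw_read_pairs < 0) || any(md$retained_reads < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  bad_e <- setdiff(md$enrichment, c("polyA", "rRNA_depleted", "unknown"))
  if (length(bad_e)) {
    stop("unknown enrichment value(s): ", paste(bad_e, collapse = ", "),
         call. = FALSE)
  }
  bad_r <- setdiff(md$role, c("host", "food", "embryonic", "non_embryonic"))
  if (length(bad_r)) {
    stop("unknown role value(s): ", paste(bad_r, collapse = ", "),
         call. = FALSE)
  }
  over <- md$retained_reads > 2 * md$raw_read_pairs
  if (any(over)) {
    stop("retained_reads exceeds 2 x raw_read_pairs for: ",
         paste(md$dataset_id[over], collapse = ", "), call. = FALSE)
  }
  md
}
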