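# fixture builders shared across test files; all data is generated in code

make_hits <- function(qid, evalue, sid = paste0("s", seq_along(qid)),
                      bitscore = 100, qstart = 1L, qend = 100L,
                      staxid = NULL) {
  n <- length(qid)
  df <- data.frame(
    qid = qid, sid = rep_len(sid, n), pident = rep_len(90, n),
    aln_len = rep_len(100L, n), mismatch = rep_len(5L, n),
    gapopen = rep_len(1L, n), qstart = rep_len(as.integer(qstart), n),
    qend = rep_len(as.integer(qend), n), sstart = rep_len(1L, n),
    send = rep_len(100L, n), evalue = rep_len(evalue, n),
    bitscore = rep_len(bitscore, n), stringsAsFactors = FALSE)
  if (!is.null(staxid)) df$staxid <- as.integer(staxid)
  df
}

no_hits <- function() make_hits(character(0), numeric(0), sid = character(0))

make_contig <- function(id, len, seed = 1) {
  set.seed(seed)
  data.frame(id = id,
             sequence = paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = ""),
             stringsAsFactors = FALSE)
}

# small taxonomy: root(1) > Viruses(2) > Famiviridae(10, family) >
# genus(11) > species(12); phage family Siphoviridae(20) under order
# Caudovirales(21); Bacteria(3) > bug(30); clade with no family rank(40>41)
toy_taxonomy <- function() {
  tax <- data.frame(
    taxid = c(1L, 2L, 3L, 10L, 11L, 12L, 21L, 20L, 22L, 30L, 40L, 41L),
    parent_taxid = c(1L, 1L, 1L, 2L, 10L, 11L, 2L, 21L, 20L, 3L, 2L, 40L),
    rank = c("no rank", "superkingdom", "superkingdom", "family", "genus",
             "species", "order", "family", "species", "species",
             "clade", "species"),
    name = c("root", "Viruses", "Bacteria", "Famiviridae", "Famivirus",
             "Famivirus iridescens", "Caudovirales", "Siphoviridae",
             "Escherichia phage T0", "Escherichia coli",
             "unclassified RNA viruses", "Shi virus 1"),
    stringsAsFactors = FALSE)
  attr(tax, "root_taxid") <- 1L
  class(tax) <- c("taxonomy", "data.frame")
  tax
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# printed bookkeeping integers used as inputs by the quantification and
# acceptance tests: seven datasets' raw read pairs, retained reads,
# all-virus aligned reads and food-virus aligned reads
table1_raw_pairs <- c(364726242, 112159243, 105403849, 532867635,
                      155212236, 95331053, 542474332)
table1_retained <- c(18134716, 5251525, 6805643, 75383380,
                     23904647, 6988326, 35925820)
table2_all_aligned <- c(9544, 388, 19676, 74721, 140782, 2429, 28732)
table2_food_aligned <- c(1362, 63, 721, 1783, 127633, 1116, 537)
dataset_names <- c("babonis", "tulin", "oren", "schwaiger_polyA",
                   "schwaiger_rRNA", "fidler", "warner")
dataset_enrichment <- c("unknown", "polyA", "polyA", "polyA",
                        "rRNA_depleted", "polyA", "polyA")

# half a unit in the last printed decimal place
tol_printed <- function(x) {
  dec <- vapply(as.character(x), function(s) {
    if (grepl("\\.", s)) nchar(sub(".*\\.", "", s)) else 0L
  }, 0L)
  0.5 * 10^(-dec)
}
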