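test_that("read_fasta parses, concatenates lines, normalizes case", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">c1", "AC", "gt", ">c2 extra header words", "ACGT"), f)
  out <- read_fasta(f)
  expect_equal(out$id, c("c1", "c2"))
  expect_equal(out$sequence, c("ACGT", "ACGT"))
})

test_that("read_fasta rejects duplicate ids and maps IUPAC codes to N", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate.*c1")

  f2 <- tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACRYT"), f2)
  expect_warning(out <- read_fasta(f2), "mapped to N")
  expect_equal(out$sequence, "ACNNT")
})

test_that("read_fasta on an empty file yields zero records, not an error", {
  f <- tempfile(fileext = ".fasta")
  file.create(f)
  expect_equal(nrow(read_fasta(f)), 0L)
})

test_that("FASTA round-trip reproduces ids and sequences exactly", {
  set.seed(11)
  contigs <- data.frame(
    id = sprintf("ctg%02d", 1:8),
    sequence = vapply(sample(50:300, 8), function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, ""), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".fasta")
  write_fasta(contigs, f)
  expect_equal(read_fasta(f), contigs)
})

test_that("read_homology_table maps fields and accepts scientific e-values", {
  f <- write_tsv_lines(
    "c1\tvirA\t88.5\t100\t10\t2\t1\t300\t1\t100\t1e-20\t95.0")
  h <- read_homology_table(f)
  expect_equal(h$qid, "c1")
  expect_equal(h$evalue, 1e-20)
  expect_equal(h$qstart, 1L)
  expect_equal(h$qend, 300L)
  expect_equal(h$bitscore, 95.0)
  expect_equal(ncol(h), 12L)
})

test_that("read_homology_table handles empty files, taxid column, bad rows", {
  expect_equal(nrow(read_homology_table(write_tsv_lines(character(0)))), 0L)

  f13 <- write_tsv_lines(
    "c1\tvirA\t88.5\t100\t10\t2\t1\t300\t1\t100\t1e-20\t95.0\t10239")
  h <- read_homology_table(f13, has_taxid = TRUE)
  expect_equal(h$staxid, 10239L)

  f11 <- write_tsv_lines(c(
    "c1\tvirA\t88.5\t100\t10\t2\t1\t300\t1\t100\t1e-20\t95.0",
    "c2\tvirA\t88.5\t100\t10\t2\t1\t300\t1\t100\t1e-20"))
  expect_error(read_homology_table(f11), "line 2")

  fbad <- write_tsv_lines(
    "c1\tvirA\tnotanumber\t100\t10\t2\t1\t300\t1\t100\t1e-20\t95.0")
  expect_error(read_homology_table(fbad), "unparsable")
})

test_that("homology table round-trip preserves row count on generated files", {
  set.seed(3)
  for (n in c(1L, 7L, 40L)) {
    h <- make_hits(sprintf("q%d", seq_len(n)),
                   10^-runif(n, 3, 40), qend = 250L)
    f <- tempfile()
    write_homology_table(h, f)
    expect_equal(nrow(read_homology_table(f)), n)
  }
})

test_that("read_taxdump builds nodes with names and detects the root", {
  nodes <- write_tsv_lines(c("1\t|\t1\t|\tno rank\t|",
                             "10\t|\t1\t|\tfamily\t|",
                             "11\t|\t10\t|\tspecies\t|"))
  names_f <- write_tsv_lines(c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "10\t|\tFamiviridae\t|\t\t|\tscientific name\t|",
    "10\t|\tFamily X\t|\t\t|\tsynonym\t|",
    "11\t|\tFamivirus iridescens\t|\t\t|\tscientific name\t|"))
  tax <- read_taxdump(nodes, names_f)
  expect_equal(nrow(tax), 3L)
  expect_equal(attr(tax, "root_taxid"), 1L)
  expect_equal(tax$name[tax$taxid == 10L], "Famiviridae")
})

test_that("read_taxdump rejects undefined parents and name ambiguity", {
  nodes_bad <- write_tsv_lines(c("1\t|\t1\t|\tno rank\t|",
                                 "10\t|\t99\t|\tfamily\t|"))
  names_ok <- write_tsv_lines(c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "10\t|\tFamiviridae\t|\t\t|\tscientific name\t|"))
  expect_error(read_taxdump(nodes_bad, names_ok), "99")

  nodes <- write_tsv_lines(c("1\t|\t1\t|\tno rank\t|",
                             "10\t|\t1\t|\tfamily\t|"))
  names_dup <- write_tsv_lines(c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "10\t|\tFamiviridae\t|\t\t|\tscientific name\t|",
    "10\t|\tOtheridae\t|\t\t|\tscientific name\t|"))
  expect_error(read_taxdump(nodes, names_dup), "multiple scientific names")

  names_missing <- write_tsv_lines(
    "1\t|\troot\t|\t\t|\tscientific name\t|")
  expect_error(read_taxdump(nodes, names_missing), "no scientific name")
})

test_that("taxdump round-trip via write_taxdump", {
  tax <- toy_taxonomy()
  nf <- tempfile(); mf <- tempfile()
  write_taxdump(tax, nf, mf)
  back <- read_taxdump(nf, mf)
  expect_equal(as.data.frame(back), as.data.frame(tax))
})

test_that("read_count_table parses values, blanks as zero, rejects bad cells", {
  f <- write_tsv_lines(c("contig\td1\td2", "c1\t5\t0", "c2\t3\t7"))
  m <- read_count_table(f)
  expect_equal(m, matrix(c(5L, 3L, 0L, 7L), 2,
                         dimnames = list(c("c1", "c2"), c("d1", "d2"))))

  fb <- write_tsv_lines(c("contig\td1\td2", "c1\t5\t", "c2\t3\t7"))
  expect_equal(read_count_table(fb)["c1", "d2"], 0L)

  fneg <- write_tsv_lines(c("contig\td1", "c1\t-3"))
  expect_error(read_count_table(fneg), "negative")
  ffrac <- write_tsv_lines(c("contig\td1", "c1\t2.5"))
  expect_error(read_count_table(ffrac), "non-integer")
  fdup <- write_tsv_lines(c("contig\td1", "c1\t1", "c1\t2"))
  expect_error(read_count_table(fdup), "duplicate")
})

test_that("dataset metadata validation enforces the pair/read invariant", {
  md <- data.frame(dataset_id = "d1", raw_read_pairs = 100L,
                   retained_reads = 150L, enrichment = "polyA",
                   role = "non_embryonic")
  expect_silent(validate <- viroscreen:::validate_dataset_metadata(md))
  md$retained_reads <- 201L
  expect_error(viroscreen:::validate_dataset_metadata(md), "2 x raw")
  md$retained_reads <- 100L
  md$enrichment <- "totalRNA"
  expect_error(viroscreen:::validate_dataset_metadata(md), "enrichment")
})
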