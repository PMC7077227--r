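test_that("hit projection converts coordinates and unions intervals", {
  h1 <- make_hits("c1", 1e-10, qstart = 101L, qend = 300L)
  expect_equal(project_hits_to_intervals(h1, 500L),
               matrix(c(100L, 300L), 1, dimnames = list(NULL, c("start", "end"))))
  # reversed (minus-frame) coordinates normalize
  h2 <- make_hits("c1", 1e-10, qstart = 300L, qend = 101L)
  expect_equal(project_hits_to_intervals(h2, 500L)[1, ],
               c(start = 100L, end = 300L))
  # overlap merges
  h3 <- make_hits(c("c1", "c1"), c(1e-10, 1e-8),
                  qstart = c(101L, 251L), qend = c(300L, 400L))
  expect_equal(project_hits_to_intervals(h3, 500L)[1, ],
               c(start = 100L, end = 400L))
  # abutting intervals merge, disjoint stay apart
  h4 <- make_hits(c("c1", "c1", "c1"), rep(1e-10, 3),
                  qstart = c(1L, 101L, 301L), qend = c(100L, 200L, 400L))
  iv <- project_hits_to_intervals(h4, 500L)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv[, "start"], c(0L, 300L))

  expect_error(project_hits_to_intervals(h1, 200L), "beyond contig length")
  expect_error(project_hits_to_intervals(
    make_hits(c("a", "b"), c(1e-5, 1e-5)), 500L), "single query")
})

test_that("classify_contig applies the ordered triage rules", {
  cfg <- pipeline_config()
  ctg <- make_contig("c1", 500)
  # clear viral signal
  r <- classify_contig(ctg, no_hits(), make_hits("c1", 1e-8), no_hits(), cfg)
  expect_equal(r$status, "viral_candidate")
  expect_equal(r$best_viral_hit$evalue, 1e-8)
  expect_gt(nrow(r$viral_intervals), 0)
  # a stronger prokaryote hit makes the origin ambiguous
  r2 <- classify_contig(ctg, no_hits(), make_hits("c1", 1e-8),
                        make_hits("c1", 1e-30), cfg)
  expect_equal(r2$status, "ambiguous")
  # length gate comes first
  short <- make_contig("c1", 150)
  r3 <- classify_contig(short, no_hits(), make_hits("c1", 1e-8), no_hits(), cfg)
  expect_equal(r3$status, "too_short")
  # 200 nt exactly passes the gate (reported minimum is 200)
  r200 <- classify_contig(make_contig("c1", 200), no_hits(),
                          make_hits("c1", 1e-8), no_hits(), cfg)
  expect_equal(r200$status, "viral_candidate")
  # no viral signal: host beats prokaryote beats no_hit
  expect_equal(classify_contig(ctg, make_hits("c1", 1e-3), no_hits(),
                               no_hits(), cfg)$status, "host")
  expect_equal(classify_contig(ctg, no_hits(), no_hits(),
                               make_hits("c1", 1e-12), cfg)$status,
               "prokaryotic")
  expect_equal(classify_contig(ctg, no_hits(), no_hits(), no_hits(),
                               cfg)$status, "no_hit")
  # a viral hit above its cutoff does not count
  expect_equal(classify_contig(ctg, no_hits(), make_hits("c1", 1e-3),
                               no_hits(), cfg)$status, "no_hit")
  # e-value tie with host is not "strictly smallest": ambiguous
  expect_equal(classify_contig(ctg, make_hits("c1", 1e-8),
                               make_hits("c1", 1e-8), no_hits(),
                               cfg)$status, "ambiguous")
})

test_that("classify_contig agrees with an exhaustive rule-table oracle", {
  # independent re-statement of the triage decision used as an oracle
  oracle <- function(len, host_e, viral_e, prok_e, cfg) {
    if (len < cfg$min_contig_len) return("too_short")
    ve <- viral_e[viral_e <= cfg$viral_evalue]
    pe <- prok_e[prok_e <= cfg$prok_evalue]
    if (!length(ve)) {
      if (length(host_e)) return("host")
      if (length(pe)) return("prokaryotic")
      return("no_hit")
    }
    bv <- min(ve)
    bh <- if (length(host_e)) min(host_e) else Inf
    bp <- if (length(pe)) min(pe) else Inf
    if (bv < bh && bv < bp) "viral_candidate" else "ambiguous"
  }
  cfg <- pipeline_config()
  set.seed(99)
  for (i in 1:20) {
    len <- sample(c(150L, 300L, 800L), 1)
    ctg <- make_contig("cx", len, seed = i)
    evs <- function() 10^-runif(sample(0:5, 1), 0, 35)
    he <- evs(); ve <- evs(); pe <- evs()
    mk <- function(e, len) if (length(e))
      make_hits(rep("cx", length(e)), e, qend = min(100L, len)) else no_hits()
    got <- classify_contig(ctg, mk(he, len), mk(ve, len), mk(pe, len), cfg)
    expect_equal(got$status, oracle(len, he, ve, pe, cfg),
                 info = sprintf("case %d", i))
  }
})

test_that("tightening the viral cutoff never creates a candidate", {
  cfg_loose <- pipeline_config(viral_evalue = 1e-5)
  cfg_tight <- pipeline_config(viral_evalue = 1e-12)
  set.seed(7)
  for (i in 1:15) {
    ctg <- make_contig("cx", 400, seed = i)
    ve <- 10^-runif(3, 0, 30)
    he <- 10^-runif(1, 0, 30)
    mk <- function(e) make_hits(rep("cx", length(e)), e)
    loose <- classify_contig(ctg, mk(he), mk(ve), no_hits(), cfg_loose)$status
    tight <- classify_contig(ctg, mk(he), mk(ve), no_hits(), cfg_tight)$status
    if (loose != "viral_candidate") {
      expect_false(tight == "viral_candidate")
    }
  }
})

test_that("trimming slices at intervals and applies the length gate post-trim", {
  cfg <- pipeline_config()
  ctg <- make_contig("c1", 1000)
  mk_result <- function(iv) {
    structure(list(contig_id = "c1", status = "viral_candidate",
                   best_viral_hit = make_hits("c1", 1e-10),
                   viral_intervals = iv), class = "triage_result")
  }
  iv <- matrix(c(100L, 400L), 1, dimnames = list(NULL, c("start", "end")))
  tr <- trim_to_viral_homology(ctg, mk_result(iv), cfg)
  expect_equal(nchar(tr$sequence), 300L)
  expect_equal(tr$id, "c1_101-400")
  expect_equal(tr$sequence, substr(ctg$sequence, 101, 400))

  # whole-contig homology: the fragment IS the contig, id kept stable
  whole <- matrix(c(0L, 1000L), 1, dimnames = list(NULL, c("start", "end")))
  tw <- trim_to_viral_homology(ctg, mk_result(whole), cfg)
  expect_equal(tw$id, "c1")
  expect_equal(tw$sequence, ctg$sequence)

  # every interval below min_contig_len: nothing emitted, exclusions logged
  small <- matrix(c(0L, 150L), 1, dimnames = list(NULL, c("start", "end")))
  ts <- trim_to_viral_homology(ctg, mk_result(small), cfg)
  expect_equal(nrow(ts), 0L)
  expect_equal(nrow(attr(ts, "excluded")), 1L)

  bad <- mk_result(iv); bad$status <- "host"
  expect_error(trim_to_viral_homology(ctg, bad, cfg), "viral_candidate")
})

test_that("every trimmed sequence is the parent substring at its interval", {
  set.seed(5)
  cfg <- pipeline_config()
  for (i in 1:10) {
    ctg <- make_contig("cx", sample(400:2000, 1), seed = 100 + i)
    len <- nchar(ctg$sequence)
    n <- sample(1:4, 1)
    qs <- sample.int(len - 250L, n)
    qe <- pmin(qs + sample(200:600, n, replace = TRUE), len)
    hits <- make_hits(rep("cx", n), 10^-runif(n, 6, 30),
                      qstart = qs, qend = qe)
    r <- classify_contig(ctg, no_hits(), hits, no_hits(), cfg)
    expect_equal(r$status, "viral_candidate")
    tr <- trim_to_viral_homology(ctg, r, cfg)
    for (k in seq_len(nrow(tr))) {
      expect_equal(tr$sequence[k],
                   substr(ctg$sequence, tr$start[k] + 1L, tr$end[k]))
      expect_gte(nchar(tr$sequence[k]), cfg$min_contig_len)
    }
  }
})

test_that("dedupe collapses exact duplicates and nested substrings", {
  df <- function(ids, seqs) data.frame(id = ids, sequence = seqs,
                                       stringsAsFactors = FALSE)
  d1 <- dedupe_contigs(df(c("a", "b"), c("ACGTACGT", "ACGTACGT")))
  expect_equal(d1$id, "a")
  d2 <- dedupe_contigs(df(c("a", "b"), c("ACGTACGT", "GTAC")))
  expect_equal(d2$id, "a")
  d3 <- dedupe_contigs(df(c("a", "b"), c("ACGT", "TTTT")))
  expect_equal(nrow(d3), 2L)
  # containment is directionless in input order
  d4 <- dedupe_contigs(df(c("short", "long"), c("GTAC", "ACGTACGT")))
  expect_equal(d4$id, "long")
})

test_that("triage assigns exactly one status per contig", {
  truth <- generate_community(seed = 3)
  paths <- emit_hit_tables(truth, dir = tempfile())
  contigs <- read_fasta(paths$contigs)
  tri <- triage_contigs(contigs,
                        read_homology_table(paths$host_hits),
                        read_homology_table(paths$viral_hits),
                        read_homology_table(paths$prok_hits))
  expect_equal(nrow(tri$summary), nrow(contigs))
  expect_equal(sum(table(tri$summary$status)), nrow(contigs))
  expect_true(all(tri$summary$status %in%
    c("viral_candidate", "host", "prokaryotic", "ambiguous",
      "too_short", "no_hit")))
})
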