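test_that("tpm_thousand normalizes rates to a fixed per-dataset total", {
  expect_equal(as.numeric(tpm_thousand(5, 1000)), 1000)
  expect_equal(as.numeric(tpm_thousand(c(4, 4), c(200, 200))), c(500, 500))
  # equal count/length rates give equal shares regardless of magnitude
  expect_equal(as.numeric(tpm_thousand(c(10, 30), c(100, 300))), c(500, 500))
  expect_equal(as.numeric(tpm_thousand(c(0, 0), c(100, 300))), c(0, 0))
  expect_error(tpm_thousand(c(1, 1), c(100, 0)), "> 0")
})

test_that("tpm_thousand columns sum to 1e6 / divisor on random matrices", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(3:20, 1); d <- sample(2:5, 1)
    counts <- matrix(rpois(n * d, 40), n, d,
                     dimnames = list(sprintf("c%d", 1:n), sprintf("d%d", 1:d)))
    lens <- sample(200:5000, n)
    tk <- tpm_thousand(counts, lens)
    expect_equal(unname(colSums(tk)), rep(1000, d))
  }
})

test_that("log2 transform masks zeros as missing", {
  m <- tpm_thousand(c(5, 0), c(100, 100))
  lg <- log2_matrix(m)
  expect_equal(lg[1], log2(1000))
  expect_true(is.na(lg[2]))
  expect_equal(attr(lg, "unit"), "log2_tpm_k")
  expect_equal(log2_matrix(structure(1, unit = "tpm_k"))[1], 0)
  expect_error(log2_matrix(matrix(1)), "tpm_k")
})

test_that("RPM normalizes aligned reads by raw read-pair depth", {
  expect_equal(round(depth_normalized_rpm(9544, 364726242), 2), 26.17)
  expect_equal(round(depth_normalized_rpm(140782, 155212236), 2), 907.03)
  expect_equal(depth_normalized_rpm(0, 1e6), 0)
  expect_error(depth_normalized_rpm(10, 0), "> 0")
  # accepts a library row as well as a bare number
  lib <- data.frame(dataset_id = "d", raw_read_pairs = 2e6)
  expect_equal(depth_normalized_rpm(4, lib), 2)
})

test_that("sds_from_mean uses the sample standard deviation", {
  z <- sds_from_mean(c(1, -1))
  expect_equal(z, c(0.7071068, -0.7071068), tolerance = 1e-6)
  # the published all-virus loads: the rRNA-depleted library's z
  rpm <- depth_normalized_rpm(table2_all_aligned, table1_raw_pairs)
  expect_equal(round(sds_from_mean(rpm)[5], 3), 2.218)
  expect_error(sds_from_mean(c(3, 3, 3)), "zero standard deviation")
  expect_error(sds_from_mean(5), "two values")
})

test_that("z-scores have mean zero and unit sample SD", {
  set.seed(17)
  for (rep in 1:10) {
    v <- rnorm(sample(3:30, 1), sd = runif(1, 0.1, 50))
    z <- sds_from_mean(v)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
})

test_that("food fractions and the polyA-side group mean", {
  libs <- data.frame(dataset_id = dataset_names,
                     raw_read_pairs = table1_raw_pairs,
                     retained_reads = table1_retained,
                     enrichment = dataset_enrichment,
                     role = c(rep("non_embryonic", 1), "embryonic",
                              rep("non_embryonic", 5)),
                     stringsAsFactors = FALSE)
  total <- setNames(table2_all_aligned, dataset_names)
  food <- setNames(table2_food_aligned, dataset_names)
  fs <- food_fraction_stats(total, food, libs)
  expect_equal(round(fs$polyA_mean, 2), 14.06)
  # the rRNA-depleted library is excluded from the group mean
  expect_equal(round(fs$fraction[["schwaiger_rRNA"]], 2), 90.66)

  expect_equal(food_fraction_stats(setNames(10, "babonis"),
                                   setNames(10, "babonis"),
                                   libs)$fraction[[1]], 100)
  expect_equal(food_fraction_stats(setNames(10, "babonis"),
                                   setNames(0, "babonis"),
                                   libs)$fraction[[1]], 0)
  expect_error(food_fraction_stats(setNames(5, "babonis"),
                                   setNames(10, "babonis"), libs),
               "exceed")
})

test_that("species collapsing sums counts and preserves column totals", {
  ann <- data.frame(contig_id = c("c1", "c2", "c3"),
                    species_label = c("spA", "spA", "spB"),
                    stringsAsFactors = FALSE)
  m <- matrix(c(5L, 7L, 2L, 1L, 0L, 4L), 3, 2,
              dimnames = list(c("c1", "c2", "c3"), c("d1", "d2")))
  cl <- collapse_by_species(m, ann)
  expect_equal(rownames(cl), c("spA", "spB"))
  expect_equal(cl["spA", "d1"], 12L)
  expect_equal(colSums(cl), colSums(m))

  distinct <- data.frame(contig_id = rownames(m),
                         species_label = rownames(m))
  expect_equal(unname(collapse_by_species(m, distinct)), unname(m))
  expect_error(collapse_by_species(m, ann[-1, ]), "unannotated")
})

test_that("collapse conservation holds on random annotated matrices", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(4:25, 1)
    m <- matrix(rpois(n * 3, 10), n, 3,
                dimnames = list(sprintf("c%d", 1:n), c("d1", "d2", "d3")))
    ann <- data.frame(contig_id = rownames(m),
                      species_label = sample(sprintf("sp%d", 1:max(2, n %/% 2)),
                                             n, replace = TRUE))
    expect_equal(colSums(collapse_by_species(m, ann)), colSums(m))
  }
})
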