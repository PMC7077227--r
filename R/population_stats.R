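#' Principal-factor extraction with eigenvalue retention
#'
#' Standardizes each variable (mean 0, SD 1), eigen-decomposes the
#' correlation matrix, and retains the factors whose eigenvalue exceeds
#' `eigenvalue_retain` (default 2), capped at `max_factors`. Variance
#' explained by factor j is `100 * lambda_j / p` where p is the number of
#' variables; eigenvalues of a correlation decomposition sum to p.
#'
#' In the inter-population design the observations are contigs (one row
#' per viral contig, normalized remapped counts) and the variables are
#' the replicate libraries of the two populations, so scores are
#' per-contig and loadings are per-library.
#'
#' @param x Numeric observation x variable matrix.
#' @param config A [pipeline_config()].
#' @param max_factors Maximum number of factors considered for retention.
#' @return An object of class `factor_model`: `eigenvalues` (descending),
#'   `retained` (indices), `loadings` (variable x retained eigenvectors),
#'   `scores` (observation x retained projections of the standardized
#'   data), `variance_explained` (percent per factor).
#' @export
factor_extract <- function(x, config = pipeline_config(), max_factors = 5L) {
  config <- as_config(config)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two variables", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  z <- scale(x)
  cm <- stats::cor(x)
  ed <- eigen(cm, symmetric = TRUE)
  lambda <- ed$values
  retained <- which(lambda > config$eigenvalue_retain)
  retained <- utils::head(retained, max_factors)
  loadings <- ed$vectors[, retained, drop = FALSE]
  rownames(loadings) <- colnames(x)
  scores <- z %*% loadings
  structure(list(
    eigenvalues = lambda,
    retained = retained,
    loadings = loadings,
    scores = scores,
    variance_explained = 100 * lambda / ncol(x)
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("factor model:", length(x$eigenvalues), "variables\n")
  cat("  eigenvalues:",
      paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  cat("  retained:", if (length(x$retained))
    paste(x$retained, collapse = ", ") else "none", "\n")
  if (length(x$retained)) {
    cat("  variance explained (%):",
        paste(sprintf("%.2f", x$variance_explained[x$retained]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Welch two-sample t-test on factor scores
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, applied separately to each retained
#' factor's scores split by group. With equal group variances the degrees
#' of freedom approach the classic `nA + nB - 2`.
#'
#' @param scores_a,scores_b Numeric score vectors for the two groups,
#'   each of length >= 2.
#' @return A list: `t`, `df`, `p`.
#' @export
welch_t_per_factor <- function(scores_a, scores_b) {
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  ht <- stats::t.test(scores_a, scores_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Inter-population comparison on a contig x replicate matrix
#'
#' Full statistical stage: RPM-normalize each replicate column by its raw
#' read-pair depth, extract factors over the replicate variables, and run
#' a Welch test per retained factor between the two replicate groups.
#' Because the variables are the replicate libraries, a factor's
#' per-library values are its component loadings; the per-factor test
#' compares group A replicates' loadings with group B replicates'
#' loadings.
#'
#' @param counts Contig x replicate count matrix.
#' @param raw_read_pairs Named vector of per-replicate raw read-pair
#'   depths (names matching columns of `counts`).
#' @param groups Named character/factor vector assigning each replicate
#'   column to one of exactly two groups.
#' @param config A [pipeline_config()].
#' @return A list: `model` (the `factor_model`) and `tests` (data.frame
#'   with one row per retained factor: factor, t, df, p).
#' @export
compare_populations <- function(counts, raw_read_pairs, groups,
                                config = pipeline_config()) {
  config <- as_config(config)
  stopifnot(identical(sort(colnames(counts)), sort(names(raw_read_pairs))),
            identical(sort(colnames(counts)), sort(names(groups))))
  gl <- unique(as.character(groups))
  if (length(gl) != 2L) stop("exactly two groups required", call. = FALSE)
  rpm <- sweep(counts, 2L,
               1e6 / raw_read_pairs[colnames(counts)], `*`)
  model <- factor_extract(rpm, config)
  ga <- names(groups)[groups == gl[1L]]
  gb <- names(groups)[groups == gl[2L]]
  tests <- lapply(seq_along(model$retained), function(k) {
    la <- model$loadings[ga, k]
    lb <- model$loadings[gb, k]
    w <- welch_t_per_factor(la, lb)
    data.frame(factor = model$retained[k], t = w$t, df = w$df, p = w$p)
  })
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(factor = integer(0), t = numeric(0), df = numeric(0),
               p = numeric(0))
  list(model = model, tests = tests)
}
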