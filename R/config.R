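#' Pipeline configuration
#'
#' Collects every numeric threshold used by the pipeline in one validated
#' object. Defaults follow the published protocol the pipeline implements:
#' reads with a host-genome hit at e-value <= 1e-15 are discarded; contigs
#' are triaged with a viral-protein cutoff of 1e-5 and a prokaryote-protein
#' cutoff of 1e-10; the all-proteins screen and the eukaryotic-virus
#' confirmation both gate at 1e-10; only (trimmed) contigs of at least
#' 200 nt are kept; relative abundance is reported as TPM divided by 1000;
#' factors with eigenvalue > 2 are retained in the inter-population
#' analysis.
#'
#' @param host_read_evalue E-value at or below which a read with a host
#'   genome hit is removed during host subtraction.
#' @param viral_evalue Cutoff for the viral-protein search arm of triage.
#' @param prok_evalue Cutoff for the prokaryote-protein search arm.
#' @param screen_evalue Cutoff for the all-proteins screen.
#' @param confirm_evalue Cutoff for the eukaryotic-virus confirmation search.
#' @param min_contig_len Minimum contig (and trimmed fragment) length in nt.
#' @param presence_min_reads Mapped reads required to call a contig present
#'   in a dataset.
#' @param eigenvalue_retain Eigenvalue threshold for factor retention.
#' @param tpm_divisor Divisor applied to TPM values (1000 reports TPM/1000).
#'
#' @return A `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config()
#' cfg$viral_evalue
#' @export
pipeline_config <- function(host_read_evalue = 1e-15,
                            viral_evalue = 1e-5,
                            prok_evalue = 1e-10,
                            screen_evalue = 1e-10,
                            confirm_evalue = 1e-10,
                            min_contig_len = 200L,
                            presence_min_reads = 1L,
                            eigenvalue_retain = 2.0,
                            tpm_divisor = 1000) {
  cfg <- list(
    host_read_evalue = as.numeric(host_read_evalue),
    viral_evalue = as.numeric(viral_evalue),
    prok_evalue = as.numeric(prok_evalue),
    screen_evalue = as.numeric(screen_evalue),
    confirm_evalue = as.numeric(confirm_evalue),
    min_contig_len = as.integer(min_contig_len),
    presence_min_reads = as.integer(presence_min_reads),
    eigenvalue_retain = as.numeric(eigenvalue_retain),
    tpm_divisor = as.numeric(tpm_divisor)
  )
  for (nm in c("host_read_evalue", "viral_evalue", "prok_evalue",
               "screen_evalue", "confirm_evalue")) {
    v <- cfg[[nm]]
    if (length(v) != 1L || is.na(v) || v < 0) {
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
    }
  }
  if (is.na(cfg$min_contig_len) || cfg$min_contig_len < 1L) {
    stop("'min_contig_len' must be >= 1", call. = FALSE)
  }
  if (is.na(cfg$presence_min_reads) || cfg$presence_min_reads < 1L) {
    stop("'presence_min_reads' must be >= 1", call. = FALSE)
  }
  if (is.na(cfg$tpm_divisor) || cfg$tpm_divisor <= 0) {
    stop("'tpm_divisor' must be > 0", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("viroscreen pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (inherits(config, "pipeline_config")) return(config)
  if (is.list(config)) return(do.call(pipeline_config, config))
  stop("'config' must be a pipeline_config or a list of its fields",
       call. = FALSE)
}
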