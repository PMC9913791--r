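# Core data containers: methylation beta matrices, probe annotation and
# count matrices. Plain S3 wrappers around base matrices/data frames, in the
# style of simple list-based containers: cheap to build in tests, explicit
# to validate.

#' Construct a beta-value matrix container
#'
#' Holds a probes x samples matrix of methylation fractions together with
#' the matching detection p-values. Missing values are encoded as `NA` in
#' the beta matrix; the detection-p matrix must have the same shape.
#'
#' @param beta numeric matrix in `[0,1]` (or `NA`), rownames = probe ids,
#'   colnames = sample ids.
#' @param detection_p numeric matrix of detection p-values in `[0,1]`, same
#'   shape as `beta`. Defaults to all-zero (every call confidently detected).
#' @return an object of class `beta_matrix` with elements `beta`,
#'   `detection_p` and a `qc_log` list (filled by [apply_probe_qc()]).
#' @export
beta_matrix <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop_input("`beta` must be a numeric matrix")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop_input("`beta` must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) stop_input("probe ids must be unique")
  if (anyDuplicated(colnames(beta))) stop_input("sample ids must be unique")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop_input("beta values must lie in [0,1]")
  if (is.null(detection_p)) {
    detection_p <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  }
  if (!identical(dim(detection_p), dim(beta))) {
    stop_input("`detection_p` must have the same shape as `beta`")
  }
  dimnames(detection_p) <- dimnames(beta)
  structure(list(beta = beta, detection_p = detection_p, qc_log = list()),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples; %d missing entries\n",
              nrow(x$beta), ncol(x$beta), sum(is.na(x$beta))))
  if (length(x$qc_log)) {
    cat(sprintf("  QC: %s probes dropped (blacklist), %s entries masked (detection p)\n",
                x$qc_log$n_probes_dropped %||% 0, x$qc_log$n_entries_masked %||% 0))
  }
  invisible(x)
}

#' Construct a probe annotation object
#'
#' Bundles the per-probe manifest (coordinates, panel membership, blacklist
#' flags), the probe-to-gene link table, the gene coordinate table and the
#' genome bin table used for compartment assignment. Coordinates are BED
#' style: 0-based, half-open.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `start`, `end`,
#'   `in_cimp_panel`, `in_epitoc_panel`, `blacklist_reason` (one of `"none"`,
#'   `"multimapping"`, `"snp_within_5bp"`, `"meqtl"`).
#' @param links data.frame with columns `probe_id`, `gene_id`, `region_class`
#'   (one of `"gene_body"`, `"promoter"`, `"enhancer"`); zero or more rows
#'   per probe.
#' @param genes optional data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (start is the transcription start used as anchor).
#' @param bins optional data.frame of genome bins with columns `chrom`,
#'   `start`, `end` and, for synthetic cohorts, the true compartment `label`.
#' @return an object of class `probe_annotation`.
#' @export
probe_annotation <- function(probes, links, genes = NULL, bins = NULL) {
  req <- c("probe_id", "chrom", "start", "end",
           "in_cimp_panel", "in_epitoc_panel", "blacklist_reason")
  if (!all(req %in% names(probes))) {
    stop_input("`probes` must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(probes$probe_id)) stop_input("probe ids must be unique")
  if (any(probes$start >= probes$end)) stop_input("probe start must be < end")
  bad <- setdiff(unique(probes$blacklist_reason),
                 c("none", "multimapping", "snp_within_5bp", "meqtl"))
  if (length(bad)) stop_input("unknown blacklist_reason: ", paste(bad, collapse = ", "))
  if (!all(c("probe_id", "gene_id", "region_class") %in% names(links))) {
    stop_input("`links` must have columns probe_id, gene_id, region_class")
  }
  bad <- setdiff(unique(links$region_class), c("gene_body", "promoter", "enhancer"))
  if (length(bad)) stop_input("unknown region_class: ", paste(bad, collapse = ", "))
  structure(list(probes = probes, links = links, genes = genes, bins = bins),
            class = "probe_annotation")
}

#' @export
print.probe_annotation <- function(x, ...) {
  cat(sprintf(
    "<probe_annotation> %d probes (%d CIMP panel, %d EpiTOC panel, %d blacklisted), %d gene links\n",
    nrow(x$probes), sum(x$probes$in_cimp_panel), sum(x$probes$in_epitoc_panel),
    sum(x$probes$blacklist_reason != "none"), nrow(x$links)))
  invisible(x)
}

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, rownames = gene ids,
#'   colnames = sample ids.
#' @param samples data.frame sample sheet with at least `sample_id`; for the
#'   synthetic cohort also `model`, `arm`, `subgroup`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_input("`counts` must be a numeric matrix")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("counts must be non-negative integers")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_input("`counts` must carry gene rownames and sample colnames")
  }
  if (!"sample_id" %in% names(samples)) stop_input("`samples` needs a sample_id column")
  if (!setequal(samples$sample_id, colnames(counts))) {
    stop_input("sample sheet and count columns disagree")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
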