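# Methylation profiling: probe QC, KNN imputation, CIMP percentage and
# classification, EpiTOC mitotic age, and delta-beta differential
# methylation calling.

#' Probe-level quality control
#'
#' Masks entries whose detection p-value exceeds `detection_alpha`
#' (strictly; an entry at exactly the cutoff is retained) and drops probes
#' flagged on the annotation blacklist (multimapping, SNP within 5 bp of
#' the interrogated CpG, meQTL). The operation is idempotent. Counts of
#' dropped probes and masked entries are recorded in the returned object's
#' `qc_log`.
#'
#' @param bm a [beta_matrix()].
#' @param ann a [probe_annotation()]; probes absent from the annotation are
#'   dropped as un-annotatable.
#' @param detection_alpha detection p-value cutoff (default 0.05).
#' @param drop_sex_chroms optionally drop probes on chrX/chrY; the default
#'   retains them.
#' @return a filtered [beta_matrix()] with masked entries set to `NA`.
#' @export
apply_probe_qc <- function(bm, ann, detection_alpha = 0.05,
                           drop_sex_chroms = FALSE) {
  stopifnot(inherits(bm, "beta_matrix"), inherits(ann, "probe_annotation"))
  keep_ids <- intersect(rownames(bm$beta), ann$probes$probe_id)
  if (length(keep_ids) == 0L) {
    stop_input("probe sets of the beta matrix and annotation do not overlap")
  }
  pr <- ann$probes[match(keep_ids, ann$probes$probe_id), , drop = FALSE]
  bad <- pr$blacklist_reason != "none"
  if (drop_sex_chroms) bad <- bad | pr$chrom %in% c("chrX", "chrY")
  n_unannotated <- nrow(bm$beta) - length(keep_ids)
  keep_ids <- keep_ids[!bad]

  beta <- bm$beta[keep_ids, , drop = FALSE]
  detp <- bm$detection_p[keep_ids, , drop = FALSE]
  mask <- detp > detection_alpha
  n_masked <- sum(mask & !is.na(beta))
  beta[mask] <- NA_real_

  out <- beta_matrix(beta, detp)
  out$qc_log <- list(
    n_probes_dropped = sum(bad) + n_unannotated,
    n_blacklisted = sum(bad),
    n_unannotated = n_unannotated,
    n_entries_masked = n_masked,
    detection_alpha = detection_alpha
  )
  out
}

#' K-nearest-neighbour imputation of missing beta values
#'
#' Operates in probe space: for a probe with missing entries, the `k`
#' nearest fully observed probes (Euclidean distance over the samples where
#' the target probe is observed) donate the mean of their values in the
#' missing sample. Imputed values are clipped to `[0,1]`.
#'
#' @param bm a [beta_matrix()] (typically after [apply_probe_qc()]).
#' @param k number of neighbours (default 10).
#' @return a [beta_matrix()] with no missing entries.
#' @export
impute_missing_knn <- function(bm, k = 10L) {
  stopifnot(inherits(bm, "beta_matrix"), is_count(k), k >= 1)
  beta <- bm$beta
  miss_rows <- which(rowSums(is.na(beta)) > 0L)
  if (length(miss_rows) == 0L) return(bm)

  all_missing <- miss_rows[rowSums(!is.na(beta[miss_rows, , drop = FALSE])) == 0L]
  if (length(all_missing)) {
    stop_input("probe(s) missing in all samples cannot be imputed: ",
               paste(utils::head(rownames(beta)[all_missing], 5), collapse = ", "))
  }
  complete_rows <- which(rowSums(is.na(beta)) == 0L)
  if (length(complete_rows) < k + 1L) {
    stop_input("need at least k+1 probes with complete data for KNN imputation")
  }
  donors <- beta[complete_rows, , drop = FALSE]

  for (i in miss_rows) {
    obs <- !is.na(beta[i, ])
    d2 <- colSums((t(donors[, obs, drop = FALSE]) - beta[i, obs])^2)
    nn <- complete_rows[order(d2)[seq_len(k)]]
    fill <- colMeans(beta[nn, !obs, drop = FALSE])
    beta[i, !obs] <- clamp01(fill)
  }
  out <- beta_matrix(beta, bm$detection_p)
  out$qc_log <- bm$qc_log
  out$qc_log$n_entries_imputed <- sum(is.na(bm$beta))
  out
}

#' CIMP methylation percentage and classification
#'
#' The CIMP methylation percentage of a sample is the percentage of
#' evaluable CIMP-panel probes whose beta value is at or above
#' `methylated_cutoff`. Samples above 40% methylated panel CpGs are CIMP+,
#' at or below 40% CIMP- (strictly greater than 40 is required for CIMP+,
#' so a sample a hair above the cut, e.g. 43.3%, is still CIMP+).
#'
#' @param bm a [beta_matrix()] after QC.
#' @param ann a [probe_annotation()] defining the CIMP panel.
#' @param samples sample ids to evaluate (default: all).
#' @param methylated_cutoff beta value at which a panel probe counts as
#'   methylated (default 0.3).
#' @param class_threshold CIMP percentage above which a sample is CIMP+
#'   (default 40).
#' @return data.frame with `sample_id`, `cimp_percent`, `cimp_class`
#'   (`"CIMP_plus"` / `"CIMP_minus"`) and `n_probes_evaluated`.
#' @export
cimp_percentage <- function(bm, ann, samples = NULL, methylated_cutoff = 0.3,
                            class_threshold = 40) {
  stopifnot(inherits(bm, "beta_matrix"), inherits(ann, "probe_annotation"))
  panel <- intersect(ann$probes$probe_id[ann$probes$in_cimp_panel],
                     rownames(bm$beta))
  if (length(panel) == 0L) {
    stop_input("CIMP panel is empty after QC; percentage undefined")
  }
  samples <- samples %||% colnames(bm$beta)
  stopifnot(all(samples %in% colnames(bm$beta)))
  sub <- bm$beta[panel, samples, drop = FALSE]
  n_eval <- colSums(!is.na(sub))
  if (any(n_eval == 0L)) {
    stop_input("no evaluable CIMP-panel probes for sample(s): ",
               paste(samples[n_eval == 0L], collapse = ", "))
  }
  pct <- 100 * colSums(sub >= methylated_cutoff, na.rm = TRUE) / n_eval
  data.frame(
    sample_id = samples,
    cimp_percent = unname(pct),
    cimp_class = ifelse(pct > class_threshold, "CIMP_plus", "CIMP_minus"),
    n_probes_evaluated = unname(n_eval),
    stringsAsFactors = FALSE
  )
}

#' Classify a CIMP methylation percentage
#'
#' @param cimp_percent percentage of methylated CIMP-panel probes, in
#'   `[0,100]`.
#' @param class_threshold CIMP+ requires strictly more than this (default 40).
#' @return `"CIMP_plus"` or `"CIMP_minus"` (vectorized).
#' @export
cimp_class <- function(cimp_percent, class_threshold = 40) {
  stopifnot(all(cimp_percent >= 0 & cimp_percent <= 100))
  ifelse(cimp_percent > class_threshold, "CIMP_plus", "CIMP_minus")
}

#' EpiTOC mitotic age
#'
#' The epigenetic mitotic age of a sample is the arithmetic mean beta value
#' over the EpiTOC panel probes present on the array. Missing values must
#' already have been imputed (see [impute_missing_knn()]).
#'
#' @param bm a [beta_matrix()] with no missing values on the panel.
#' @param ann a [probe_annotation()] defining the EpiTOC panel.
#' @param samples sample ids to evaluate (default: all).
#' @return data.frame with `sample_id`, `epitoc_age` (in `[0,1]`) and
#'   `n_panel_probes`.
#' @export
epitoc_age <- function(bm, ann, samples = NULL) {
  stopifnot(inherits(bm, "beta_matrix"), inherits(ann, "probe_annotation"))
  panel <- intersect(ann$probes$probe_id[ann$probes$in_epitoc_panel],
                     rownames(bm$beta))
  if (length(panel) == 0L) stop_input("EpiTOC panel is empty after QC")
  samples <- samples %||% colnames(bm$beta)
  stopifnot(all(samples %in% colnames(bm$beta)))
  sub <- bm$beta[panel, samples, drop = FALSE]
  if (anyNA(sub)) {
    stop_input("EpiTOC panel contains missing values; impute first (impute_missing_knn)")
  }
  data.frame(
    sample_id = samples,
    epitoc_age = unname(colMeans(sub)),
    n_panel_probes = length(panel),
    stringsAsFactors = FALSE
  )
}

#' Delta-beta differential methylation calling
#'
#' For each probe, delta beta is the mean beta over treated samples minus
#' the mean over vehicle samples (available-case means over non-missing
#' entries). A probe is differentially methylated when the absolute delta
#' beta is strictly greater than `threshold`; at exactly the threshold it
#' is not called. Probes with no observed value in either arm are excluded
#' and reported in the `excluded` attribute.
#'
#' @param treated,vehicle [beta_matrix()] objects (or plain matrices)
#'   sharing the same probe set.
#' @param threshold absolute delta-beta cutoff (default 0.2).
#' @return data.frame with `probe_id`, `delta_beta`, `is_dm` and
#'   `direction` (`"hypo"` for negative delta beta, `"hyper"` otherwise),
#'   with excluded probe ids in `attr(, "excluded")`.
#' @export
call_dm <- function(treated, vehicle, threshold = 0.2) {
  tb <- if (inherits(treated, "beta_matrix")) treated$beta else treated
  vb <- if (inherits(vehicle, "beta_matrix")) vehicle$beta else vehicle
  if (!setequal(rownames(tb), rownames(vb))) {
    stop_input("treated and vehicle arms must share the same probe set")
  }
  if (ncol(tb) < 1L || ncol(vb) < 1L) stop_input("each arm needs at least one sample")
  vb <- vb[rownames(tb), , drop = FALSE]
  mt <- rowMeans(tb, na.rm = TRUE)
  mv <- rowMeans(vb, na.rm = TRUE)
  ok <- is.finite(mt) & is.finite(mv)
  excluded <- rownames(tb)[!ok]
  delta <- mt[ok] - mv[ok]
  res <- data.frame(
    probe_id = rownames(tb)[ok],
    delta_beta = unname(delta),
    is_dm = unname(abs(delta) > threshold),
    direction = ifelse(delta < 0, "hypo", "hyper"),
    stringsAsFactors = FALSE
  )
  attr(res, "excluded") <- excluded
  res
}

#' Correlation between EpiTOC age and CIMP methylation percentage
#'
#' @param age numeric vector of EpiTOC ages (or the data.frame from
#'   [epitoc_age()]).
#' @param cimp_percent numeric vector of CIMP percentages (or the
#'   data.frame from [cimp_percentage()]), paired with `age`.
#' @return Pearson correlation coefficient; `NA` (with a warning) when
#'   either variable has zero variance.
#' @export
correlate_age_vs_cimp <- function(age, cimp_percent) {
  if (is.data.frame(age)) age <- age$epitoc_age
  if (is.data.frame(cimp_percent)) cimp_percent <- cimp_percent$cimp_percent
  if (length(age) != length(cimp_percent)) stop_input("inputs must be paired")
  if (length(age) < 3L) stop_input("need at least 3 pairs")
  if (stats::sd(age) == 0 || stats::sd(cimp_percent) == 0) {
    warning("zero variance in age or CIMP percentage; correlation undefined")
    return(NA_real_)
  }
  stats::cor(age, cimp_percent, method = "pearson")
}
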