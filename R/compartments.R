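# Consensus Hi-C A/B compartment calling, feature-to-compartment
# assignment, and the open-chromatin enrichment (relative risk) statistic.

check_track <- function(tr) {
  req <- c("chrom", "start", "end", "label")
  if (!all(req %in% names(tr))) {
    stop_input("compartment track needs columns: ", paste(req, collapse = ", "))
  }
  ord <- order(tr$chrom, tr$start)
  tr <- tr[ord, , drop = FALSE]
  for (ch in unique(tr$chrom)) {
    b <- tr[tr$chrom == ch, ]
    if (any(b$start >= b$end)) stop_input("bin start must be < end")
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop_input("bins overlap on ", ch)
    }
  }
  rownames(tr) <- NULL
  tr
}

#' Consensus A/B compartment track
#'
#' Merges per-sample compartment call tracks on a shared bin grid by
#' unanimity: a bin is labeled A only if every sample calls it A, B only if
#' every sample calls it B, and `ambiguous` otherwise. Ambiguous bins are
#' retained in the track so that downstream feature assignment can exclude
#' the features falling into them.
#'
#' @param tracks list of per-sample data.frames with columns `chrom`,
#'   `start`, `end`, `label` (`"A"`/`"B"`); all tracks must share an
#'   identical bin grid (no resampling is attempted).
#' @return consensus track data.frame with `label` in
#'   `{"A", "B", "ambiguous"}`.
#' @export
consensus_compartments <- function(tracks) {
  if (!length(tracks)) stop_input("no tracks given")
  tracks <- lapply(tracks, check_track)
  grid <- tracks[[1]][c("chrom", "start", "end")]
  for (tr in tracks[-1]) {
    if (!identical(tr[c("chrom", "start", "end")], grid)) {
      stop_input("tracks do not share an identical bin grid")
    }
  }
  labels <- vapply(tracks, function(tr) tr$label, character(nrow(grid)))
  labels <- matrix(labels, nrow = nrow(grid))
  if (!all(labels %in% c("A", "B"))) {
    stop_input("per-sample labels must be A or B")
  }
  all_a <- rowSums(labels == "A") == ncol(labels)
  all_b <- rowSums(labels == "B") == ncol(labels)
  grid$label <- ifelse(all_a, "A", ifelse(all_b, "B", "ambiguous"))
  grid
}

#' Assign features to consensus compartments
#'
#' Each feature is represented by a single anchor point (a probe's
#' coordinate; a gene's transcription start, or optionally its midpoint)
#' and takes the label of the bin containing that point. Features whose
#' anchor falls in an ambiguous bin, or outside every bin, are `excluded`.
#' A = open chromatin, B = closed.
#'
#' @param features data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param consensus a [consensus_compartments()] track.
#' @param anchor `"start"` (default; probe coordinate / gene TSS) or
#'   `"midpoint"`.
#' @return data.frame with `feature_id` and `compartment` in
#'   `{"A", "B", "excluded"}`.
#' @export
assign_features <- function(features, consensus,
                            anchor = c("start", "midpoint")) {
  anchor <- match.arg(anchor)
  req <- c("feature_id", "chrom", "start", "end")
  if (!all(req %in% names(features))) {
    stop_input("features need columns: ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(features$start)) || any(!is.finite(features$end)) ||
      any(features$start < 0) || any(features$start >= features$end)) {
    stop_input("malformed feature coordinates")
  }
  pt <- if (anchor == "start") features$start else
    floor((features$start + features$end) / 2)

  out <- rep("excluded", nrow(features))
  for (ch in unique(features$chrom)) {
    fi <- which(features$chrom == ch)
    bins <- consensus[consensus$chrom == ch, , drop = FALSE]
    if (!nrow(bins)) next
    idx <- findInterval(pt[fi], bins$start)
    inside <- idx >= 1 & pt[fi] < bins$end[pmax(idx, 1)]
    lab <- bins$label[idx[inside]]
    out[fi[inside]] <- ifelse(lab == "ambiguous", "excluded", lab)
  }
  n_out <- sum(out == "excluded")
  if (n_out > 0) {
    message(n_out, " feature(s) excluded (ambiguous bin or no compartment info)")
  }
  data.frame(feature_id = features$feature_id, compartment = out,
             stringsAsFactors = FALSE)
}

#' Open-chromatin enrichment of a feature set (relative risk)
#'
#' Compares the proportion of a feature set (e.g. DM CpGs or differentially
#' expressed genes) in open (A) chromatin against the proportion among the
#' remaining background features: the relative risk is
#' `prop open(feature) / prop open(background excluding the feature set)`.
#' Full precision is retained; rounding to two decimals is applied only by
#' the print method.
#'
#' @param n_open_feature,n_closed_feature open/closed counts of the feature
#'   set.
#' @param n_open_background,n_closed_background open/closed counts of the
#'   full background (which contains the feature set).
#' @return object of class `enrichment_table`: a list with the four cells,
#'   `p_open_feature`, `p_open_background`, `p_open_background_excl` and
#'   `relative_risk` (`NA` with a warning on a zero denominator).
#' @export
open_chromatin_enrichment <- function(n_open_feature, n_closed_feature,
                                      n_open_background, n_closed_background) {
  cells <- c(n_open_feature, n_closed_feature,
             n_open_background, n_closed_background)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop_input("cell counts must be non-negative integers")
  }
  if (n_open_feature > n_open_background ||
      n_closed_feature > n_closed_background) {
    stop_input("feature set must be contained in the background")
  }
  n_feat <- n_open_feature + n_closed_feature
  rest_open <- n_open_background - n_open_feature
  rest_closed <- n_closed_background - n_closed_feature
  p_feat <- if (n_feat > 0) n_open_feature / n_feat else NA_real_
  p_rest <- if (rest_open + rest_closed > 0) {
    rest_open / (rest_open + rest_closed)
  } else NA_real_
  rr <- if (is.na(p_feat) || is.na(p_rest) || p_rest == 0) {
    warning("relative risk undefined (zero denominator)")
    NA_real_
  } else p_feat / p_rest

  structure(list(
    n_open_feature = n_open_feature,
    n_closed_feature = n_closed_feature,
    n_open_background = n_open_background,
    n_closed_background = n_closed_background,
    p_open_feature = p_feat,
    p_open_background = n_open_background /
      (n_open_background + n_closed_background),
    p_open_background_excl = p_rest,
    relative_risk = rr
  ), class = "enrichment_table")
}

#' Open-chromatin enrichment from compartment label vectors
#'
#' @param feature_labels named character vector of `"A"`/`"B"` labels for
#'   the feature set (excluded features removed beforehand).
#' @param background_labels named labels for the full background; the
#'   feature names must all occur in the background names.
#' @return an `enrichment_table`, see [open_chromatin_enrichment()].
#' @export
enrichment_from_labels <- function(feature_labels, background_labels) {
  if (is.null(names(feature_labels)) || is.null(names(background_labels))) {
    stop_input("label vectors must be named by feature id")
  }
  if (!all(names(feature_labels) %in% names(background_labels))) {
    stop_input("feature set must be a subset of the background")
  }
  if (!all(c(feature_labels, background_labels) %in% c("A", "B"))) {
    stop_input("labels must be A or B (drop excluded features first)")
  }
  open_chromatin_enrichment(
    sum(feature_labels == "A"), sum(feature_labels == "B"),
    sum(background_labels == "A"), sum(background_labels == "B")
  )
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("<enrichment_table>\n")
  cat(sprintf("  feature:    %d open / %d closed (prop open %.2f)\n",
              x$n_open_feature, x$n_closed_feature, x$p_open_feature))
  cat(sprintf("  background: %d open / %d closed (prop open %.2f)\n",
              x$n_open_background, x$n_closed_background, x$p_open_background))
  cat(sprintf("  relative risk (vs background excluding feature): %.2f\n",
              x$relative_risk))
  invisible(x)
}

#' @export
as.data.frame.enrichment_table <- function(x, ...) {
  data.frame(n_open_feature = x$n_open_feature,
             n_closed_feature = x$n_closed_feature,
             n_open_background = x$n_open_background,
             n_closed_background = x$n_closed_background,
             p_open_feature = x$p_open_feature,
             p_open_background = x$p_open_background,
             p_open_background_excl = x$p_open_background_excl,
             relative_risk = x$relative_risk)
}
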