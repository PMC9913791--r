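# Differential expression: median-of-ratios size factors, a
# negative-binomial Wald test with trend-shrunken moment dispersions, and
# the baseline decitabine-sensitivity signature.

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed against the per-gene geometric-mean
#' pseudo-reference, using genes expressed in every sample. Multiplying one
#' sample's counts by a constant scales that sample's factor by the same
#' constant; identical samples get identical factors.
#'
#' @param cm a [count_matrix()] or plain counts matrix.
#' @return named numeric vector of positive factors, one per sample.
#' @export
normalize_size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    stop_input("no gene has nonzero counts in every sample; ",
               "consider a pseudo-reference over positive counts")
  }
  logs <- log(counts[use, , drop = FALSE])
  ref <- rowMeans(logs)
  sf <- apply(logs, 2, function(lc) exp(stats::median(lc - ref)))
  if (any(sf <= 0)) stop_input("non-positive size factor")
  sf
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0,1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_input("p-values must lie in [0,1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Moment estimate of NB dispersion per gene from normalized counts,
# shrunk toward a 1/mu + const trend fitted across genes.
estimate_dispersions <- function(counts, sf, group, prior_n = 10) {
  z <- sweep(counts, 2, sf, "/")
  m_inv_sf <- mean(1 / sf)
  groups <- unique(group)
  n <- ncol(counts)
  # pooled within-group variance of normalized counts
  ss <- 0
  mu_all <- rowMeans(z)
  for (g in groups) {
    zi <- z[, group == g, drop = FALSE]
    ss <- ss + rowSums((zi - rowMeans(zi))^2)
  }
  v <- ss / (n - length(groups))
  raw <- (v - mu_all * m_inv_sf) / mu_all^2
  raw[!is.finite(raw)] <- NA
  raw_pos <- pmax(raw, 1e-8)

  # parametric trend a0 + a1/mu fitted on the raw moment estimates;
  # negative estimates stay in the fit (dropping them would bias the
  # trend upward), only the fitted curve is clamped
  use <- !is.na(raw) & mu_all > 1
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / mu_all[use]))
    a0 <- max(unname(stats::coef(fit)[1]), 1e-4)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
  } else {
    a0 <- max(mean(raw_pos, na.rm = TRUE), 1e-4)
    a1 <- 0
  }
  trend <- a0 + a1 / mu_all
  df <- n - length(groups)
  w <- prior_n / (prior_n + df)
  disp <- w * trend + (1 - w) * pmin(raw_pos, 10)
  pmax(disp, 1e-8)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Per-gene NB model with a group mean on each side of the contrast and a
#' gene-wise dispersion estimated by moments from normalized counts and
#' shrunk toward a fitted mean-dispersion trend. Group means are estimated
#' as size-factor-normalized totals; the Wald statistic for the log fold
#' change uses the NB Fisher information at the estimates, referred to the
#' standard normal. P-values are Benjamini-Hochberg adjusted across all tested
#' genes; genes with zero counts everywhere are excluded and reported in
#' `attr(, "excluded")`.
#'
#' @param cm a [count_matrix()] or plain counts matrix.
#' @param group vector of two group labels per sample; the log2 fold change
#'   is `level2` over `level1` of `factor(group)` (override with `ref`).
#' @param ref optional reference (denominator) group level.
#' @param sf optional size factors; computed with
#'   [normalize_size_factors()] when missing.
#' @param alpha significance level on the adjusted p-value for the `is_de`
#'   flag (default 0.05).
#' @return data.frame with `gene_id`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p`, `padj`, `is_de`.
#' @export
de_test <- function(cm, group, ref = NULL, sf = NULL, alpha = 0.05) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  group <- as.character(group)
  if (length(group) != ncol(counts)) stop_input("one group label per sample required")
  lev <- unique(group)
  if (length(lev) != 2L) stop_input("exactly two groups required")
  if (!is.null(ref)) {
    if (!ref %in% lev) stop_input("`ref` is not a group level")
    lev <- c(ref, setdiff(lev, ref))
  }
  if (min(table(group)) < 2L) {
    stop_input("each group needs at least 2 samples (dispersion unidentifiable)")
  }
  sf <- sf %||% normalize_size_factors(counts)

  nonzero <- rowSums(counts) > 0
  excluded <- rownames(counts)[!nonzero]
  counts <- counts[nonzero, , drop = FALSE]

  disp <- estimate_dispersions(counts, sf, group)
  i1 <- group == lev[1]
  i2 <- group == lev[2]
  s1 <- sum(sf[i1]); s2 <- sum(sf[i2])
  # shifted normalized group means; the half-count shift keeps zero groups finite
  m1 <- (rowSums(counts[, i1, drop = FALSE]) + 0.5) / s1
  m2 <- (rowSums(counts[, i2, drop = FALSE]) + 0.5) / s2

  info_g <- function(m, idx) {
    mu <- outer(m, sf[idx])
    rowSums(mu / (1 + disp * mu))
  }
  var_log <- 1 / info_g(m1, which(i1)) + 1 / info_g(m2, which(i2))
  lfc_ln <- log(m2) - log(m1)
  se_ln <- sqrt(var_log)
  stat <- lfc_ln / se_ln
  p <- 2 * stats::pnorm(-abs(stat))
  padj <- bh_adjust(p)

  res <- data.frame(
    gene_id = rownames(counts),
    base_mean = unname(rowMeans(sweep(counts, 2, sf, "/"))),
    log2fc = unname(lfc_ln / log(2)),
    se = unname(se_ln / log(2)),
    stat = unname(stat),
    p = unname(p),
    padj = unname(padj),
    is_de = unname(padj < alpha),
    stringsAsFactors = FALSE
  )
  attr(res, "excluded") <- excluded
  attr(res, "contrast") <- paste(lev[2], "vs", lev[1])
  res
}

#' Derive the baseline decitabine-sensitivity signature
#'
#' From a differential-expression comparison of sensitive versus
#' less-sensitive vehicle (baseline) samples, keeps genes with
#' `|log2fc| > fc_threshold` and `padj < padj_threshold`, orders by
#' ascending adjusted p-value (ties: larger absolute fold change first,
#' then gene id) and truncates to the top `n_top` genes.
#'
#' @param de_baseline a [de_test()] result with the sensitive group as the
#'   fold-change numerator.
#' @param fc_threshold absolute log2 fold-change cutoff (default 1).
#' @param padj_threshold adjusted p-value cutoff (default 0.05).
#' @param n_top maximum signature size (default 70).
#' @return data.frame with `gene_id`, `log2fc`, `padj` and `side`
#'   (`"up_in_sensitive"` / `"down_in_sensitive"`); empty with a warning
#'   when no gene passes.
#' @export
derive_signature <- function(de_baseline, fc_threshold = 1,
                             padj_threshold = 0.05, n_top = 70L) {
  req <- c("gene_id", "log2fc", "padj")
  if (!all(req %in% names(de_baseline))) {
    stop_input("`de_baseline` must carry gene_id, log2fc and padj")
  }
  pass <- de_baseline[abs(de_baseline$log2fc) > fc_threshold &
                        de_baseline$padj < padj_threshold, req, drop = FALSE]
  if (nrow(pass) == 0L) {
    warning("no gene passes the signature filters; empty signature")
    return(data.frame(gene_id = character(), log2fc = numeric(),
                      padj = numeric(), side = character(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(pass$padj, -abs(pass$log2fc), pass$gene_id)
  pass <- pass[utils::head(ord, n_top), , drop = FALSE]
  pass$side <- ifelse(pass$log2fc > 0, "up_in_sensitive", "down_in_sensitive")
  rownames(pass) <- NULL
  pass
}
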