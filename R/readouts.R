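# Pre-clinical readouts: bead-corrected absolute cell counts, normalized
# tumor growth, Kaplan-Meier estimation and the log-rank test.

#' Bead-corrected absolute cell count
#'
#' Converts flow-cytometry event counts into an absolute hCD45+ cell count
#' per volume of peripheral blood using counting beads spiked into a fixed
#' blood volume. The default formula is, exactly as used in the emulated
#' experimental protocol,
#'
#' `cell_count * bead_volume / (bead_count * cell_volume * bead_concentration)`.
#'
#' Its dimensional form (bead concentration in the denominator) differs
#' from the usual bead-counting convention; the alternative
#' `formula = "standard"` computes the conventional
#' `(cell_count / bead_count) * (bead_volume * bead_concentration) / cell_volume`
#' (cells/uL). Both are offered; see the methods vignette.
#'
#' @param cell_count hCD45+ gated events.
#' @param bead_count bead gated events (must be positive; zero signals a
#'   staining failure).
#' @param bead_volume bead suspension volume added (uL).
#' @param cell_volume blood volume stained (uL), 30 uL in the emulated
#'   protocol.
#' @param bead_concentration bead concentration (beads/uL).
#' @param formula `"as_published"` (default) or `"standard"`.
#' @return numeric vector of absolute counts (vectorized over inputs).
#' @export
absolute_cell_count <- function(cell_count, bead_count, bead_volume,
                                cell_volume = 30, bead_concentration,
                                formula = c("as_published", "standard")) {
  formula <- match.arg(formula)
  if (any(cell_count < 0) || any(bead_count < 0)) {
    stop_input("event counts must be non-negative")
  }
  if (any(bead_count == 0)) {
    stop_input("bead_count is zero (staining failure); cannot normalize")
  }
  if (any(bead_volume <= 0) || any(cell_volume <= 0) ||
      any(bead_concentration <= 0)) {
    stop_input("volumes and bead concentration must be positive")
  }
  switch(formula,
    as_published = (cell_count * bead_volume) /
      (bead_count * cell_volume * bead_concentration),
    standard = (cell_count / bead_count) *
      (bead_volume * bead_concentration) / cell_volume
  )
}

#' Normalized tumor growth ratio
#'
#' Tumor growth of an arm is the mean bead-corrected absolute hCD45+ count
#' on day 5 divided by the mean on day 1; the normalized ratio divides the
#' treated arm's growth by the vehicle arm's growth. Values below 1 mean
#' the treatment slowed (or reversed) expansion of circulating blasts
#' relative to vehicle.
#'
#' @param flow data.frame of flow records with columns `arm`, `day`,
#'   `hcd45_count`, `bead_count`, `bead_volume_ul`, `cell_volume_ul`,
#'   `bead_concentration_per_ul` (one model).
#' @param treated_arm,vehicle_arm arm labels (defaults `"DAC"` /
#'   `"vehicle"`).
#' @param days the two measurement days (default `c(1, 5)`).
#' @param formula passed to [absolute_cell_count()].
#' @return the normalized growth ratio (single number).
#' @export
normalized_tumor_growth <- function(flow, treated_arm = "DAC",
                                    vehicle_arm = "vehicle",
                                    days = c(1, 5),
                                    formula = "as_published") {
  flow$abs_count <- absolute_cell_count(
    flow$hcd45_count, flow$bead_count, flow$bead_volume_ul,
    flow$cell_volume_ul, flow$bead_concentration_per_ul, formula = formula)
  growth <- function(arm) {
    d1 <- flow$abs_count[flow$arm == arm & flow$day == days[1]]
    d5 <- flow$abs_count[flow$arm == arm & flow$day == days[2]]
    if (!length(d1) || !length(d5)) {
      stop_input("arm '", arm, "' is missing day ", days[1], " or day ",
                 days[2], " records")
    }
    if (mean(d1) <= 0) stop_input("day-", days[1], " average must be positive")
    mean(d5) / mean(d1)
  }
  growth(treated_arm) / growth(vehicle_arm)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function; censored records
#' reduce the risk set without triggering a step.
#'
#' @param time positive event/censoring times.
#' @param event 1 = endpoint reached, 0 = censored.
#' @return data.frame `time`, `n_risk`, `n_event`, `surv` (step function
#'   values; `surv` starts from S(0) = 1 and is non-increasing).
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop_input("need at least one record")
  if (any(time <= 0)) stop_input("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop_input("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event),
             surv = c(1, fit$surv))
}

#' Log-rank (Mantel-Cox) comparison of two survival arms
#'
#' Standard log-rank chi-square with one degree of freedom and a two-sided
#' p-value; optionally a permutation p-value obtained by resampling arm
#' labels, for small samples where the chi-square reference is doubtful.
#'
#' @param time,event survival times and event indicators across both arms.
#' @param group arm label per record (exactly two levels, both non-empty).
#' @param n_perm if > 0, also compute a permutation p-value from this many
#'   random label permutations.
#' @param seed seed for the permutation stream.
#' @return list with `statistic` (chi-square), `p` (asymptotic), and when
#'   requested `p_perm`; plus `band`, the significance band of the reported
#'   p-value (`p_perm` when computed, else `p`).
#' @export
logrank_test <- function(time, event, group, n_perm = 0L, seed = 1L) {
  group <- as.character(group)
  if (length(unique(group)) != 2L) stop_input("exactly two arms required")
  if (min(table(group)) < 1L) stop_input("empty arm")
  if (sum(event) < 1) stop_input("need at least one event")
  chisq_of <- function(g) {
    fit <- survival::survdiff(survival::Surv(time, event) ~ g)
    unname(fit$chisq)
  }
  obs <- chisq_of(group)
  p <- stats::pchisq(obs, df = 1, lower.tail = FALSE)
  out <- list(statistic = obs, p = p)
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    perm <- vapply(seq_len(n_perm), function(i) chisq_of(sample(group)),
                   numeric(1))
    out$p_perm <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
  }
  out$band <- significance_band(out$p_perm %||% out$p)
  out
}

#' Significance band of a p-value
#'
#' The conventional reporting bands used on the survival figures:
#' `ns` (p >= 0.05), `*` (< 0.05), `**` (< 0.01), `***` (< 0.001).
#'
#' @param p p-value(s).
#' @return character vector of bands.
#' @export
significance_band <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
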