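# Synthetic PDX cohort generator.
#
# Emulates, at desk scale, the structure of a 5-model vehicle/decitabine PDX
# trial: EPIC-like beta matrices with a CIMP panel spared from global
# treatment hypomethylation, negative-binomial RNA counts with a
# subgroup-dependent number of treatment-responsive genes, per-sample Hi-C
# A/B compartment tracks on a toy genome of contiguous 50 kb bins, and
# survival / flow-cytometry outcome tables. Truth tables (which probes were
# shifted, which genes respond, true bin labels) are always emitted so that
# every downstream stage can be recovery-tested.

#' Configuration for the synthetic PDX cohort
#'
#' All sizes, effect magnitudes and rates of the generator in one validated
#' object. Defaults encode the emulated study design: 5 PDX models split into
#' a more-sensitive (models 1-3) and a less-sensitive (models 4-5) subgroup,
#' vehicle and decitabine arms with 4 replicates each, a 1099-CpG CIMP panel
#' spared from the global treatment hypomethylation, 82% of probes and 74%
#' of genes located in open (A) chromatin, and more treatment-responsive
#' genes in the sensitive subgroup than in the less-sensitive one.
#'
#' @param n_probes number of array probes.
#' @param n_genes number of genes.
#' @param cimp_panel_size number of probes in the CIMP classification panel.
#' @param epitoc_panel_size number of probes in the EpiTOC mitotic-clock panel.
#' @param n_models number of PDX models.
#' @param replicates_per_arm biological replicates per model x arm (3 or 4).
#' @param sensitive_models integer indices of the more-sensitive models.
#' @param cimp_probability per-model probability that a CIMP-panel probe is
#'   methylated; recycled to `n_models`.
#' @param global_hypo_effect mean beta shift applied to affected probes in
#'   treated samples (negative = hypomethylation).
#' @param affected_probe_fraction fraction of eligible (non-CIMP when
#'   `cimp_spare`) probes that receive the treatment shift.
#' @param cimp_spare if `TRUE`, CIMP-panel probes receive no treatment shift.
#' @param noise_sd per-sample Gaussian noise on the beta scale.
#' @param detect_fail_rate fraction of entries given detection p > 0.05.
#' @param blacklist_fraction fraction of non-panel probes flagged as
#'   multimapping / SNP-within-5bp / meQTL stand-ins.
#' @param nb_dispersion negative-binomial dispersion of the count model.
#' @param count_meanlog,count_sdlog log-normal parameters of baseline gene
#'   expression means.
#' @param libsize_sdlog log-normal spread of per-sample library size factors.
#' @param n_responsive_genes_sensitive,n_responsive_genes_less numbers of
#'   treatment-responsive genes in sensitive / less-sensitive models; the
#'   less-sensitive set is a subset of the sensitive set, so it is also the
#'   set responding in every model.
#' @param responsive_lfc_range range of |log2 fold change| for responsive genes.
#' @param frac_up_in_responsive fraction of responsive genes that are
#'   up-regulated after treatment (majority positive among
#'   hypomethylation-linked genes).
#' @param responsive_open_fraction fraction of responsive genes drawn from
#'   open (A) chromatin bins; decitabine-responsive expression changes
#'   concentrate in active chromatin.
#' @param min_responsive_mean,min_capable_probes responsive genes are drawn
#'   from genes with baseline mean expression at least `min_responsive_mean`
#'   and at least `min_capable_probes` linked probes that can actually lose
#'   methylation (methylated at baseline and treatment-affected).
#' @param n_baseline_diff_genes,baseline_lfc_range number of genes whose
#'   baseline expression differs between the sensitive and less-sensitive
#'   subgroups (model-intrinsic differences feeding the sensitivity
#'   signature), and the |log2 fold change| range of those differences.
#' @param myc_set_size,myc_lfc size and (negative) log2 fold change of the
#'   synthetic "MYC target" set, down-regulated by treatment in every model.
#' @param open_fraction_probes,open_fraction_genes fractions of probes/genes
#'   placed in open (A) chromatin bins.
#' @param bin_size,n_bins toy genome: one linear chromosome of `n_bins`
#'   contiguous bins of `bin_size` bp.
#' @param fraction_a_bins fraction of bins whose true compartment is A.
#' @param n_compartment_samples number of per-sample Hi-C call tracks.
#' @param compartment_concordance probability that a sample track agrees
#'   with the true bin label.
#' @param hazard_scale named vector of exponential mean survival times (days)
#'   per arm (`vehicle`, `DAC_1cycle`, `DAC_2cycle`).
#' @param sensitive_hazard_factor multiplier on treated-arm survival scale
#'   for sensitive models.
#' @param mice_per_arm mice per model x arm in the survival experiment.
#' @param censor_day administrative censoring horizon (days).
#' @param vehicle_growth,treated_growth_sensitive,treated_growth_less fold
#'   change of circulating hCD45+ density from day 1 to day 5 by arm/subgroup.
#' @param seed integer master seed (mandatory).
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_probes = 20000L,
                          n_genes = 3000L,
                          cimp_panel_size = 1099L,
                          epitoc_panel_size = 200L,
                          n_models = 5L,
                          replicates_per_arm = 4L,
                          sensitive_models = 1:3,
                          cimp_probability = c(0.90, 0.45, 0.95, 0.90, 0.55),
                          global_hypo_effect = -0.25,
                          affected_probe_fraction = 0.6,
                          cimp_spare = TRUE,
                          noise_sd = 0.05,
                          detect_fail_rate = 0.005,
                          blacklist_fraction = 0.02,
                          nb_dispersion = 0.05,
                          count_meanlog = 5,
                          count_sdlog = 1.2,
                          libsize_sdlog = 0.15,
                          n_responsive_genes_sensitive = 400L,
                          n_responsive_genes_less = 80L,
                          responsive_lfc_range = c(1.5, 3),
                          frac_up_in_responsive = 0.7,
                          responsive_open_fraction = 0.9,
                          min_responsive_mean = 50,
                          min_capable_probes = 2L,
                          n_baseline_diff_genes = 100L,
                          baseline_lfc_range = c(1.5, 3),
                          myc_set_size = 30L,
                          myc_lfc = -2,
                          open_fraction_probes = 0.82,
                          open_fraction_genes = 0.74,
                          bin_size = 50000L,
                          n_bins = 2000L,
                          fraction_a_bins = 0.6,
                          n_compartment_samples = 4L,
                          compartment_concordance = 0.9,
                          hazard_scale = c(vehicle = 30, DAC_1cycle = 45,
                                           DAC_2cycle = 60),
                          sensitive_hazard_factor = 1.4,
                          mice_per_arm = 5L,
                          censor_day = 250,
                          vehicle_growth = 4,
                          treated_growth_sensitive = 0.5,
                          treated_growth_less = 2,
                          seed) {
  if (missing(seed)) stop_input("`seed` is mandatory")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  counts <- c("n_probes", "n_genes", "n_models", "replicates_per_arm",
              "bin_size", "n_bins", "n_compartment_samples", "mice_per_arm")
  for (f in counts) {
    if (!is_count(cfg[[f]]) || cfg[[f]] <= 0) stop_input("`", f, "` must be a positive count")
  }
  for (f in c("cimp_panel_size", "epitoc_panel_size", "myc_set_size",
              "n_responsive_genes_sensitive", "n_responsive_genes_less")) {
    if (!is_count(cfg[[f]])) stop_input("`", f, "` must be a non-negative count")
  }
  fracs <- c("affected_probe_fraction", "detect_fail_rate", "blacklist_fraction",
             "frac_up_in_responsive", "open_fraction_probes", "open_fraction_genes",
             "fraction_a_bins", "compartment_concordance",
             "responsive_open_fraction")
  for (f in fracs) {
    if (!is_fraction(cfg[[f]])) stop_input("`", f, "` must lie in [0,1]")
  }
  if (cfg$cimp_panel_size + cfg$epitoc_panel_size > cfg$n_probes) {
    stop_input("panel sizes exceed n_probes (cimp_panel_size + epitoc_panel_size must be <= n_probes)")
  }
  if (!cfg$replicates_per_arm %in% c(3L, 4L)) {
    stop_input("`replicates_per_arm` must be 3 or 4 (biological triplicates or quadruplets)")
  }
  if (cfg$n_responsive_genes_less > cfg$n_responsive_genes_sensitive) {
    stop_input("n_responsive_genes_sensitive must be >= n_responsive_genes_less")
  }
  if (cfg$myc_set_size > cfg$n_responsive_genes_less) {
    stop_input("myc_set_size must fit inside the commonly responsive set")
  }
  cfg$cimp_probability <- rep_len(cfg$cimp_probability, cfg$n_models)
  if (any(cfg$cimp_probability < 0 | cfg$cimp_probability > 1)) {
    stop_input("cimp_probability values must lie in [0,1]")
  }
  if (!all(cfg$sensitive_models %in% seq_len(cfg$n_models))) {
    stop_input("sensitive_models must index existing models")
  }
  if (!all(c("vehicle", "DAC_1cycle", "DAC_2cycle") %in% names(cfg$hazard_scale))) {
    stop_input("hazard_scale must name arms vehicle, DAC_1cycle, DAC_2cycle")
  }
  if (any(cfg$hazard_scale <= 0)) stop_input("hazard_scale values must be positive")
  if (cfg$nb_dispersion <= 0) stop_input("nb_dispersion must be positive")
  if (cfg$noise_sd < 0) stop_input("noise_sd must be non-negative")
  cfg
}

model_subgroup <- function(cfg, model_idx) {
  ifelse(model_idx %in% cfg$sensitive_models, "sensitive", "less_sensitive")
}

#' Generate the probe / gene / bin annotation for a synthetic cohort
#'
#' Places probes and genes on a toy genome (one linear chromosome of
#' contiguous fixed-width bins), draws true A/B compartment labels per bin,
#' assigns probes to genes (many-to-many, with region classes gene body /
#' promoter / enhancer), selects disjoint CIMP and EpiTOC probe panels, and
#' flags a blacklist of multimapping / SNP-within-5bp / meQTL stand-ins.
#' Probes (genes) land in A bins with probability `open_fraction_probes`
#' (`open_fraction_genes`).
#'
#' @param config a [cohort_config()].
#' @return a [probe_annotation()] whose `bins` element carries the true
#'   compartment labels.
#' @export
generate_probe_annotation <- function(config) {
  cfg <- validate_cohort_config(config)
  set.seed(stage_seed(cfg$seed, "annotation"))

  n_bins <- cfg$n_bins
  bins <- data.frame(
    chrom = "chrT",
    start = (seq_len(n_bins) - 1L) * cfg$bin_size,
    end = seq_len(n_bins) * cfg$bin_size,
    label = "B",
    stringsAsFactors = FALSE
  )
  n_a <- round(cfg$fraction_a_bins * n_bins)
  bins$label[sample.int(n_bins, n_a)] <- "A"
  a_bins <- which(bins$label == "A")
  b_bins <- which(bins$label == "B")

  place <- function(n, frac_open) {
    in_a <- stats::runif(n) < frac_open
    bin <- integer(n)
    bin[in_a] <- sample(a_bins, sum(in_a), replace = TRUE)
    bin[!in_a] <- sample(b_bins, sum(!in_a), replace = TRUE)
    bin
  }

  gene_bin <- place(cfg$n_genes, cfg$open_fraction_genes)
  tss <- bins$start[gene_bin] + sample.int(cfg$bin_size - 1L, cfg$n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("G%05d", seq_len(cfg$n_genes)),
    chrom = "chrT",
    start = tss,
    end = pmin(tss + 20000L, n_bins * cfg$bin_size),
    stringsAsFactors = FALSE
  )

  probe_bin <- place(cfg$n_probes, cfg$open_fraction_probes)
  pos <- bins$start[probe_bin] + sample.int(cfg$bin_size - 2L, cfg$n_probes, replace = TRUE)
  probes <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(cfg$n_probes)),
    chrom = "chrT",
    start = pos,
    end = pos + 2L,
    in_cimp_panel = FALSE,
    in_epitoc_panel = FALSE,
    blacklist_reason = "none",
    stringsAsFactors = FALSE
  )

  panel_idx <- sample.int(cfg$n_probes, cfg$cimp_panel_size + cfg$epitoc_panel_size)
  cimp_idx <- panel_idx[seq_len(cfg$cimp_panel_size)]
  epitoc_idx <- setdiff(panel_idx, cimp_idx)
  probes$in_cimp_panel[cimp_idx] <- TRUE
  probes$in_epitoc_panel[epitoc_idx] <- TRUE

  # panels are defined on the post-QC probe set, so blacklist stand-ins are
  # drawn from non-panel probes only
  non_panel <- which(!probes$in_cimp_panel & !probes$in_epitoc_panel)
  n_black <- round(cfg$blacklist_fraction * cfg$n_probes)
  n_black <- min(n_black, length(non_panel))
  if (n_black > 0) {
    bl <- sample(non_panel, n_black)
    probes$blacklist_reason[bl] <- sample(
      c("multimapping", "snp_within_5bp", "meqtl"), n_black, replace = TRUE)
  }

  n_links <- sample(0:2, cfg$n_probes, replace = TRUE, prob = c(0.25, 0.6, 0.15))
  link_probe <- rep(probes$probe_id, n_links)
  links <- data.frame(
    probe_id = link_probe,
    gene_id = genes$gene_id[sample.int(cfg$n_genes, length(link_probe), replace = TRUE)],
    region_class = sample(c("gene_body", "promoter", "enhancer"),
                          length(link_probe), replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)),
    stringsAsFactors = FALSE
  )
  links <- links[!duplicated(links[c("probe_id", "gene_id")]), , drop = FALSE]
  rownames(links) <- NULL

  probe_annotation(probes, links, genes = genes, bins = bins)
}

meth_sample_sheet <- function(cfg, arms = c("vehicle", "DAC")) {
  grid <- expand.grid(
    replicate = seq_len(cfg$replicates_per_arm),
    arm = arms,
    model = seq_len(cfg$n_models),
    stringsAsFactors = FALSE
  )
  data.frame(
    sample_id = sprintf("PDX%d_%s_r%d", grid$model, grid$arm, grid$replicate),
    model = paste0("PDX", grid$model),
    model_idx = grid$model,
    arm = grid$arm,
    subgroup = model_subgroup(cfg, grid$model),
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
}

#' Generate the methylation arm of the synthetic cohort
#'
#' Vehicle betas are drawn from a two-component mixture (methylated probes
#' concentrated near 0.8, unmethylated near 0.1) plus per-sample Gaussian
#' noise. CIMP-panel probes are methylated with each model's configured CIMP
#' probability; EpiTOC-panel baselines increase with that probability so the
#' mitotic clock and CIMP percentage are positively coupled. Treated arms
#' shift a fixed fraction of eligible probes by `global_hypo_effect`
#' (truncated to `[0,1]`), sparing the CIMP panel when `cimp_spare`. A small
#' fraction of detection p-values above 0.05 is injected.
#'
#' @param config a [cohort_config()].
#' @param annotation output of [generate_probe_annotation()].
#' @return list with `bm` (a [beta_matrix()] over all model x arm samples),
#'   `samples` (sample sheet), and `truth` (affected probe ids, per-probe
#'   treatment effect, per-model CIMP methylated states).
#' @export
generate_beta_cohort <- function(config, annotation) {
  cfg <- validate_cohort_config(config)
  set.seed(stage_seed(cfg$seed, "beta"))
  pr <- annotation$probes
  n <- nrow(pr)
  samples <- meth_sample_sheet(cfg)

  is_cimp <- pr$in_cimp_panel
  is_epitoc <- pr$in_epitoc_panel

  # shared (non-CIMP, non-EpiTOC) baselines: two-component beta mixture
  methylated <- stats::runif(n) < 0.55
  baseline <- ifelse(methylated, stats::rbeta(n, 40, 10), stats::rbeta(n, 5, 45))

  # per-model CIMP panel states and EpiTOC baselines
  cimp_state <- matrix(FALSE, n, cfg$n_models)
  base_model <- matrix(rep(baseline, cfg$n_models), n, cfg$n_models)
  for (m in seq_len(cfg$n_models)) {
    p <- cfg$cimp_probability[m]
    st <- stats::runif(sum(is_cimp)) < p
    cimp_state[is_cimp, m] <- st
    base_model[is_cimp, m] <- ifelse(st, stats::rbeta(sum(is_cimp), 40, 10),
                                     stats::rbeta(sum(is_cimp), 5, 45))
    mu <- clamp01(0.25 + 0.5 * p, 0.02)
    base_model[is_epitoc, m] <- stats::rbeta(sum(is_epitoc), mu * 30, (1 - mu) * 30)
  }

  eligible <- if (cfg$cimp_spare) which(!is_cimp) else seq_len(n)
  n_aff <- round(cfg$affected_probe_fraction * length(eligible))
  affected_idx <- sort(sample(eligible, n_aff))
  effect <- numeric(n)
  effect[affected_idx] <- cfg$global_hypo_effect + stats::rnorm(n_aff, 0, 0.05)

  beta <- matrix(NA_real_, n, nrow(samples),
                 dimnames = list(pr$probe_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    m <- samples$model_idx[j]
    mu <- base_model[, m]
    if (samples$arm[j] == "DAC") mu <- mu + effect
    beta[, j] <- clamp01(mu + stats::rnorm(n, 0, cfg$noise_sd))
  }

  detection_p <- matrix(stats::runif(length(beta), 0, 0.01), n, nrow(samples),
                        dimnames = dimnames(beta))
  fail <- stats::runif(length(beta)) < cfg$detect_fail_rate
  detection_p[fail] <- stats::runif(sum(fail), 0.0500001, 1)

  list(
    bm = beta_matrix(beta, detection_p),
    samples = samples,
    truth = list(
      affected_probes = pr$probe_id[affected_idx],
      # probes where the hypomethylating shift can fully express itself:
      # affected, methylated at baseline, outside the model-specific panels
      dm_capable_probes = pr$probe_id[
        intersect(affected_idx, which(methylated & !is_cimp & !is_epitoc))],
      probe_effect = stats::setNames(effect, pr$probe_id),
      cimp_state = cimp_state
    )
  )
}

#' Generate the RNA count arm of the synthetic cohort
#'
#' Counts are negative-binomial with log-normal baseline means and
#' per-sample library size factors. Treatment-responsive genes are chosen
#' among genes linked to hypomethylated (treatment-affected) probes: a
#' common set of `n_responsive_genes_less` genes responds in every model,
#' and sensitive models additionally respond on
#' `n_responsive_genes_sensitive - n_responsive_genes_less` further genes.
#' Responses are mostly up-regulation; a synthetic `MYC_TARGETS` subset of
#' the common set is down-regulated in every model. A small stand-in
#' gene-set collection (the MYC set plus random sets) is emitted for GSEA.
#'
#' @param config a [cohort_config()].
#' @param annotation output of [generate_probe_annotation()].
#' @param dm_truth the `truth` element of [generate_beta_cohort()] (links
#'   responsive genes to treatment-affected probes).
#' @return list with `cm` (a [count_matrix()]), `truth` (per-gene response
#'   table and per-sample true size factors) and `gene_sets` (named list).
#' @export
generate_counts <- function(config, annotation, dm_truth) {
  cfg <- validate_cohort_config(config)
  set.seed(stage_seed(cfg$seed, "counts"))
  genes <- annotation$genes$gene_id
  samples <- meth_sample_sheet(cfg)

  mu0 <- stats::setNames(stats::rlnorm(length(genes), cfg$count_meanlog,
                                       cfg$count_sdlog), genes)
  if (any(mu0 <= 0)) stop_input("non-positive NB mean generated")
  sf_true <- stats::setNames(stats::rlnorm(nrow(samples), 0, cfg$libsize_sdlog),
                             samples$sample_id)

  # responsive genes: expressed, linked to enough probes that can actually
  # lose methylation, and located mostly in open chromatin
  capable <- dm_truth$dm_capable_probes %||% dm_truth$affected_probes
  link_cap <- annotation$links[annotation$links$probe_id %in% capable, ]
  n_cap <- table(link_cap$gene_id)
  candidates <- intersect(
    names(n_cap)[n_cap >= cfg$min_capable_probes],
    genes[mu0 >= cfg$min_responsive_mean])
  if (length(candidates) < cfg$n_responsive_genes_sensitive) {
    stop_input("not enough hypomethylation-linked expressed genes to host ",
               "the responsive sets; increase affected_probe_fraction, ",
               "gene links, or lower min_capable_probes")
  }
  gene_bin <- findInterval(annotation$genes$start, annotation$bins$start)
  gene_open <- stats::setNames(annotation$bins$label[gene_bin] == "A", genes)
  n_open_target <- round(cfg$responsive_open_fraction *
                           cfg$n_responsive_genes_sensitive)
  cand_open <- candidates[gene_open[candidates]]
  cand_closed <- candidates[!gene_open[candidates]]
  take_open <- min(n_open_target, length(cand_open))
  take_closed <- min(cfg$n_responsive_genes_sensitive - take_open,
                     length(cand_closed))
  sens_set <- c(sample(cand_open, take_open), sample(cand_closed, take_closed))
  short <- cfg$n_responsive_genes_sensitive - length(sens_set)
  if (short > 0) sens_set <- c(sens_set, sample(setdiff(candidates, sens_set), short))
  sens_set <- sort(sens_set)
  common_set <- sort(sample(sens_set, cfg$n_responsive_genes_less))
  myc_set <- sort(sample(common_set, cfg$myc_set_size))

  lfc <- stats::setNames(numeric(length(genes)), genes)
  resp <- setdiff(sens_set, myc_set)
  sign <- ifelse(stats::runif(length(resp)) < cfg$frac_up_in_responsive, 1, -1)
  lfc[resp] <- sign * stats::runif(length(resp), cfg$responsive_lfc_range[1],
                                   cfg$responsive_lfc_range[2])
  lfc[myc_set] <- cfg$myc_lfc

  # model-intrinsic baseline differences between subgroups (the substrate
  # of the sensitivity signature), on genes outside the responsive sets
  base_pool <- setdiff(genes[mu0 >= 20], sens_set)
  n_base <- min(cfg$n_baseline_diff_genes, length(base_pool))
  base_set <- sort(sample(base_pool, n_base))
  base_lfc <- stats::setNames(numeric(length(genes)), genes)
  base_lfc[base_set] <- sample(c(-1, 1), n_base, replace = TRUE) *
    stats::runif(n_base, cfg$baseline_lfc_range[1], cfg$baseline_lfc_range[2])

  counts <- matrix(0L, length(genes), nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  size <- 1 / cfg$nb_dispersion
  for (j in seq_len(nrow(samples))) {
    mu <- mu0
    if (samples$subgroup[j] == "sensitive") mu <- mu * 2^base_lfc
    if (samples$arm[j] == "DAC") {
      active <- if (samples$subgroup[j] == "sensitive") sens_set else common_set
      mu[active] <- mu[active] * 2^lfc[active]
    }
    counts[, j] <- stats::rnbinom(length(genes), mu = sf_true[j] * mu, size = size)
  }

  responsive_in <- rep("none", length(genes))
  responsive_in[genes %in% sens_set] <- "sensitive_only"
  responsive_in[genes %in% common_set] <- "all"
  truth_genes <- data.frame(
    gene_id = genes,
    lfc = unname(lfc),
    responsive_in = responsive_in,
    in_myc_set = genes %in% myc_set,
    baseline_lfc = unname(base_lfc),
    stringsAsFactors = FALSE
  )

  other_sets <- lapply(seq_len(9), function(i) sort(sample(genes, 30)))
  names(other_sets) <- sprintf("RANDOM_SET_%02d", seq_along(other_sets))
  gene_sets <- c(list(MYC_TARGETS = myc_set), other_sets)

  list(
    cm = count_matrix(counts, samples),
    truth = list(genes = truth_genes, size_factors = sf_true),
    gene_sets = gene_sets
  )
}

#' Generate compartment tracks and in-vivo outcome tables
#'
#' Produces per-sample A/B call tracks over the toy-genome bins (each bin
#' agrees with the true label with probability `compartment_concordance`),
#' an exponential survival table over three arms (vehicle, one and two
#' decitabine cycles; treated arms live longer, sensitive models longer
#' still), and a flow-cytometry table with counting-bead events for
#' bead-corrected leukemic-burden estimation (circulating hCD45+ density
#' grows in vehicle mice and is reduced by treatment, more in the sensitive
#' subgroup).
#'
#' @param config a [cohort_config()].
#' @param annotation output of [generate_probe_annotation()].
#' @return list with `tracks` (list of per-sample bin data frames),
#'   `survival` (model, arm, time_days, event), `flow` (one row per
#'   mouse-day with bead and cell event counts) and `truth` (true bin
#'   labels, per-arm survival scales, growth factors).
#' @export
generate_compartments_and_outcomes <- function(config, annotation) {
  cfg <- validate_cohort_config(config)
  bins <- annotation$bins
  if (is.null(bins)) stop_input("annotation carries no bin table")

  set.seed(stage_seed(cfg$seed, "compartments"))
  tracks <- lapply(seq_len(cfg$n_compartment_samples), function(s) {
    agree <- stats::runif(nrow(bins)) < cfg$compartment_concordance
    lab <- ifelse(agree, bins$label, ifelse(bins$label == "A", "B", "A"))
    data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
               label = lab, stringsAsFactors = FALSE)
  })
  names(tracks) <- sprintf("TALL%d", seq_along(tracks))

  set.seed(stage_seed(cfg$seed, "survival"))
  arms <- c("vehicle", "DAC_1cycle", "DAC_2cycle")
  grid <- expand.grid(mouse = seq_len(cfg$mice_per_arm), arm = arms,
                      model = seq_len(cfg$n_models), stringsAsFactors = FALSE)
  scale <- cfg$hazard_scale[grid$arm] *
    ifelse(grid$arm != "vehicle" & grid$model %in% cfg$sensitive_models,
           cfg$sensitive_hazard_factor, 1)
  t_raw <- stats::rexp(nrow(grid), rate = 1 / scale)
  survival <- data.frame(
    model = paste0("PDX", grid$model),
    arm = grid$arm,
    mouse = sprintf("PDX%d_%s_m%d", grid$model, grid$arm, grid$mouse),
    time_days = round(pmin(t_raw, cfg$censor_day), 1),
    event = as.integer(t_raw <= cfg$censor_day),
    stringsAsFactors = FALSE
  )
  survival$time_days[survival$time_days <= 0] <- 0.1

  set.seed(stage_seed(cfg$seed, "flow"))
  fgrid <- expand.grid(mouse = seq_len(cfg$mice_per_arm), day = c(1L, 5L),
                       arm = c("vehicle", "DAC"),
                       model = seq_len(cfg$n_models), stringsAsFactors = FALSE)
  subgroup <- model_subgroup(cfg, fgrid$model)
  growth <- ifelse(fgrid$arm == "vehicle", cfg$vehicle_growth,
                   ifelse(subgroup == "sensitive", cfg$treated_growth_sensitive,
                          cfg$treated_growth_less))
  base_lambda <- stats::rlnorm(nrow(fgrid), log(2000), 0.2)
  lambda <- ifelse(fgrid$day == 1L, base_lambda, base_lambda * growth)
  bead_conc <- 50
  bead_vol <- 50
  flow <- data.frame(
    model = paste0("PDX", fgrid$model),
    arm = fgrid$arm,
    subgroup = subgroup,
    mouse = sprintf("PDX%d_%s_m%d", fgrid$model, fgrid$arm, fgrid$mouse),
    day = fgrid$day,
    hcd45_count = stats::rpois(nrow(fgrid), lambda),
    mcd45_count = stats::rpois(nrow(fgrid), ifelse(fgrid$arm == "DAC" & fgrid$day == 5L,
                                                   900, 3000)),
    bead_count = stats::rpois(nrow(fgrid), bead_conc * bead_vol),
    bead_volume_ul = bead_vol,
    cell_volume_ul = 30,
    bead_concentration_per_ul = bead_conc,
    stringsAsFactors = FALSE
  )

  list(
    tracks = tracks,
    survival = survival,
    flow = flow,
    truth = list(bins = bins,
                 survival_scale = cfg$hazard_scale,
                 growth = c(vehicle = cfg$vehicle_growth,
                            sensitive = cfg$treated_growth_sensitive,
                            less_sensitive = cfg$treated_growth_less))
  )
}

#' Generate the full synthetic cohort
#'
#' Convenience wrapper running all four generator stages with seeds derived
#' from the single configured master seed. Identical config (including seed)
#' yields byte-identical outputs.
#'
#' @param config a [cohort_config()].
#' @return list with elements `config`, `annotation`, `meth`, `rna`,
#'   `outcomes` (the stage outputs, truth tables included).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  ann <- generate_probe_annotation(cfg)
  meth <- generate_beta_cohort(cfg, ann)
  rna <- generate_counts(cfg, ann, meth$truth)
  outcomes <- generate_compartments_and_outcomes(cfg, ann)
  list(config = cfg, annotation = ann, meth = meth, rna = rna,
       outcomes = outcomes)
}
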