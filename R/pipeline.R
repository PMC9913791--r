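# End-to-end pipeline: generate (or load) a cohort, run QC, CIMP / EpiTOC,
# differential methylation, differential expression, GSEA, integration,
# compartment enrichment and pre-clinical readouts, writing every result
# table plus a machine-readable run manifest.

#' Default run configuration
#'
#' Analysis thresholds mirror the emulated study: detection p 0.05, |delta
#' beta| 0.2, adjusted p 0.05, CIMP+ above 40% methylated panel CpGs with a
#' 0.3 methylated-beta cutoff, signature filters |log2FC| > 1 and adjusted
#' p < 0.05 with at most 70 genes, KNN imputation with k = 10.
#'
#' @param seed integer master seed.
#' @param synthetic named list of [cohort_config()] overrides (an empty
#'   list means generator defaults).
#' @return a run-configuration list, serializable to YAML.
#' @export
default_run_config <- function(seed = 1L, synthetic = list()) {
  list(
    seed = as.integer(seed),
    thresholds = list(
      detection_alpha = 0.05,
      delta_beta = 0.2,
      padj = 0.05,
      cimp_class_threshold = 40,
      methylated_beta = 0.3,
      signature_fc = 1,
      signature_n = 70L,
      knn_k = 10L
    ),
    gsea = list(n_perm = 500L),
    synthetic = synthetic
  )
}

#' Read a run configuration from a YAML key-value file
#'
#' Unset fields fall back to [default_run_config()].
#'
#' @param path YAML file.
#' @return run-configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop_input("config must set `seed`")
  base <- default_run_config(cfg$seed)
  base$thresholds <- utils::modifyList(base$thresholds, cfg$thresholds %||% list())
  base$gsea <- utils::modifyList(base$gsea, cfg$gsea %||% list())
  base$synthetic <- cfg$synthetic %||% base$synthetic
  base$inputs <- cfg$inputs
  base
}

validate_thresholds <- function(th) {
  stopifnot(
    is_fraction(th$detection_alpha),
    th$delta_beta > 0, th$delta_beta < 1,
    is_fraction(th$padj),
    th$cimp_class_threshold >= 0, th$cimp_class_threshold <= 100,
    is_fraction(th$methylated_beta),
    th$signature_fc >= 0,
    is_count(th$signature_n), th$signature_n >= 1,
    is_count(th$knn_k), th$knn_k >= 1
  )
  invisible(th)
}

load_cohort_inputs <- function(inputs) {
  need <- c("beta", "annotation", "counts", "samples", "tracks",
            "survival", "flow", "gene_sets")
  missing <- setdiff(need, names(inputs))
  if (length(missing)) {
    stop_input("config is missing input path(s): ", paste(missing, collapse = ", "),
               " (and no synthetic spec is present)")
  }
  ann <- read_annotation(inputs$annotation, genes_path = inputs$genes,
                         bins_path = inputs$bins)
  samples <- read_tsv(inputs$samples)
  bm <- read_beta_matrix(inputs$beta, inputs$detection_p)
  cm <- read_count_matrix(inputs$counts, inputs$samples)
  tracks <- lapply(inputs$tracks, read_tsv)
  names(tracks) <- basename(unlist(inputs$tracks))
  list(
    config = NULL,
    annotation = ann,
    meth = list(bm = bm, samples = samples, truth = NULL),
    rna = list(cm = cm, truth = NULL, gene_sets = read_gmt(inputs$gene_sets)),
    outcomes = list(tracks = tracks,
                    survival = utils::read.csv(inputs$survival,
                                               stringsAsFactors = FALSE),
                    flow = utils::read.csv(inputs$flow, stringsAsFactors = FALSE),
                    truth = NULL)
  )
}

pipeline_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  wall <- proc.time()[["elapsed"]] - t0
  pf <- parent.frame()
  if (exists("walls", pf, inherits = FALSE)) pf$walls[[name]] <- wall
  list(value = value, wall = wall)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on a synthetic cohort (or on
#' user-supplied input files named in the config), writing result tables
#' and a manifest (`manifest.tsv`: stage, file, md5 checksum, rows, wall
#' time) under `outdir`. The configuration actually used is serialized to
#' `run_config.yaml`. Reruns with the same config and seed reproduce the
#' checksums of all output tables.
#'
#' @param config a run-configuration list ([default_run_config()]) or the
#'   path to a YAML config file.
#' @param outdir output directory.
#' @param seed optional override of the config seed.
#' @return invisibly, a list with `outdir`, the `manifest` data.frame and
#'   the in-memory `results`.
#' @export
run_pipeline <- function(config = default_run_config(), outdir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) stop_input("config must set `seed`")
  th <- validate_thresholds(config$thresholds)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list()
  walls <- list()
  emit <- function(stage, name, df, writer = write_tsv) {
    path <- file.path(outdir, name)
    writer(df, path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = name,
      md5 = unname(tools::md5sum(path)),
      n_rows = if (is.data.frame(df)) nrow(df) else NA_integer_,
      stringsAsFactors = FALSE)
    invisible(path)
  }
  write_csv <- function(df, path) utils::write.csv(df, path, row.names = FALSE)

  # -- simulate / load ------------------------------------------------------
  st <- pipeline_stage("simulate", {
    if (!is.null(config$inputs)) {
      load_cohort_inputs(config$inputs)
    } else if (!is.null(config$synthetic)) {
      cc <- do.call(cohort_config, c(config$synthetic, list(seed = config$seed)))
      cohort <- generate_cohort(cc)
      write_cohort(cohort, file.path(outdir, "cohort"))
      cohort
    } else {
      stop_input("config has neither `inputs` paths nor a `synthetic` spec")
    }
  })
  cohort <- st$value
  ann <- cohort$annotation
  samples <- cohort$meth$samples

  # -- QC -------------------------------------------------------------------
  st <- pipeline_stage("qc", apply_probe_qc(cohort$meth$bm, ann,
                                            detection_alpha = th$detection_alpha))
  bm <- st$value
  emit("qc", "qc_log.tsv", data.frame(
    metric = names(bm$qc_log), value = unlist(bm$qc_log, use.names = FALSE)))

  # -- CIMP -----------------------------------------------------------------
  st <- pipeline_stage("cimp", {
    cc <- cimp_percentage(bm, ann, methylated_cutoff = th$methylated_beta,
                          class_threshold = th$cimp_class_threshold)
    merge(cc, samples[c("sample_id", "model", "arm", "subgroup")],
          by = "sample_id")
  })
  cimp <- st$value
  emit("cimp", "cimp_calls.csv", cimp, write_csv)
  cimp_model <- stats::aggregate(cimp_percent ~ model,
                                 data = cimp[cimp$arm == "vehicle", ],
                                 FUN = mean)
  cimp_model$cimp_class <- cimp_class(cimp_model$cimp_percent,
                                      th$cimp_class_threshold)
  emit("cimp", "cimp_models.csv", cimp_model, write_csv)

  # -- EpiTOC (KNN imputation on the panel, then mean beta) -----------------
  st <- pipeline_stage("epitoc", {
    panel_ids <- intersect(ann$probes$probe_id[ann$probes$in_epitoc_panel],
                           rownames(bm$beta))
    sub <- beta_matrix(bm$beta[panel_ids, , drop = FALSE],
                       bm$detection_p[panel_ids, , drop = FALSE])
    sub <- impute_missing_knn(sub, k = min(th$knn_k, length(panel_ids) - 1L))
    ea <- epitoc_age(sub, ann)
    merge(ea, samples[c("sample_id", "model", "arm", "subgroup")],
          by = "sample_id")
  })
  epitoc <- st$value
  emit("epitoc", "epitoc_age.csv", epitoc, write_csv)
  age_cimp <- merge(
    stats::aggregate(epitoc_age ~ model, data = epitoc[epitoc$arm == "vehicle", ],
                     FUN = mean),
    cimp_model[c("model", "cimp_percent")], by = "model")
  r_age_cimp <- correlate_age_vs_cimp(age_cimp$epitoc_age, age_cimp$cimp_percent)

  # -- differential methylation --------------------------------------------
  models <- unique(samples$model)
  arm_cols <- function(df, md, a) df$sample_id[df$model %in% md & df$arm == a]
  st <- pipeline_stage("dm", {
    dm_by_model <- lapply(models, function(m) {
      call_dm(bm$beta[, arm_cols(samples, m, "DAC"), drop = FALSE],
              bm$beta[, arm_cols(samples, m, "vehicle"), drop = FALSE],
              threshold = th$delta_beta)
    })
    names(dm_by_model) <- models
    subgroups <- unique(samples$subgroup)
    dm_by_subgroup <- lapply(subgroups, function(sg) {
      md <- unique(samples$model[samples$subgroup == sg])
      call_dm(bm$beta[, arm_cols(samples, md, "DAC"), drop = FALSE],
              bm$beta[, arm_cols(samples, md, "vehicle"), drop = FALSE],
              threshold = th$delta_beta)
    })
    names(dm_by_subgroup) <- subgroups
    list(model = dm_by_model, subgroup = dm_by_subgroup)
  })
  dm <- st$value
  for (m in models) {
    emit("dm", sprintf("dm_%s.tsv", m), dm$model[[m]])
  }

  # -- differential expression ---------------------------------------------
  cm <- cohort$rna$cm
  rna_samples <- cm$samples
  st <- pipeline_stage("de", {
    de_by_model <- lapply(models, function(m) {
      idx <- rna_samples$model == m
      de_test(cm$counts[, idx, drop = FALSE], rna_samples$arm[idx],
              ref = "vehicle", alpha = th$padj)
    })
    names(de_by_model) <- models
    de_by_subgroup <- lapply(unique(rna_samples$subgroup), function(sg) {
      idx <- rna_samples$subgroup == sg
      de_test(cm$counts[, idx, drop = FALSE], rna_samples$arm[idx],
              ref = "vehicle", alpha = th$padj)
    })
    names(de_by_subgroup) <- unique(rna_samples$subgroup)
    base_idx <- rna_samples$arm == "vehicle"
    de_baseline <- de_test(cm$counts[, base_idx, drop = FALSE],
                           rna_samples$subgroup[base_idx],
                           ref = "less_sensitive", alpha = th$padj)
    list(model = de_by_model, subgroup = de_by_subgroup,
         baseline = de_baseline)
  })
  de <- st$value
  for (m in models) emit("de", sprintf("de_%s.tsv", m), de$model[[m]])
  for (sg in names(de$subgroup)) emit("de", sprintf("de_%s.tsv", sg), de$subgroup[[sg]])
  emit("de", "de_baseline_sensitive_vs_less.tsv", de$baseline)

  # -- GSEA -----------------------------------------------------------------
  st <- pipeline_stage("gsea", {
    res <- lapply(models, function(m) {
      d <- de$model[[m]]
      g <- preranked_gsea(stats::setNames(d$stat, d$gene_id),
                          cohort$rna$gene_sets,
                          n_perm = config$gsea$n_perm,
                          seed = stage_seed(config$seed, "gsea"))
      g$model <- m
      g
    })
    do.call(rbind, res)
  })
  gsea <- st$value
  emit("gsea", "gsea.tsv", gsea)

  # -- integration ----------------------------------------------------------
  st <- pipeline_stage("integrate", {
    gm_model <- lapply(models, function(m) summarize_gene_methylation(dm$model[[m]], ann))
    names(gm_model) <- models
    table1 <- do.call(rbind, lapply(models, function(m) {
      build_integration_table(gm_model[[m]], de$model[[m]], dm$model[[m]],
                              model = m, de_alpha = th$padj)
    }))
    table3 <- do.call(rbind, lapply(names(dm$subgroup), function(sg) {
      gm <- summarize_gene_methylation(dm$subgroup[[sg]], ann)
      build_integration_table(gm, de$subgroup[[sg]], dm$subgroup[[sg]],
                              model = sg, de_alpha = th$padj)
    }))
    joint_sets <- function(dir_sign) {
      lapply(models, function(m) {
        gm <- gm_model[[m]]
        d <- de$model[[m]]
        hypo <- gm$gene_id[gm$n_hypo > 0]
        deg <- d$gene_id[d$padj < th$padj &
                           (if (dir_sign > 0) d$log2fc > 0 else d$log2fc < 0)]
        intersect(hypo, deg)
      })
    }
    up_sets <- joint_sets(1); down_sets <- joint_sets(-1)
    names(up_sets) <- names(down_sets) <- models
    n <- length(models)
    concord <- rbind(
      data.frame(direction = "hypo_up", k = n,
                 gene_id = cross_model_concordance(up_sets, n),
                 stringsAsFactors = FALSE),
      data.frame(direction = "hypo_down", k = n,
                 gene_id = cross_model_concordance(down_sets, n),
                 stringsAsFactors = FALSE),
      data.frame(direction = "hypo_up", k = n - 1L,
                 gene_id = cross_model_concordance(up_sets, n - 1L),
                 stringsAsFactors = FALSE)
    )
    list(table1 = table1, table3 = table3, concordance = concord,
         gm_model = gm_model)
  })
  integration <- st$value
  emit("integrate", "integration_by_model.csv", integration$table1, write_csv)
  emit("integrate", "integration_by_subgroup.csv", integration$table3, write_csv)
  emit("integrate", "concordant_genes.tsv", integration$concordance)

  # -- compartments ---------------------------------------------------------
  st <- pipeline_stage("compartments", {
    consensus <- consensus_compartments(cohort$outcomes$tracks)
    probe_feats <- data.frame(feature_id = ann$probes$probe_id,
                              chrom = ann$probes$chrom,
                              start = ann$probes$start, end = ann$probes$end,
                              stringsAsFactors = FALSE)
    probe_lab <- assign_features(probe_feats, consensus)
    gene_feats <- data.frame(feature_id = ann$genes$gene_id,
                             chrom = ann$genes$chrom,
                             start = ann$genes$start, end = ann$genes$end,
                             stringsAsFactors = FALSE)
    gene_lab <- assign_features(gene_feats, consensus)
    plab <- stats::setNames(probe_lab$compartment, probe_lab$feature_id)
    plab <- plab[plab != "excluded"]
    glab <- stats::setNames(gene_lab$compartment, gene_lab$feature_id)
    glab <- glab[glab != "excluded"]

    rows <- list()
    for (sg in names(dm$subgroup)) {
      d <- dm$subgroup[[sg]]
      dm_ids <- intersect(d$probe_id[d$is_dm], names(plab))
      et <- as.data.frame(enrichment_from_labels(plab[dm_ids], plab))
      et$feature <- "DM_CpG"; et$subgroup <- sg
      rows[[length(rows) + 1L]] <- et
      dd <- de$subgroup[[sg]]
      deg_ids <- intersect(dd$gene_id[dd$is_de], names(glab))
      et <- as.data.frame(enrichment_from_labels(glab[deg_ids], glab))
      et$feature <- "DEG"; et$subgroup <- sg
      rows[[length(rows) + 1L]] <- et
    }
    table4 <- do.call(rbind, rows)
    table4 <- table4[c("subgroup", "feature",
                       setdiff(names(table4), c("subgroup", "feature")))]
    list(consensus = consensus, probe_labels = probe_lab,
         gene_labels = gene_lab, table4 = table4)
  })
  comp <- st$value
  emit("compartments", "consensus_compartments.tsv", comp$consensus)
  emit("compartments", "enrichment_table4.csv", comp$table4, write_csv)

  # -- pre-clinical readouts ------------------------------------------------
  st <- pipeline_stage("readouts", {
    flow <- cohort$outcomes$flow
    growth <- do.call(rbind, lapply(models, function(m) {
      data.frame(model = m,
                 growth_ratio = normalized_tumor_growth(flow[flow$model == m, ]),
                 stringsAsFactors = FALSE)
    }))
    surv <- cohort$outcomes$survival
    lr <- do.call(rbind, lapply(models, function(m) {
      do.call(rbind, lapply(c("DAC_1cycle", "DAC_2cycle"), function(a) {
        s <- surv[surv$model == m & surv$arm %in% c("vehicle", a), ]
        t <- logrank_test(s$time_days, s$event, s$arm)
        data.frame(model = m, comparison = paste0("vehicle_vs_", a),
                   chisq = t$statistic, p = t$p, band = t$band,
                   stringsAsFactors = FALSE)
      }))
    }))
    km <- do.call(rbind, lapply(split(surv, surv[c("arm", "model")]), function(s) {
      if (!nrow(s)) return(NULL)
      cbind(model = s$model[1], arm = s$arm[1],
            km_estimate(s$time_days, s$event))
    }))
    rownames(km) <- NULL
    list(growth = growth, logrank = lr, km = km)
  })
  readouts <- st$value
  emit("readouts", "growth_ratios.csv", readouts$growth, write_csv)
  emit("readouts", "logrank.csv", readouts$logrank, write_csv)
  emit("readouts", "km_curves.tsv", readouts$km)

  # -- sensitivity signature ------------------------------------------------
  st <- pipeline_stage("signature", {
    derive_signature(de$baseline, fc_threshold = th$signature_fc,
                     padj_threshold = th$padj, n_top = th$signature_n)
  })
  signature <- st$value
  emit("signature", "sensitivity_signature.tsv", signature)

  cfg_out <- config
  cfg_out$synthetic <- if (!is.null(cohort$config)) {
    unclass(cohort$config)
  } else config$synthetic
  yaml::write_yaml(cfg_out, file.path(outdir, "run_config.yaml"))

  manifest <- do.call(rbind, manifest)
  manifest$wall_time_s <- vapply(manifest$stage, function(s) {
    round(walls[[s]] %||% NA_real_, 3)
  }, numeric(1))
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))

  invisible(list(
    outdir = outdir,
    manifest = manifest,
    results = list(
      cohort = cohort, qc = bm, cimp = cimp, cimp_model = cimp_model,
      epitoc = epitoc, r_age_cimp = r_age_cimp, dm = dm, de = de,
      gsea = gsea, integration = integration, compartments = comp,
      readouts = readouts, signature = signature
    )
  ))
}
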