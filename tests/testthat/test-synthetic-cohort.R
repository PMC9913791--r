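# The synthetic-cohort generator: configuration validation, determinism,
# and the statistical structure the downstream analyses assume.

test_that("config validation rejects impossible designs", {
  expect_error(cohort_config(seed = 1, cimp_panel_size = 19000L,
                             epitoc_panel_size = 2000L),
               "panel sizes")
  expect_error(cohort_config(seed = 1, replicates_per_arm = 5L), "3 or 4")
  expect_error(cohort_config(seed = 1, affected_probe_fraction = 1.2), "\\[0,1\\]")
  expect_error(cohort_config(seed = 1, n_responsive_genes_sensitive = 10L,
                             n_responsive_genes_less = 20L), ">=")
  expect_error(cohort_config(), "seed")
})

test_that("annotation has the configured panel structure", {
  ann <- default_cohort()$annotation
  expect_equal(sum(ann$probes$in_cimp_panel), 1099L)
  expect_equal(sum(ann$probes$in_epitoc_panel), 200L)
  expect_false(any(ann$probes$in_cimp_panel & ann$probes$in_epitoc_panel))
  expect_true(all(ann$probes$start < ann$probes$end))
  expect_true(all(ann$links$region_class %in%
                    c("gene_body", "promoter", "enhancer")))
  # empty CIMP panel is allowed but flags downstream
  ann0 <- generate_probe_annotation(
    cohort_config(seed = 1, n_probes = 500L, n_genes = 50L, n_bins = 50L,
                  cimp_panel_size = 0L, epitoc_panel_size = 20L))
  expect_equal(sum(ann0$probes$in_cimp_panel), 0L)
})

test_that("identical seed and config give byte-identical cohorts", {
  cfg <- cohort_config(seed = 11, n_probes = 800L, n_genes = 150L,
                       n_bins = 100L, cimp_panel_size = 60L,
                       epitoc_panel_size = 20L,
                       n_responsive_genes_sensitive = 20L,
                       n_responsive_genes_less = 8L, myc_set_size = 5L,
                       n_baseline_diff_genes = 10L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$meth$bm$beta, b$meth$bm$beta)
  expect_identical(a$rna$cm$counts, b$rna$cm$counts)
  expect_identical(a$outcomes, b$outcomes)
})

test_that("generated values satisfy the basic range invariants", {
  co <- default_cohort()
  expect_true(all(co$meth$bm$beta >= 0 & co$meth$bm$beta <= 1))
  expect_true(all(co$rna$cm$counts >= 0))
  expect_true(all(co$rna$cm$counts == round(co$rna$cm$counts)))
  expect_true(all(co$outcomes$survival$time_days > 0))
  expect_true(all(co$outcomes$survival$event %in% c(0, 1)))
})

test_that("CIMP panel percentage tracks the configured methylation probability", {
  co <- default_cohort()
  bm <- apply_probe_qc(co$meth$bm, co$annotation)
  veh <- co$meth$samples$sample_id[co$meth$samples$arm == "vehicle"]
  cc <- cimp_percentage(bm, co$annotation, samples = veh)
  cc$model <- co$meth$samples$model[match(cc$sample_id,
                                          co$meth$samples$sample_id)]
  pct <- tapply(cc$cimp_percent, cc$model, mean)
  cfg_p <- 100 * co$config$cimp_probability
  # within a few points of the configured probability (binomial sampling at
  # panel size 1099 plus the beta-mixture tail crossing the 0.3 cutoff)
  expect_true(all(abs(pct[paste0("PDX", 1:5)] - cfg_p) < 3))
})

test_that("treatment spares the CIMP panel while hypomethylating globally", {
  co <- default_cohort()
  s <- co$meth$samples
  dm <- call_dm(co$meth$bm$beta[, s$sample_id[s$arm == "DAC"]],
                co$meth$bm$beta[, s$sample_id[s$arm == "vehicle"]])
  in_cimp <- dm$probe_id %in%
    co$annotation$probes$probe_id[co$annotation$probes$in_cimp_panel]
  affected <- dm$probe_id %in% co$meth$truth$affected_probes
  expect_lt(mean(abs(dm$delta_beta[in_cimp])),
            mean(abs(dm$delta_beta[affected])))
  # and the global shift is a decrease
  expect_lt(mean(dm$delta_beta[affected]), -0.1)
})

test_that("a null treatment effect yields only noise-level DM calls", {
  cfg <- cohort_config(seed = 5, n_probes = 2000L, n_genes = 200L,
                       n_bins = 200L, cimp_panel_size = 100L,
                       epitoc_panel_size = 50L, global_hypo_effect = 0,
                       n_responsive_genes_sensitive = 10L,
                       n_responsive_genes_less = 5L, myc_set_size = 2L,
                       n_baseline_diff_genes = 5L, min_capable_probes = 1L,
                       min_responsive_mean = 0)
  ann <- generate_probe_annotation(cfg)
  meth <- generate_beta_cohort(cfg, ann)
  s <- meth$samples
  dm <- call_dm(meth$bm$beta[, s$sample_id[s$arm == "DAC"]],
                meth$bm$beta[, s$sample_id[s$arm == "vehicle"]])
  expect_lt(mean(dm$is_dm), 0.01)
})

test_that("compartment tracks, survival and flow have the designed shape", {
  out <- default_cohort()$outcomes
  expect_length(out$tracks, 4L)
  expect_true(all(vapply(out$tracks, function(t) all(t$label %in% c("A", "B")),
                         logical(1))))
  # full concordance leaves no ambiguity
  cfg1 <- cohort_config(seed = 2, n_probes = 500L, n_genes = 100L,
                        n_bins = 60L, cimp_panel_size = 10L,
                        epitoc_panel_size = 10L, compartment_concordance = 1,
                        n_responsive_genes_sensitive = 5L,
                        n_responsive_genes_less = 2L, myc_set_size = 1L,
                        n_baseline_diff_genes = 2L, min_capable_probes = 1L,
                        min_responsive_mean = 0)
  out1 <- generate_compartments_and_outcomes(cfg1, generate_probe_annotation(cfg1))
  cons <- consensus_compartments(out1$tracks)
  expect_false(any(cons$label == "ambiguous"))
  expect_true(all(c("hcd45_count", "bead_count", "bead_volume_ul",
                    "cell_volume_ul", "bead_concentration_per_ul")
                  %in% names(out$flow)))
})

test_that("probes land in open chromatin at the configured 82% rate", {
  co <- default_cohort()
  ann <- co$annotation
  bin_label <- ann$bins$label[findInterval(ann$probes$start, ann$bins$start)]
  expect_equal(mean(bin_label == "A"), 0.82, tolerance = 0.025)
  gene_label <- ann$bins$label[findInterval(ann$genes$start, ann$bins$start)]
  expect_equal(mean(gene_label == "A"), 0.74, tolerance = 0.025)
})

test_that("equal hazards give a uniform log-rank p-value over replicates", {
  set.seed(7)
  ps <- replicate(200, {
    time <- rexp(10, rate = 1 / 30)
    logrank_test(time, rep(1, 10), rep(c("a", "b"), each = 5))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))  # chi-square p has ties
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort files round-trip through the plain-text writers", {
  co <- default_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  bm <- read_beta_matrix(file.path(dir, "beta.tsv"),
                         file.path(dir, "detection_p.tsv"))
  expect_equal(bm$beta, co$meth$bm$beta, tolerance = 1e-8)
  ann <- read_annotation(file.path(dir, "annotation.tsv"),
                         genes_path = file.path(dir, "genes.tsv"),
                         bins_path = file.path(dir, "bins_truth.tsv"))
  expect_equal(nrow(ann$probes), nrow(co$annotation$probes))
  expect_setequal(paste(ann$links$probe_id, ann$links$gene_id),
                  paste(co$annotation$links$probe_id, co$annotation$links$gene_id))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(sets, co$rna$gene_sets)
})
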