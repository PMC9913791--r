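# Probe QC, KNN imputation, CIMP percentage, EpiTOC age and delta-beta
# differential methylation.

test_that("detection-p masking is strict and blacklisted probes are dropped", {
  bm <- toy_beta(10, 3)
  ids <- rownames(bm$beta)
  bm$detection_p[2, 1] <- 0.06
  bm$detection_p[3, 2] <- 0.05   # exactly at the cutoff: retained
  ann <- toy_annotation(ids, blacklist = ids[9:10])
  out <- apply_probe_qc(bm, ann)
  expect_equal(nrow(out$beta), 8L)
  expect_true(is.na(out$beta[ids[2], 1]))
  expect_false(is.na(out$beta[ids[3], 2]))
  expect_equal(out$qc_log$n_probes_dropped, 2L)
  expect_equal(out$qc_log$n_entries_masked, 1L)
  expect_error(apply_probe_qc(bm, toy_annotation(paste0("other", 1:3))),
               "overlap")
})

test_that("QC is idempotent", {
  bm <- toy_beta(20, 5)
  bm$detection_p[sample(100, 8)] <- 0.5
  ids <- rownames(bm$beta)
  ann <- toy_annotation(ids, blacklist = ids[1:3])
  once <- apply_probe_qc(bm, ann)
  twice <- apply_probe_qc(once, ann)
  expect_identical(once$beta, twice$beta)
})

test_that("KNN imputation reproduces a hand-computed toy case", {
  # probe p1 is missing in sample s3; its two nearest complete neighbours
  # on samples s1/s2 are p2 (distance 0.02) and p3 (distance 0.04), whose
  # s3 values average to 0.3
  beta <- rbind(
    p1 = c(0.50, 0.50, NA),
    p2 = c(0.50, 0.52, 0.2),
    p3 = c(0.54, 0.50, 0.4),
    p4 = c(0.90, 0.90, 0.9),
    p5 = c(0.10, 0.10, 0.1)
  )
  colnames(beta) <- c("s1", "s2", "s3")
  out <- impute_missing_knn(beta_matrix(beta), k = 2)
  expect_equal(out$beta["p1", "s3"], 0.3)
  expect_false(anyNA(out$beta))
})

test_that("imputation is the identity without missing values and clips to [0,1]", {
  bm <- toy_beta(8, 4)
  expect_identical(impute_missing_knn(bm, k = 3), bm)
  beta <- bm$beta
  beta[1, ] <- c(NA, 1, 1, 1)
  out <- impute_missing_knn(beta_matrix(beta), k = 3)
  expect_true(all(out$beta >= 0 & out$beta <= 1))
  beta[2, ] <- NA_real_
  expect_error(impute_missing_knn(beta_matrix(beta), k = 3), "cg002")
})

test_that("CIMP percentage handles saturated and empty panels", {
  beta <- matrix(0.9, 5, 2, dimnames = list(paste0("c", 1:5), c("a", "b")))
  ann <- toy_annotation(paste0("c", 1:5), cimp = paste0("c", 1:5))
  cc <- cimp_percentage(beta_matrix(beta), ann)
  expect_equal(cc$cimp_percent, c(100, 100))
  expect_equal(cc$cimp_class, c("CIMP_plus", "CIMP_plus"))
  cc0 <- cimp_percentage(beta_matrix(beta * 0), ann)
  expect_equal(cc0$cimp_percent, c(0, 0))
  expect_equal(cc0$cimp_class, c("CIMP_minus", "CIMP_minus"))
  ann_empty <- toy_annotation(paste0("c", 1:5))
  expect_error(cimp_percentage(beta_matrix(beta), ann_empty), "empty")
})

test_that("CIMP classification is invariant to probe and sample order", {
  co <- default_cohort()
  bm <- apply_probe_qc(co$meth$bm, co$annotation)
  cc1 <- cimp_percentage(bm, co$annotation)
  perm <- beta_matrix(bm$beta[rev(seq_len(nrow(bm$beta))),
                              rev(seq_len(ncol(bm$beta)))],
                      bm$detection_p[rev(seq_len(nrow(bm$beta))),
                                     rev(seq_len(ncol(bm$beta)))])
  cc2 <- cimp_percentage(perm, co$annotation)
  cc2 <- cc2[match(cc1$sample_id, cc2$sample_id), ]
  expect_equal(cc1$cimp_percent, cc2$cimp_percent)
  expect_equal(cc1$cimp_class, cc2$cimp_class)
})

test_that("EpiTOC age is the panel mean and demands complete data", {
  beta <- matrix(c(0.2, 0.4, 0.6), 3, 2,
                 dimnames = list(paste0("e", 1:3), c("a", "b")))
  ann <- toy_annotation(paste0("e", 1:3), epitoc = paste0("e", 1:3))
  ea <- epitoc_age(beta_matrix(beta), ann)
  expect_equal(ea$epitoc_age, c(0.4, 0.4))
  ea0 <- epitoc_age(beta_matrix(beta * 0), ann)
  expect_equal(ea0$epitoc_age, c(0, 0))
  beta[1, 1] <- NA
  expect_error(epitoc_age(beta_matrix(beta), ann), "impute")
})

test_that("delta-beta calls follow the strict 0.2 rule with correct arithmetic", {
  treated <- matrix(c(0.30, 0.30), 1, 2, dimnames = list("p", c("t1", "t2")))
  vehicle <- matrix(c(0.60, 0.60), 1, 2, dimnames = list("p", c("v1", "v2")))
  dm <- call_dm(treated, vehicle)
  expect_equal(dm$delta_beta, -0.3)
  expect_true(dm$is_dm)
  expect_equal(dm$direction, "hypo")
})

test_that("delta beta is antisymmetric under arm swap and skips empty probes", {
  co <- default_cohort()
  s <- co$meth$samples
  sub <- s$sample_id[s$model == "PDX1"]
  tb <- co$meth$bm$beta[1:500, sub[s$arm[match(sub, s$sample_id)] == "DAC"]]
  vb <- co$meth$bm$beta[1:500, sub[s$arm[match(sub, s$sample_id)] == "vehicle"]]
  fwd <- call_dm(tb, vb)
  rev <- call_dm(vb, tb)
  expect_equal(fwd$delta_beta, -rev$delta_beta)
  tb2 <- tb; tb2[3, ] <- NA
  dm <- call_dm(tb2, vb)
  expect_equal(attr(dm, "excluded"), rownames(tb)[3])
  expect_false(rownames(tb)[3] %in% dm$probe_id)
})

test_that("age-CIMP correlation handles collinear and degenerate inputs", {
  expect_equal(correlate_age_vs_cimp(c(0.1, 0.2, 0.3), c(10, 20, 30)), 1)
  expect_equal(correlate_age_vs_cimp(c(0.1, 0.2, 0.3), c(30, 20, 10)), -1)
  expect_warning(r <- correlate_age_vs_cimp(c(0.2, 0.2, 0.2), c(10, 20, 30)),
                 "variance")
  expect_true(is.na(r))
  expect_error(correlate_age_vs_cimp(c(0.1, 0.2), c(1, 2)), "3 pairs")
})

test_that("the generator couples EpiTOC age to CIMP percentage positively", {
  p <- default_pipeline()$results
  expect_gt(p$r_age_cimp, 0)
})
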