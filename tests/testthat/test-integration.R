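# Gene-level integration of DM probes with DE genes and cross-model
# concordance.

toy_dm <- function(ids, delta) {
  data.frame(probe_id = ids, delta_beta = delta,
             is_dm = abs(delta) > 0.2,
             direction = ifelse(delta < 0, "hypo", "hyper"),
             stringsAsFactors = FALSE)
}

toy_links_ann <- function(links) {
  ids <- unique(links$probe_id)
  toy_annotation(ids, links = links)
}

test_that("per-gene DM summaries count probes by region and direction", {
  links <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    gene_id = c("NOSIP", "NOSIP", "NOSIP", "NOSIP", "OTHER"),
    region_class = c("gene_body", "promoter", "promoter", "promoter",
                     "enhancer"),
    stringsAsFactors = FALSE
  )
  dm <- toy_dm(c("p1", "p2", "p3", "p4", "p5"),
               c(-0.3, -0.25, -0.4, -0.5, 0.1))
  gm <- summarize_gene_methylation(dm, toy_links_ann(links))
  row <- gm[gm$gene_id == "NOSIP", ]
  expect_equal(row$n_gene_body, 1L)
  expect_equal(row$n_promoter, 3L)
  expect_equal(row$n_hypo, 4L)
  expect_equal(row$net_direction, "hypo")
  expect_false("OTHER" %in% gm$gene_id)  # its probe is not DM
})

test_that("mixed directions and unannotated probes are handled", {
  links <- data.frame(probe_id = c("p1", "p2"), gene_id = c("G", "G"),
                      region_class = c("promoter", "gene_body"),
                      stringsAsFactors = FALSE)
  dm <- toy_dm(c("p1", "p2", "p9"), c(-0.3, 0.3, -0.5))
  gm <- summarize_gene_methylation(dm, toy_links_ann(links))
  expect_equal(gm$net_direction, "mixed")
  expect_equal(attr(gm, "unannotated"), "p9")
  none <- summarize_gene_methylation(toy_dm("p1", 0.05), toy_links_ann(links))
  expect_equal(nrow(none), 0L)
})

test_that("a probe linked to two genes contributes to both", {
  links <- data.frame(probe_id = c("p1", "p1"), gene_id = c("G1", "G2"),
                      region_class = c("promoter", "enhancer"),
                      stringsAsFactors = FALSE)
  gm <- summarize_gene_methylation(toy_dm("p1", -0.4), toy_links_ann(links))
  expect_setequal(gm$gene_id, c("G1", "G2"))
})

test_that("integration rows count joint sets correctly", {
  gm <- data.frame(gene_id = paste0("G", 1:5), n_gene_body = 1L,
                   n_promoter = 0L, n_enhancer = 0L, n_hypo = 1L,
                   n_hyper = 0L, net_direction = "hypo",
                   stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("G1", "G2", "G9"),
                   log2fc = c(1, 2, 1.5), p = c(0.001, 0.002, 0.001),
                   padj = c(0.01, 0.02, 0.01),
                   is_de = c(TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  row <- build_integration_table(gm, de, model = "toy")
  expect_equal(row$n_hypo_genes, 5L)
  expect_equal(row$n_up_genes, 3L)
  expect_equal(row$n_hypo_and_up, 2L)
  expect_lte(row$n_hypo_and_up, min(row$n_hypo_genes, row$n_up_genes))
  # no DE genes: joint counts zero, methylation counts unchanged
  de0 <- de[0, ]
  row0 <- build_integration_table(gm, de0, model = "toy")
  expect_equal(row0$n_hypo_and_up, 0L)
  expect_equal(row0$n_hypo_genes, 5L)
  # raw-p joining admits the gene the padj rule rejects
  de2 <- de
  de2$padj <- c(0.2, 0.2, 0.2)
  expect_equal(build_integration_table(gm, de2, model = "t")$n_hypo_and_up, 0L)
  expect_equal(build_integration_table(gm, de2, model = "t",
                                       de_rule = "raw")$n_hypo_and_up, 2L)
})

test_that("cross-model concordance counts membership correctly", {
  sets <- list(m1 = c("A", "B", "C"), m2 = c("B", "C"), m3 = c("B", "C", "D"))
  expect_equal(cross_model_concordance(sets, 3), c("B", "C"))
  expect_equal(cross_model_concordance(sets, 2), c("B", "C"))
  expect_equal(cross_model_concordance(sets["m1"], 1), c("A", "B", "C"))
  expect_error(cross_model_concordance(sets, 4), "exceeds")
  # monotone in k
  for (k in 2:3) {
    expect_true(all(cross_model_concordance(sets, k) %in%
                      cross_model_concordance(sets, k - 1)))
  }
})

test_that("joint counts are invariant to model and gene order", {
  sets <- list(m1 = c("C", "A", "B"), m2 = c("C", "B"), m3 = c("D", "B", "C"))
  expect_equal(cross_model_concordance(sets, 2),
               cross_model_concordance(rev(sets), 2))
})

test_that("truth-responsive common genes are recovered across all models", {
  p <- default_pipeline()$results
  tg <- p$cohort$rna$truth$genes
  cc <- p$integration$concordance
  n <- length(p$de$model)
  for (side in c("up", "down")) {
    truth <- tg$gene_id[tg$responsive_in == "all" &
                          (if (side == "up") tg$lfc > 0 else tg$lfc < 0)]
    found <- cc$gene_id[cc$direction == paste0("hypo_", side) & cc$k == n]
    expect_gte(length(intersect(found, truth)) / length(truth), 0.8)
  }
})
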