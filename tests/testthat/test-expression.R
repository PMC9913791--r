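# Size factors, the NB Wald test, BH adjustment and the sensitivity
# signature.

nb_toy <- function(n_genes, sf = rep(1, 8), mu = NULL, lfc = NULL,
                   size = 20, seed = 1, n_per_group = 4) {
  set.seed(seed)
  n <- 2 * n_per_group
  mu <- mu %||% rlnorm(n_genes, 5, 1.2)
  m <- matrix(rep(mu, n), n_genes, n)
  if (!is.null(lfc)) {
    m[, (n_per_group + 1):n] <- m[, (n_per_group + 1):n] * 2^lfc
  }
  m <- sweep(m, 2, sf, "*")
  counts <- matrix(rnbinom(length(m), mu = m, size = size), n_genes, n,
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                   sprintf("s%d", seq_len(n))))
  counts
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("size factors are symmetric, scale-equivariant and recover truth", {
  counts <- nb_toy(300, seed = 2)
  a <- counts[, 1:4]
  two <- cbind(a[, 1, drop = FALSE], a[, 1, drop = FALSE])
  colnames(two) <- c("x", "y")
  expect_equal(unname(normalize_size_factors(two)), c(1, 1))
  dbl <- cbind(a[, 1, drop = FALSE], 2 * a[, 1, drop = FALSE])
  colnames(dbl) <- c("x", "y")
  sf <- normalize_size_factors(dbl)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # known library sizes 0.5x / 1x / 2x
  truth <- c(0.5, 1, 2, 1, 0.5, 1, 2, 1)
  counts <- nb_toy(2000, sf = truth, seed = 3)
  sf <- normalize_size_factors(counts)
  sf <- sf / exp(mean(log(sf)))
  truth_c <- truth / exp(mean(log(truth)))
  expect_true(all(abs(sf / truth_c - 1) < 0.05))
  zero <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(normalize_size_factors(zero), "pseudo-reference")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("the NB Wald test recovers a doubled gene and flat genes", {
  lfc <- numeric(500); lfc[1:20] <- 1
  counts <- nb_toy(500, lfc = lfc, size = 100, seed = 4)
  d <- de_test(counts, rep(c("v", "t"), each = 4), ref = "v")
  est <- d$log2fc[match(sprintf("g%04d", 1:20), d$gene_id)]
  expect_true(all(abs(est - 1) < 0.3))
  flat <- matrix(7L, 3, 8, dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:8)))
  dflat <- de_test(flat, rep(c("v", "t"), each = 4), ref = "v")
  expect_equal(dflat$log2fc, rep(0, 3))
  expect_true(all(dflat$p > 0.9))
})

test_that("de_test is label-symmetric and excludes all-zero genes", {
  counts <- nb_toy(200, seed = 5)
  counts[7, ] <- 0L
  g <- rep(c("v", "t"), each = 4)
  a <- de_test(counts, g, ref = "v")
  b <- de_test(counts, g, ref = "t")
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
  expect_equal(attr(a, "excluded"), "g0007")
  expect_false("g0007" %in% a$gene_id)
  expect_error(de_test(counts[, 1:3], c("v", "v", "t")), "2 samples")
})

test_that("DE gene sets are nested in the adjusted-p threshold", {
  lfc <- numeric(400); lfc[1:40] <- rep(c(1, -1), 20)
  counts <- nb_toy(400, lfc = lfc, seed = 6)
  d <- de_test(counts, rep(c("v", "t"), each = 4), ref = "v")
  s05 <- d$gene_id[d$padj < 0.05]
  s10 <- d$gene_id[d$padj < 0.10]
  expect_true(all(s05 %in% s10))
})

test_that("power rises monotonically with effect size", {
  power_at <- function(effect) {
    lfc <- numeric(800); lfc[1:80] <- effect
    counts <- nb_toy(800, lfc = lfc, seed = 7)
    d <- de_test(counts, rep(c("v", "t"), each = 4), ref = "v")
    mean(d$is_de[match(sprintf("g%04d", 1:80), d$gene_id)])
  }
  pw <- vapply(c(0.5, 1, 2), power_at, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("the signature filter, ranking and truncation behave as specified", {
  de <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    log2fc = c(rep(2, 100), rep(0.5, 100)),
    padj = c(seq(1e-6, 0.049, length.out = 100), rep(0.2, 100)),
    stringsAsFactors = FALSE
  )
  sig <- derive_signature(de)
  expect_equal(nrow(sig), 70L)
  expect_equal(sig$gene_id, sprintf("g%03d", 1:70))
  expect_true(all(sig$side == "up_in_sensitive"))
  # fewer passing genes than the cap: all returned
  sig12 <- derive_signature(de[c(1:12, 150:200), ])
  expect_equal(nrow(sig12), 12L)
  # padj ties break by larger |log2fc|
  tie <- data.frame(gene_id = c("a", "b"), log2fc = c(1.5, -3),
                    padj = c(0.01, 0.01), stringsAsFactors = FALSE)
  expect_equal(derive_signature(tie)$gene_id, c("b", "a"))
  none <- data.frame(gene_id = "a", log2fc = 0.2, padj = 0.9,
                     stringsAsFactors = FALSE)
  expect_warning(empty <- derive_signature(none), "no gene")
  expect_equal(nrow(empty), 0L)
})

test_that("the pipeline signature comes from baseline subgroup differences", {
  p <- default_pipeline()$results
  tg <- p$cohort$rna$truth$genes
  truth_base <- tg$gene_id[tg$baseline_lfc != 0]
  expect_equal(nrow(p$signature), 70L)
  expect_gt(mean(p$signature$gene_id %in% truth_base), 0.9)
})
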