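# Independent brute-force oracle for the GSEA running-sum enrichment
# score: explicit per-position loop, no shared code with the package path.

es_oracle <- function(scores, set, weight = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% set
  w <- abs(s)^weight
  sumw <- sum(w[hit])
  if (sumw == 0) { w[] <- 1; sumw <- sum(hit) }
  nm <- sum(!hit)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) w[i] / sumw else -1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
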