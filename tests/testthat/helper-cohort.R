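# Shared fixtures, generated in code. The default cohort and the full
# pipeline run are expensive enough to build once and reuse across files.

TEST_SEED <- 101L

cached <- local({
  store <- new.env(parent = emptyenv())
  function(key, build) {
    if (is.null(store[[key]])) store[[key]] <- build()
    store[[key]]
  }
})

default_cohort <- function() {
  cached("cohort", function() generate_cohort(cohort_config(seed = TEST_SEED)))
}

default_pipeline <- function() {
  cached("pipeline", function() {
    dir <- file.path(tempdir(), "dacpdx_pipeline_fixture")
    suppressMessages(suppressWarnings(
      run_pipeline(default_run_config(seed = TEST_SEED), outdir = dir)
    ))
  })
}

# small deterministic beta matrix for unit tests
toy_beta <- function(nr = 6, nc = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(round(runif(nr * nc), 3), nr, nc,
              dimnames = list(sprintf("cg%03d", seq_len(nr)),
                              sprintf("s%d", seq_len(nc))))
  beta_matrix(m)
}

toy_annotation <- function(probe_ids, cimp = character(), epitoc = character(),
                           blacklist = character(), links = NULL) {
  probes <- data.frame(
    probe_id = probe_ids, chrom = "chrT",
    start = seq(0, by = 100, length.out = length(probe_ids)),
    end = seq(0, by = 100, length.out = length(probe_ids)) + 2,
    in_cimp_panel = probe_ids %in% cimp,
    in_epitoc_panel = probe_ids %in% epitoc,
    blacklist_reason = ifelse(probe_ids %in% blacklist, "multimapping", "none"),
    stringsAsFactors = FALSE
  )
  if (is.null(links)) {
    links <- data.frame(probe_id = character(), gene_id = character(),
                        region_class = character(), stringsAsFactors = FALSE)
  }
  probe_annotation(probes, links)
}
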