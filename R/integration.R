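# Gene-level integration of differential methylation with differential
# expression: per-gene DM probe summaries, per-model/per-subgroup joint
# count tables, and cross-model concordant gene sets.

#' Summarize differentially methylated probes per gene
#'
#' Joins DM probes onto the probe-to-gene link table. A gene is counted as
#' hypomethylated as soon as one hypo DM probe links to it (and likewise
#' hypermethylated); a probe linked to several genes contributes to each.
#' Region classes (gene body / promoter / enhancer) are tallied separately.
#' DM probes absent from the annotation are skipped and listed in
#' `attr(, "unannotated")`.
#'
#' @param dm a [call_dm()] result.
#' @param ann a [probe_annotation()].
#' @return data.frame with one row per gene having at least one DM probe:
#'   `gene_id`, region counts `n_gene_body`, `n_promoter`, `n_enhancer`,
#'   direction counts `n_hypo`, `n_hyper`, and `net_direction`
#'   (`"hypo"`, `"hyper"` or `"mixed"` when both signs are present).
#' @export
summarize_gene_methylation <- function(dm, ann) {
  stopifnot(inherits(ann, "probe_annotation"))
  dm_probes <- dm[dm$is_dm, c("probe_id", "direction"), drop = FALSE]
  unannotated <- setdiff(dm_probes$probe_id, ann$links$probe_id)
  hit <- merge(dm_probes, ann$links, by = "probe_id")
  if (nrow(hit) == 0L) {
    out <- data.frame(gene_id = character(), n_gene_body = integer(),
                      n_promoter = integer(), n_enhancer = integer(),
                      n_hypo = integer(), n_hyper = integer(),
                      net_direction = character(), stringsAsFactors = FALSE)
    attr(out, "unannotated") <- unannotated
    return(out)
  }
  cnt <- function(flag) {
    tapply(flag, hit$gene_id, sum)
  }
  g <- sort(unique(hit$gene_id))
  out <- data.frame(
    gene_id = g,
    n_gene_body = as.integer(cnt(hit$region_class == "gene_body")[g]),
    n_promoter = as.integer(cnt(hit$region_class == "promoter")[g]),
    n_enhancer = as.integer(cnt(hit$region_class == "enhancer")[g]),
    n_hypo = as.integer(cnt(hit$direction == "hypo")[g]),
    n_hyper = as.integer(cnt(hit$direction == "hyper")[g]),
    stringsAsFactors = FALSE
  )
  out$net_direction <- ifelse(out$n_hypo > 0 & out$n_hyper > 0, "mixed",
                              ifelse(out$n_hypo > 0, "hypo", "hyper"))
  rownames(out) <- NULL
  attr(out, "unannotated") <- unannotated
  out
}

#' Build one row of the methylation-by-expression integration table
#'
#' Counts, for one model (or subgroup), differentially methylated genes and
#' probes by direction, differentially expressed genes by direction, and
#' the joint hypomethylated-and-up / hypomethylated-and-down gene counts.
#' Genes absent from the expression results stay in the methylation-only
#' counts but are excluded from the joint counts.
#'
#' @param gm a [summarize_gene_methylation()] result.
#' @param de a [de_test()] result (treated over vehicle).
#' @param dm the [call_dm()] result behind `gm`, used for unique DM-probe
#'   counts; pass `NULL` to report `NA` probe counts.
#' @param model label for the row.
#' @param de_rule `"padj"` (default: adjusted p < `de_alpha`) or `"raw"`
#'   (raw p < `de_alpha`) to define differentially expressed genes.
#' @param de_alpha significance cutoff (default 0.05).
#' @return one-row data.frame with the count columns described above.
#' @export
build_integration_table <- function(gm, de, dm = NULL, model = "model",
                                    de_rule = c("padj", "raw"),
                                    de_alpha = 0.05) {
  de_rule <- match.arg(de_rule)
  pvals <- if (de_rule == "padj") de$padj else de$p
  de_genes_up <- de$gene_id[pvals < de_alpha & de$log2fc > 0]
  de_genes_down <- de$gene_id[pvals < de_alpha & de$log2fc < 0]
  hypo_genes <- gm$gene_id[gm$n_hypo > 0]
  hyper_genes <- gm$gene_id[gm$n_hyper > 0]
  measured <- de$gene_id

  data.frame(
    model = model,
    n_hypo_genes = length(hypo_genes),
    n_hyper_genes = length(hyper_genes),
    n_dm_cpgs_hypo = if (is.null(dm)) NA_integer_ else
      sum(dm$is_dm & dm$direction == "hypo"),
    n_dm_cpgs_hyper = if (is.null(dm)) NA_integer_ else
      sum(dm$is_dm & dm$direction == "hyper"),
    n_up_genes = length(de_genes_up),
    n_down_genes = length(de_genes_down),
    n_hypo_and_up = length(intersect(intersect(hypo_genes, measured), de_genes_up)),
    n_hypo_and_down = length(intersect(intersect(hypo_genes, measured), de_genes_down)),
    stringsAsFactors = FALSE
  )
}

#' Genes concordant across models
#'
#' Given one gene set per model (e.g. hypomethylated-and-upregulated genes),
#' returns the genes present in at least `k` models. `k = n` gives the
#' "in all models" set, `k = n - 1` the "in three out of four" analogue.
#'
#' @param sets_by_model named list of character vectors, one per model.
#' @param k minimum number of models a gene must appear in.
#' @return sorted character vector of concordant genes.
#' @export
cross_model_concordance <- function(sets_by_model, k) {
  if (length(sets_by_model) < 2L && k > 1L) {
    stop_input("need at least 2 model sets")
  }
  if (!is_count(k) || k < 1L) stop_input("`k` must be a positive count")
  if (k > length(sets_by_model)) {
    stop_input("`k` exceeds the number of models (", length(sets_by_model), ")")
  }
  tab <- table(unlist(lapply(sets_by_model, unique)))
  sort(names(tab)[tab >= k])
}
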