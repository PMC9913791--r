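# Readers and writers for the package's plain-text interchange formats:
# beta/detection-p TSVs, annotation TSV (gene links collapsed), counts TSV,
# sample sheets, BED-like compartment tracks, survival/flow CSVs and GMT
# gene-set collections.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_matrix_tsv <- function(mat, path, id_col) {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Read a beta matrix (and detection p-values) from TSV
#'
#' @param beta_path TSV with a probe-id first column and one column per
#'   sample; empty / `NA` cells are missing values.
#' @param detection_p_path optional TSV of identical shape with detection
#'   p-values.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(beta_path, detection_p_path = NULL) {
  beta <- read_matrix_tsv(beta_path)
  detp <- if (!is.null(detection_p_path)) read_matrix_tsv(detection_p_path)
  beta_matrix(beta, detp)
}

#' Write a beta matrix (and detection p-values) as TSV
#'
#' @param bm a [beta_matrix()].
#' @param beta_path,detection_p_path output paths; detection p-values are
#'   skipped when `detection_p_path` is `NULL`.
#' @export
write_beta_matrix <- function(bm, beta_path, detection_p_path = NULL) {
  write_matrix_tsv(bm$beta, beta_path, "probe_id")
  if (!is.null(detection_p_path)) {
    write_matrix_tsv(bm$detection_p, detection_p_path, "probe_id")
  }
  invisible(beta_path)
}

#' Write a probe annotation as TSV files
#'
#' The probe manifest is written with BED-style 0-based half-open
#' coordinates and the gene links collapsed into a `gene_links` column of
#' `gene:region` pairs separated by `;`. Gene and bin tables, when present,
#' go to sibling files.
#'
#' @param ann a [probe_annotation()].
#' @param path output TSV path for the probe manifest.
#' @param genes_path,bins_path optional paths for the gene / bin tables.
#' @export
write_annotation <- function(ann, path, genes_path = NULL, bins_path = NULL) {
  stopifnot(inherits(ann, "probe_annotation"))
  collapsed <- stats::aggregate(
    link ~ probe_id,
    data = data.frame(probe_id = ann$links$probe_id,
                      link = paste0(ann$links$gene_id, ":",
                                    ann$links$region_class),
                      stringsAsFactors = FALSE),
    FUN = paste, collapse = ";")
  df <- ann$probes
  df$gene_links <- collapsed$link[match(df$probe_id, collapsed$probe_id)]
  df$gene_links[is.na(df$gene_links)] <- ""
  write_tsv(df, path)
  if (!is.null(genes_path) && !is.null(ann$genes)) write_tsv(ann$genes, genes_path)
  if (!is.null(bins_path) && !is.null(ann$bins)) write_tsv(ann$bins, bins_path)
  invisible(path)
}

#' Read a probe annotation from TSV files
#'
#' @param path probe manifest TSV written by [write_annotation()].
#' @param genes_path,bins_path optional gene / bin table TSVs.
#' @return a [probe_annotation()].
#' @export
read_annotation <- function(path, genes_path = NULL, bins_path = NULL) {
  df <- read_tsv(path)
  has_link <- !is.na(df$gene_links) & nzchar(df$gene_links)
  parts <- strsplit(df$gene_links[has_link], ";", fixed = TRUE)
  n <- lengths(parts)
  pairs <- strsplit(unlist(parts), ":", fixed = TRUE)
  links <- data.frame(
    probe_id = rep(df$probe_id[has_link], n),
    gene_id = vapply(pairs, `[`, "", 1),
    region_class = vapply(pairs, `[`, "", 2),
    stringsAsFactors = FALSE
  )
  df$gene_links <- NULL
  probe_annotation(
    df, links,
    genes = if (!is.null(genes_path)) read_tsv(genes_path),
    bins = if (!is.null(bins_path)) read_tsv(bins_path)
  )
}

#' Read a count matrix and sample sheet
#'
#' @param counts_path TSV with a gene-id first column and one column per
#'   sample.
#' @param samples_path sample sheet (TSV/CSV by extension) with at least a
#'   `sample_id` column.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  counts <- read_matrix_tsv(counts_path)
  storage.mode(counts) <- "integer"
  samples <- if (grepl("\\.csv$", samples_path)) {
    utils::read.csv(samples_path, stringsAsFactors = FALSE)
  } else read_tsv(samples_path)
  count_matrix(counts, samples)
}

#' Read / write GMT gene-set collections
#'
#' GMT is one set per line: name, description, then member genes, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Rebuilds the in-memory cohort list (annotation, beta matrix, counts,
#' tracks, outcome tables, gene sets) from the standard file names.
#'
#' @param dir cohort directory.
#' @return a list shaped like the [generate_cohort()] result (without the
#'   `config` element; truth tables are loaded when present).
#' @export
read_cohort_dir <- function(dir) {
  p <- function(...) file.path(dir, ...)
  ann <- read_annotation(p("annotation.tsv"), genes_path = p("genes.tsv"),
                         bins_path = p("bins_truth.tsv"))
  samples <- read_tsv(p("samples.tsv"))
  bm <- read_beta_matrix(p("beta.tsv"), p("detection_p.tsv"))
  cm <- read_count_matrix(p("counts.tsv"), p("samples.tsv"))
  track_files <- sort(list.files(dir, pattern = "^compartments_.*\\.tsv$",
                                 full.names = TRUE))
  tracks <- lapply(track_files, read_tsv)
  names(tracks) <- sub("^compartments_(.*)\\.tsv$", "\\1",
                       basename(track_files))
  truth <- NULL
  if (file.exists(p("truth_affected_probes.tsv"))) {
    truth <- list(
      affected_probes = read_tsv(p("truth_affected_probes.tsv"))$probe_id,
      genes = read_tsv(p("truth_responsive_genes.tsv"))
    )
  }
  list(
    config = NULL,
    annotation = ann,
    meth = list(bm = bm, samples = samples, truth = truth),
    rna = list(cm = cm, truth = truth,
               gene_sets = read_gmt(p("gene_sets.gmt"))),
    outcomes = list(tracks = tracks,
                    survival = utils::read.csv(p("survival.csv"),
                                               stringsAsFactors = FALSE),
                    flow = utils::read.csv(p("flow.csv"),
                                           stringsAsFactors = FALSE),
                    truth = NULL)
  )
}

#' Write a full synthetic cohort to a directory
#'
#' Writes every table of a [generate_cohort()] result under standard file
#' names: beta/detection-p/counts matrices, annotation with genes and true
#' bin labels, sample sheets, per-sample compartment tracks, survival and
#' flow CSVs, the stand-in gene-set collection (GMT) and the truth tables.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_beta_matrix(cohort$meth$bm, p("beta.tsv"), p("detection_p.tsv"))
  write_tsv(cohort$meth$samples, p("samples.tsv"))
  write_annotation(cohort$annotation, p("annotation.tsv"),
                   genes_path = p("genes.tsv"),
                   bins_path = p("bins_truth.tsv"))
  write_matrix_tsv(cohort$rna$cm$counts, p("counts.tsv"), "gene_id")
  for (i in seq_along(cohort$outcomes$tracks)) {
    write_tsv(cohort$outcomes$tracks[[i]],
              p(sprintf("compartments_%s.tsv", names(cohort$outcomes$tracks)[i])))
  }
  utils::write.csv(cohort$outcomes$survival, p("survival.csv"), row.names = FALSE)
  utils::write.csv(cohort$outcomes$flow, p("flow.csv"), row.names = FALSE)
  write_gmt(cohort$rna$gene_sets, p("gene_sets.gmt"))
  write_tsv(data.frame(probe_id = cohort$meth$truth$affected_probes,
                       stringsAsFactors = FALSE),
            p("truth_affected_probes.tsv"))
  write_tsv(cohort$rna$truth$genes, p("truth_responsive_genes.tsv"))
  invisible(dir)
}
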