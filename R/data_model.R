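#' Probe-level AEU dataset
#'
#' Bundles the three tables the pipeline consumes: a normalized log2
#' probe-by-sample expression matrix, a probe annotation mapping each probe
#' to its probe-set (exon-level unit) and gene with a genomic-order index,
#' and a two-group sample design.  The constructor cross-validates the three
#' and reorders probes by gene and genomic index so downstream per-gene
#' operations can slice contiguous row blocks.
#'
#' @param expr numeric matrix, probes x samples, log2 scale, with rownames
#'   (probe ids) and colnames (sample ids).
#' @param annotation data.frame with columns `probe_id`, `gene_id`,
#'   `probeset_id`, `genomic_index` (rank of the probe within its gene in
#'   genomic order); optional `chrom`, `start`, `end`, `strand`.
#' @param design data.frame with columns `sample_id` and `group`
#'   (`"A"`/`"B"`), one row per sample; both groups must be non-empty and
#'   have at least two samples.
#' @return An object of class `aeu_dataset`: a list with elements `expr`,
#'   `annotation`, `design` and `groups` (named character vector
#'   sample -> group).
#' @export
aeu_dataset <- function(expr, annotation, design) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    igems_validation_error("igems_bad_expression",
      "expression matrix needs probe rownames and sample colnames")
  if (anyNA(expr) || any(!is.finite(expr)))
    igems_validation_error("igems_non_numeric",
      "expression matrix contains missing or non-finite values")
  if (anyDuplicated(rownames(expr)))
    igems_validation_error("igems_duplicate_probe",
      "duplicated probe_id in expression matrix")

  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req <- c("sample_id", "group")
  if (!all(req %in% names(design)))
    igems_validation_error("igems_bad_design",
      "design needs columns sample_id and group")
  if (anyDuplicated(design$sample_id))
    igems_validation_error("igems_duplicate_sample",
      sprintf("duplicated sample_id in design: %s",
              paste(unique(design$sample_id[duplicated(design$sample_id)]),
                    collapse = ", ")))
  if (!all(design$group %in% c("A", "B")))
    igems_validation_error("igems_bad_group",
      "design group labels must be 'A' or 'B'")
  unassigned <- setdiff(colnames(expr), design$sample_id)
  if (length(unassigned) > 0)
    igems_validation_error("igems_unassigned_sample",
      sprintf("unassigned sample(s) in expression but not in design: %s",
              paste(unassigned, collapse = ", ")))
  unknown <- setdiff(design$sample_id, colnames(expr))
  if (length(unknown) > 0)
    igems_validation_error("igems_unknown_sample",
      sprintf("design sample(s) absent from expression: %s",
              paste(unknown, collapse = ", ")))
  tab <- table(design$group)
  if (length(tab) < 2 || any(tab < 2))
    igems_validation_error("igems_small_group",
      "each of groups A and B needs at least two samples")

  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  reqa <- c("probe_id", "gene_id", "probeset_id", "genomic_index")
  if (!all(reqa %in% names(annotation)))
    igems_validation_error("igems_bad_annotation",
      sprintf("annotation needs columns %s", paste(reqa, collapse = ", ")))
  if (anyDuplicated(annotation$probe_id))
    igems_validation_error("igems_duplicate_annotation",
      sprintf("duplicated probe_id in annotation: %s",
              paste(unique(annotation$probe_id[duplicated(annotation$probe_id)]),
                    collapse = ", ")))

  # Probes missing from either table are dropped (with a logged count);
  # mismatch is expected when annotation covers more of the array design.
  common <- intersect(rownames(expr), annotation$probe_id)
  n_expr_only <- nrow(expr) - length(common)
  n_annot_only <- nrow(annotation) - length(common)
  if (n_expr_only > 0)
    igems_log("dropped %d probe(s) present in expression but not annotated",
              n_expr_only)
  if (n_annot_only > 0)
    igems_log("excluded %d annotated probe(s) absent from expression",
              n_annot_only)
  if (length(common) == 0)
    igems_validation_error("igems_no_probes",
      "no probe is shared between expression and annotation")

  annotation <- annotation[match(common, annotation$probe_id), , drop = FALSE]
  expr <- expr[common, design$sample_id, drop = FALSE]

  # Order by gene then genomic index.  Indices must be unique within a
  # gene (they define the genomic order); they are then re-ranked to 1..n
  # so that probes dropped at the intersection step leave no gaps.
  ord <- order(annotation$gene_id, annotation$genomic_index)
  annotation <- annotation[ord, , drop = FALSE]
  expr <- expr[ord, , drop = FALSE]
  rownames(annotation) <- NULL
  bad <- vapply(split(annotation$genomic_index, annotation$gene_id),
                anyDuplicated, integer(1)) > 0
  if (any(bad))
    igems_validation_error("igems_bad_genomic_index",
      sprintf("duplicated genomic_index within gene(s): %s",
              paste(names(bad)[bad], collapse = ", ")))
  annotation$genomic_index <- as.integer(
    stats::ave(annotation$genomic_index, annotation$gene_id, FUN = seq_along))

  groups <- stats::setNames(design$group, design$sample_id)
  structure(list(expr = expr, annotation = annotation,
                 design = design, groups = groups),
            class = "aeu_dataset")
}

#' @export
print.aeu_dataset <- function(x, ...) {
  cat(sprintf(
    "aeu_dataset: %d probes, %d probe-sets, %d genes, %d samples (A=%d, B=%d)\n",
    nrow(x$expr), length(unique(x$annotation$probeset_id)),
    length(unique(x$annotation$gene_id)), ncol(x$expr),
    sum(x$groups == "A"), sum(x$groups == "B")))
  invisible(x)
}

#' Read an expression/annotation/design triplet from TSV files
#'
#' Expression: header `probe_id<TAB>sample...`, one row per probe, log2
#' values.  Annotation: `probe_id, gene_id, probeset_id, genomic_index`
#' (plus optional coordinate columns).  Design: `sample_id, group`.
#'
#' @param expr_path,annot_path,design_path paths to the three TSV files.
#' @return A validated [aeu_dataset].
#' @export
load_dataset <- function(expr_path, annot_path, design_path) {
  for (p in c(expr_path, annot_path, design_path))
    if (!file.exists(p))
      igems_validation_error("igems_missing_file",
                             sprintf("input file not found: %s", p))
  expr_df <- utils::read.delim(expr_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  if (names(expr_df)[1] != "probe_id")
    igems_validation_error("igems_bad_expression",
      "expression file must start with a probe_id column")
  vals <- expr_df[, -1, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1))))
    igems_validation_error("igems_non_numeric",
      "non-numeric value in expression table")
  expr <- as.matrix(vals)
  rownames(expr) <- expr_df$probe_id
  annotation <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  aeu_dataset(expr, annotation, design)
}

#' Write a dataset back to the three-TSV on-disk layout
#'
#' @param dataset an [aeu_dataset].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (`expr`, `annot`, `design`).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "aeu_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(expr = file.path(dir, "expr.tsv"),
                annot = file.path(dir, "annot.tsv"),
                design = file.path(dir, "design.tsv"))
  expr_df <- data.frame(probe_id = rownames(dataset$expr),
                        dataset$expr, check.names = FALSE,
                        stringsAsFactors = FALSE)
  utils::write.table(expr_df, paths$expr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$annotation, paths$annot, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$design, paths$design, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Remove probe-sets with too few probes
#'
#' Probe-sets interrogated by fewer than `min_probes` probes are dropped
#' before model fitting, as such probe-sets do not measure exon expression
#' reliably.  Genomic indices are re-ranked so each surviving gene again
#' carries a contiguous 1..n ordering; genes left without any probe-set are
#' removed (and logged).
#'
#' @param dataset an [aeu_dataset].
#' @param min_probes minimum number of probes a probe-set must retain
#'   (default 3).
#' @return The filtered [aeu_dataset].
#' @export
filter_min_probes <- function(dataset, min_probes = 3) {
  stopifnot(inherits(dataset, "aeu_dataset"))
  if (!is.numeric(min_probes) || min_probes < 1)
    igems_validation_error("igems_bad_parameter", "min_probes must be >= 1")
  ann <- dataset$annotation
  sizes <- table(ann$probeset_id)
  keep_ps <- names(sizes)[sizes >= min_probes]
  keep <- ann$probeset_id %in% keep_ps
  lost_genes <- setdiff(unique(ann$gene_id), unique(ann$gene_id[keep]))
  if (length(lost_genes) > 0)
    igems_log("removed %d gene(s) left without probe-sets of >= %d probes",
              length(lost_genes), min_probes)
  ann <- ann[keep, , drop = FALSE]
  expr <- dataset$expr[keep, , drop = FALSE]
  if (nrow(ann) == 0)
    igems_validation_error("igems_no_probes",
      "no probe survives the probe-set size filter")
  # Re-rank genomic order within each gene to a contiguous permutation.
  ann$genomic_index <- stats::ave(ann$genomic_index, ann$gene_id,
                                  FUN = function(g) rank(g, ties.method = "first"))
  ann$genomic_index <- as.integer(ann$genomic_index)
  out <- dataset
  out$expr <- expr
  out$annotation <- ann
  out
}

#' Quantile-normalize the expression matrix across samples
#'
#' Forces every sample column onto the common distribution given by the
#' across-sample mean of order statistics (the convention of
#' `limma::normalizeQuantiles`), preserving within-sample ranks.  The
#' pipeline expects RMA-style pre-normalized input; this step is optional
#' plumbing for raw-ish simulated data.
#'
#' @param x an [aeu_dataset] or a numeric matrix (probes x samples).
#' @return The same type as `x` with normalized values.
#' @export
quantile_normalize <- function(x) {
  m <- if (inherits(x, "aeu_dataset")) x$expr else as.matrix(x)
  if (ncol(m) < 2)
    igems_validation_error("igems_bad_parameter",
      "quantile normalization needs at least two samples")
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(norm) <- dimnames(m)
  if (inherits(x, "aeu_dataset")) {
    x$expr <- norm
    x
  } else {
    norm
  }
}

#' Filter genes on across-sample standard deviation of gene-level expression
#'
#' Removes genes whose gene-level log2 expression is low and invariant
#' across samples (SD below `threshold`), the optional pre-filter used when
#' contrasting strongly divergent tissues where whole transcriptional units
#' are silent in one condition (the published tissue contrast used
#' `threshold = 3` log2 units).  `threshold = NULL` (off) retains all genes.
#'
#' @param gene_summaries numeric matrix of gene-level expression
#'   (genes x samples), e.g. from [gene_summaries()].
#' @param threshold non-negative SD cutoff in log2 units, or `NULL` for off.
#' @return Character vector of retained gene ids.
#' @export
sd_filter <- function(gene_summaries, threshold) {
  gene_summaries <- as.matrix(gene_summaries)
  if (is.null(threshold)) return(rownames(gene_summaries))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    igems_validation_error("igems_bad_parameter",
      "sd_filter threshold must be a single non-negative number (or NULL)")
  sds <- apply(gene_summaries, 1, stats::sd)
  rownames(gene_summaries)[sds >= threshold]
}
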