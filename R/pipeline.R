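#' Subset a dataset to a set of genes
#'
#' @param dataset an [aeu_dataset].
#' @param gene_ids genes to keep.
#' @return The reduced [aeu_dataset].
#' @export
subset_genes <- function(dataset, gene_ids) {
  stopifnot(inherits(dataset, "aeu_dataset"))
  keep <- dataset$annotation$gene_id %in% gene_ids
  if (!any(keep))
    igems_validation_error("igems_no_probes", "no gene retained")
  out <- dataset
  out$expr <- dataset$expr[keep, , drop = FALSE]
  out$annotation <- dataset$annotation[keep, , drop = FALSE]
  rownames(out$annotation) <- NULL
  out
}

#' Run the full three-step AEU pipeline
#'
#' Orchestrates: optional quantile normalization; the minimum-probe filter;
#' per-gene median-polish fits; the optional gene-SD pre-filter; Step 1
#' (MUF score with gene-size-adjusted empirical FDR); Step 2 (splicing
#' index against decile thresholds computed over the Step-1 candidates'
#' probe-sets); Step 3 (negative-selection filter backed by a moderated
#' differential-expression test).  Deterministic given `seed`.
#'
#' @param expr_path,annot_path,design_path input TSVs (see
#'   [load_dataset()]); alternatively pass `dataset`.
#' @param dataset an [aeu_dataset], bypassing file input.
#' @param out_dir output directory for `genes.tsv`, `exons.tsv`,
#'   `run_log.txt`; `NULL` skips writing.
#' @param muf_alpha Step-1 empirical FDR cutoff (default 0.01).
#' @param si_quantile SI tail mass per side (default 0.10, the deciles).
#' @param de_alpha Step-3 DE significance cutoff (default 0.01).
#' @param null_draws resampling depth for the MUF null (default 10000).
#' @param seed master RNG seed (default 17).
#' @param min_probes minimum probes per probe-set (default 3).
#' @param sd_threshold optional gene-SD pre-filter threshold (`NULL` = off).
#' @param muf_variant `"prefix"` (default) or `"window"`, see [muf_score()].
#' @param null_method `"permutation"` (default) or `"differences"`, see
#'   [build_null_pool()].
#' @param step3_de_target `"preceding"` (default) or `"self"`, see
#'   [step3_filter()].
#' @param normalize quantile-normalize the input first (default `FALSE`;
#'   the pipeline expects pre-normalized log2 input).
#' @param dump_residuals character vector of gene ids whose residual
#'   profiles are written under `out_dir/residuals/`.
#' @return Invisibly, a list: `genes`, `exons`, `funnel`, `config`, `log`,
#'   plus the `scores` object from [score_genes()].
#' @export
run_pipeline <- function(expr_path = NULL, annot_path = NULL,
                         design_path = NULL, dataset = NULL, out_dir = NULL,
                         muf_alpha = 0.01, si_quantile = 0.10,
                         de_alpha = 0.01, null_draws = 10000, seed = 17,
                         min_probes = 3, sd_threshold = NULL,
                         muf_variant = c("prefix", "window"),
                         null_method = c("permutation", "differences"),
                         step3_de_target = c("preceding", "self"),
                         normalize = FALSE, dump_residuals = NULL) {
  muf_variant <- match.arg(muf_variant)
  null_method <- match.arg(null_method)
  step3_de_target <- match.arg(step3_de_target)
  config <- list(muf_alpha = muf_alpha, si_quantile = si_quantile,
                 de_alpha = de_alpha, null_draws = null_draws, seed = seed,
                 min_probes = min_probes,
                 sd_threshold = sd_threshold %||% "off",
                 muf_variant = muf_variant, null_method = null_method,
                 step3_de_target = step3_de_target, normalize = normalize)

  collected <- with_log_collector({
    if (is.null(dataset))
      dataset <- load_dataset(expr_path, annot_path, design_path)
    stopifnot(inherits(dataset, "aeu_dataset"))
    n_input_genes <- length(unique(dataset$annotation$gene_id))
    igems_log("input: %d probes, %d genes, %d samples",
              nrow(dataset$expr), n_input_genes, ncol(dataset$expr))
    if (normalize) dataset <- quantile_normalize(dataset)
    dataset <- filter_min_probes(dataset, min_probes)
    igems_log("after probe-set size filter (>= %d probes): %d probes, %d genes",
              min_probes, nrow(dataset$expr),
              length(unique(dataset$annotation$gene_id)))

    fits <- fit_all_genes(dataset)
    gsum <- gene_summaries(fits)
    if (!is.null(sd_threshold)) {
      retained <- sd_filter(gsum, sd_threshold)
      igems_log("SD filter (threshold %g): retained %d of %d genes",
                sd_threshold, length(retained), nrow(gsum))
      dataset <- subset_genes(dataset, retained)
      fits <- fits[retained]
      gsum <- gsum[retained, , drop = FALSE]
    }

    scored <- score_genes(dataset, null_draws = null_draws, seed = seed,
                          muf_variant = muf_variant,
                          null_method = null_method,
                          refine_alpha = muf_alpha, fits = fits)
    gene_scores <- scored$scores
    if (length(scored$excluded_from_null) > 0)
      igems_log("null refinement excluded %d candidate gene(s) from the pool",
                length(scored$excluded_from_null))
    step1_ids <- step1_select(gene_scores, muf_alpha)
    gene_scores$step1 <- gene_scores$gene_id %in% step1_ids
    igems_log("step 1 (MUF empirical FDR < %g): %d of %d genes",
              muf_alpha, length(step1_ids), nrow(gene_scores))

    ps <- probeset_summaries(dataset)
    si <- splicing_index(ps, gsum, dataset$groups)
    in_step1 <- ps$map$gene_id %in% step1_ids
    step2 <- rep(FALSE, nrow(ps$map))
    thresholds <- c(lower = NA_real_, upper = NA_real_)
    if (sum(in_step1) >= 10) {
      thresholds <- si_thresholds(si[in_step1], si_quantile)
      step2[in_step1] <- step2_select(si[in_step1], thresholds)
      igems_log("step 2 (SI thresholds [%0.4g, %0.4g]): %d of %d candidate probe-sets flagged",
                thresholds[["lower"]], thresholds[["upper"]],
                sum(step2), sum(in_step1))
    } else {
      igems_log("step 2 skipped: fewer than 10 candidate probe-sets")
    }

    de <- moderated_t_test(ps$summaries, dataset$groups)
    grp_means <- list(
      A = rowMeans(ps$summaries[, dataset$groups[colnames(ps$summaries)] == "A",
                                drop = FALSE]),
      B = rowMeans(ps$summaries[, dataset$groups[colnames(ps$summaries)] == "B",
                                drop = FALSE]))
    exons <- data.frame(gene_id = ps$map$gene_id,
                        probeset_id = ps$map$probeset_id,
                        rank_in_gene = ps$map$rank_in_gene,
                        mean_A = unname(grp_means$A),
                        mean_B = unname(grp_means$B),
                        si = unname(si),
                        de_t = de$t[match(ps$map$probeset_id, de$probeset_id)],
                        de_p = de$p[match(ps$map$probeset_id, de$probeset_id)],
                        de_fdr = de$fdr[match(ps$map$probeset_id, de$probeset_id)],
                        step2 = step2,
                        stringsAsFactors = FALSE, row.names = NULL)
    exons <- step3_filter(exons, gene_group_medians(dataset), de,
                          de_alpha = de_alpha, de_target = step3_de_target)
    res <- assemble_results(gene_scores, exons)
    igems_log("step 3 removed %d of %d flagged probe-sets; final: %d gene(s), %d exon(s)",
              res$funnel[["exons_removed_step3"]], res$funnel[["exons_step2"]],
              res$funnel[["final"]], res$funnel[["exons_final"]])
    c(res, list(scores = scored, thresholds = thresholds,
                fits = fits, dataset = dataset))
  })
  result <- collected$result
  result$config <- config
  result$log <- collected$log

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(result, out_dir)
    if (length(dump_residuals) > 0) {
      rdir <- file.path(out_dir, "residuals")
      dir.create(rdir, showWarnings = FALSE)
      for (g in intersect(dump_residuals, names(result$fits))) {
        utils::write.table(
          residual_profile(result$fits[[g]], result$dataset$groups,
                           result$dataset$annotation),
          file.path(rdir, paste0(g, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  invisible(result)
}

write_results <- function(result, out_dir) {
  gcols <- c("gene_id", "n_probes", "muf", "muf_fdr", "muf_fdr_bh",
             "step1", "step2_gene", "final")
  genes <- result$genes[, gcols]
  genes$step1 <- tolower(genes$step1)
  genes$step2_gene <- tolower(genes$step2_gene)
  genes$final <- tolower(genes$final)
  utils::write.table(genes, file.path(out_dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ecols <- c("gene_id", "probeset_id", "rank_in_gene", "mean_A", "mean_B",
             "si", "de_t", "de_p", "de_fdr", "below_median_A",
             "below_median_B", "step2", "step3_removed", "final_call")
  exons <- result$exons[, ecols]
  for (cc in c("below_median_A", "below_median_B", "step2",
               "step3_removed", "final_call"))
    exons[[cc]] <- tolower(exons[[cc]])
  utils::write.table(exons, file.path(out_dir, "exons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_lines <- c("igems run log",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("igems"))),
                 "config:",
                 sprintf("  %s = %s", names(result$config),
                         vapply(result$config, function(v)
                           paste(format(v), collapse = ","), character(1))),
                 "funnel:",
                 sprintf("  %s = %d", names(result$funnel), result$funnel),
                 "messages:",
                 paste0("  ", result$log))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(NULL)
}
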