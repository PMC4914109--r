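#' Exon-level (probe-set) expression summaries
#'
#' Per probe-set and sample, the median over the probe-set's probes of the
#' log2 values — an outlier-robust exon-level summary.
#'
#' @param dataset an [aeu_dataset].
#' @return List with `summaries` (matrix, probe-sets x samples), and
#'   `map` (data.frame `probeset_id`, `gene_id`, `rank_in_gene`,
#'   `n_probes`), rows aligned; probe-sets ordered by gene then genomic
#'   rank.
#' @export
probeset_summaries <- function(dataset) {
  stopifnot(inherits(dataset, "aeu_dataset"))
  ann <- dataset$annotation
  # rank probe-sets within each gene by the genomic index of their first probe
  first_idx <- tapply(ann$genomic_index, ann$probeset_id, min)
  gene_of <- tapply(ann$gene_id, ann$probeset_id, function(g) g[1])
  map <- data.frame(probeset_id = names(first_idx),
                    gene_id = as.character(gene_of[names(first_idx)]),
                    first_index = as.integer(first_idx),
                    stringsAsFactors = FALSE)
  map <- map[order(map$gene_id, map$first_index), , drop = FALSE]
  map$rank_in_gene <- as.integer(stats::ave(map$first_index, map$gene_id,
                                            FUN = function(x) rank(x, ties.method = "first")))
  sizes <- table(ann$probeset_id)
  map$n_probes <- as.integer(sizes[map$probeset_id])
  map$first_index <- NULL
  rownames(map) <- NULL
  rows <- split(seq_len(nrow(ann)), ann$probeset_id)
  summaries <- t(vapply(map$probeset_id, function(ps) {
    apply(dataset$expr[rows[[ps]], , drop = FALSE], 2, stats::median)
  }, numeric(ncol(dataset$expr))))
  rownames(summaries) <- map$probeset_id
  list(summaries = summaries, map = map)
}

#' Gene-level expression summaries from the additive model fit
#'
#' Per gene and sample, \eqn{g_j = \mu + \beta_j}: the model's gene-level
#' expression, used as the reference the splicing index corrects against
#' and as input to the SD pre-filter.
#'
#' @param fits named list of `gene_fit` objects (from [fit_all_genes()]).
#' @return Numeric matrix, genes x samples.
#' @export
gene_summaries <- function(fits) {
  stopifnot(length(fits) > 0, inherits(fits[[1]], "gene_fit"))
  out <- t(vapply(fits, function(f) f$overall + f$sample_effects,
                  numeric(length(fits[[1]]$sample_effects))))
  rownames(out) <- names(fits)
  out
}

#' Splicing index per probe-set
#'
#' Corrects each exon-level summary by its gene-level value and contrasts
#' the two sample classes:
#' \deqn{SI_e = \mathrm{mean}_{j \in A}(x_{ej} - g_j) -
#'       \mathrm{mean}_{j \in B}(x_{ej} - g_j)}
#' on the log2 scale.  An exon tracking its gene in both groups has SI near
#' zero; differential usage pushes SI into the tails.
#'
#' @param ps an exon-summary object from [probeset_summaries()].
#' @param gene_sum gene-level matrix from [gene_summaries()].
#' @param groups named sample -> group vector (or design data.frame).
#' @return Named numeric vector of SI values, one per probe-set (order of
#'   `ps$map`).
#' @export
splicing_index <- function(ps, gene_sum, groups) {
  groups <- as_group_vector(groups)
  x <- ps$summaries
  sa <- colnames(x)[groups[colnames(x)] == "A"]
  sb <- colnames(x)[groups[colnames(x)] == "B"]
  if (length(sa) == 0 || length(sb) == 0)
    igems_validation_error("igems_small_group",
      "splicing index needs samples in both groups")
  g <- gene_sum[ps$map$gene_id, colnames(x), drop = FALSE]
  corrected <- x - g
  rowMeans(corrected[, sa, drop = FALSE]) -
    rowMeans(corrected[, sb, drop = FALSE])
}

#' Decile thresholds on the splicing-index distribution
#'
#' Lower and upper `q`/(1-`q`) quantiles (linear interpolation) of the SI
#' values of the Step-1 candidate genes' probe-sets; the published analyses
#' used the deciles (`q = 0.10`).
#'
#' @param si numeric vector of SI values (candidate-gene probe-sets only).
#' @param q tail mass per side, in (0, 0.5).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
si_thresholds <- function(si, q = 0.10) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 0.5)
    igems_validation_error("igems_bad_parameter", "q must be in (0, 0.5)")
  if (length(si) < 10)
    igems_validation_error("igems_bad_parameter",
      "need at least 10 probe-sets to estimate SI thresholds")
  qs <- stats::quantile(si, c(q, 1 - q), names = FALSE, type = 7)
  c(lower = qs[1], upper = qs[2])
}

#' Step-2 selection: probe-sets in the SI tails
#'
#' Flags probe-sets with `si <= lower` or `si >= upper` (ties at a
#' threshold are included).  A degenerate SI distribution (collapsed
#' deciles, `lower >= upper`) flags nothing.  A gene survives Step 2 iff at
#' least one of its probe-sets is flagged.
#'
#' @param si named numeric vector of SI values.
#' @param thresholds from [si_thresholds()].
#' @return Logical vector parallel to `si`.
#' @export
step2_select <- function(si, thresholds) {
  if (thresholds[["lower"]] >= thresholds[["upper"]])
    return(rep(FALSE, length(si)))
  si <= thresholds[["lower"]] | si >= thresholds[["upper"]]
}

#' Moderated two-sample t test per probe-set
#'
#' Empirical-Bayes moderated t statistics contrasting groups A and B for
#' every probe-set summary, computed with `limma` (`lmFit` + `eBayes`):
#' per-row variances are shrunk toward a common prior,
#' \eqn{\tilde s^2 = (d_0 s_0^2 + df\, s^2)/(d_0 + df)}, and p-values use
#' \eqn{d_0 + df} degrees of freedom, with Benjamini-Hochberg adjustment
#' across probe-sets.  With fewer than `min_sets` probe-sets (too few rows
#' to estimate the prior) or when prior estimation fails, an ordinary
#' pooled-variance two-sample t is used instead and the `method` field
#' records the fallback.
#'
#' @param x numeric matrix of exon summaries (probe-sets x samples), or a
#'   [probeset_summaries()] result.
#' @param groups named sample -> group vector (or design data.frame).
#' @param min_sets minimum number of rows for empirical-Bayes moderation
#'   (default 10).
#' @return data.frame: `probeset_id`, `effect` (mean A - mean B), `t`,
#'   `df`, `p`, `fdr` (BH), `method` (`"eBayes"` or `"ordinary"`).
#' @export
moderated_t_test <- function(x, groups, min_sets = 10) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$summaries)) x <- x$summaries
  x <- as.matrix(x)
  groups <- as_group_vector(groups)
  sa <- colnames(x)[groups[colnames(x)] == "A"]
  sb <- colnames(x)[groups[colnames(x)] == "B"]
  if (length(sa) < 2 || length(sb) < 2)
    igems_validation_error("igems_small_group",
      "moderated t needs at least two samples per group")
  effect <- rowMeans(x[, sa, drop = FALSE]) - rowMeans(x[, sb, drop = FALSE])
  res <- NULL
  if (nrow(x) >= min_sets) {
    grp <- factor(ifelse(colnames(x) %in% sa, "A", "B"), levels = c("B", "A"))
    design <- stats::model.matrix(~grp)  # coefficient 2 = A - B
    res <- tryCatch({
      fit <- limma::lmFit(x, design)
      fit <- limma::eBayes(fit)
      data.frame(probeset_id = rownames(x),
                 effect = unname(effect),
                 t = unname(fit$t[, 2]),
                 df = unname(rep_len(fit$df.total, nrow(x))),
                 p = unname(fit$p.value[, 2]),
                 method = "eBayes",
                 stringsAsFactors = FALSE, row.names = NULL)
    }, error = function(e) NULL)
    if (!is.null(res) && (anyNA(res$t) || anyNA(res$p))) res <- NULL
  }
  if (is.null(res)) {
    if (nrow(x) >= min_sets)
      igems_log("moderated t prior estimation failed; using ordinary pooled t")
    na <- length(sa); nb <- length(sb)
    va <- apply(x[, sa, drop = FALSE], 1, stats::var)
    vb <- apply(x[, sb, drop = FALSE], 1, stats::var)
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(s2 * (1 / na + 1 / nb))
    t <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, sign(effect) * Inf))
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(t), df)
    res <- data.frame(probeset_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                      effect = unname(effect), t = unname(t),
                      df = df, p = unname(p), method = "ordinary",
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res[, c("probeset_id", "effect", "t", "df", "p", "fdr", "method")]
}

#' Per-gene, per-group median of probe-level expression
#'
#' The "median gene expression" reference the Step-3 rule compares exon
#' summaries against: for each gene, the median over all its probe-level
#' log2 values within the samples of each group.
#'
#' @param dataset an [aeu_dataset].
#' @return Matrix genes x 2 with columns `A`, `B`.
#' @export
gene_group_medians <- function(dataset) {
  stopifnot(inherits(dataset, "aeu_dataset"))
  sa <- names(dataset$groups)[dataset$groups == "A"]
  sb <- names(dataset$groups)[dataset$groups == "B"]
  idx <- split(seq_len(nrow(dataset$expr)), dataset$annotation$gene_id)
  out <- t(vapply(idx, function(rows) {
    c(A = stats::median(dataset$expr[rows, sa, drop = FALSE]),
      B = stats::median(dataset$expr[rows, sb, drop = FALSE]))
  }, numeric(2)))
  out
}

#' Step-3 negative-selection filter
#'
#' Removes Step-2 flagged exons that carry the signature of a
#' background-level false positive: exon expression below the gene's median
#' expression in *both* groups, while the probe-set immediately preceding
#' the flagged exon in genomic order shows no differential expression
#' (moderated-t BH value above `de_alpha`).  That pattern arises when a
#' gene's 5' probe-sets sit at array background in both conditions and the
#' whole gene shifts in expression — a gene-level change masquerading as
#' local exon usage.  For a flagged exon that is the first probe-set of its
#' gene, the exon itself substitutes for the missing predecessor in the DE
#' clause (or always, with `de_target = "self"`).
#'
#' @param exons exon table carrying at least `gene_id`, `probeset_id`,
#'   `rank_in_gene`, `mean_A`, `mean_B`, `step2`.
#' @param gene_medians matrix from [gene_group_medians()].
#' @param de [moderated_t_test()] result covering all probe-sets.
#' @param de_alpha DE significance cutoff (default 0.01, the published
#'   "FDR > 1 percent" clause).
#' @param de_target `"preceding"` (default) tests the predecessor exon,
#'   `"self"` tests the flagged exon itself.
#' @return `exons` with added/updated logical columns `below_median_A`,
#'   `below_median_B`, `step3_removed`.
#' @export
step3_filter <- function(exons, gene_medians, de, de_alpha = 0.01,
                         de_target = c("preceding", "self")) {
  de_target <- match.arg(de_target)
  if (!is.numeric(de_alpha) || de_alpha <= 0 || de_alpha >= 1)
    igems_validation_error("igems_bad_parameter", "de_alpha must be in (0, 1)")
  de_fdr <- stats::setNames(de$fdr, de$probeset_id)
  exons$below_median_A <- exons$mean_A < gene_medians[exons$gene_id, "A"]
  exons$below_median_B <- exons$mean_B < gene_medians[exons$gene_id, "B"]
  # probe-set whose DE status backs the clause, per row
  target_ps <- exons$probeset_id
  if (de_target == "preceding") {
    pred <- match(paste(exons$gene_id, exons$rank_in_gene - 1L),
                  paste(exons$gene_id, exons$rank_in_gene))
    has_pred <- !is.na(pred)
    target_ps[has_pred] <- exons$probeset_id[pred[has_pred]]
    n_first <- sum(exons$step2 & !has_pred)
    if (n_first > 0)
      igems_log("%d flagged first-exon event(s): DE clause applied to the exon itself",
                n_first)
  }
  not_de <- de_fdr[target_ps] > de_alpha
  exons$step3_removed <- exons$step2 & exons$below_median_A &
    exons$below_median_B & as.vector(not_de)
  exons
}

#' Assemble the final gene and exon result tables
#'
#' Combines gene scores with the exon-level table into the pipeline's two
#' outputs.  The final AEU call per exon is
#' `step1 & step2 & !step3_removed`; a gene makes the final list iff it has
#' at least one final-call exon.
#'
#' @param gene_scores `scores` data.frame from [score_genes()], plus a
#'   logical `step1` column.
#' @param exons exon table after [step3_filter()].
#' @return List with `genes` (gene table with `step1`, `step2_gene`,
#'   `final` flags and per-step exon counts), `exons` (with `final_call`),
#'   and `funnel` (named counts of genes surviving each step).
#' @export
assemble_results <- function(gene_scores, exons) {
  step1_of <- stats::setNames(gene_scores$step1, gene_scores$gene_id)
  exons$final_call <- step1_of[exons$gene_id] & exons$step2 &
    !exons$step3_removed
  exons$final_call[is.na(exons$final_call)] <- FALSE
  by_gene <- function(flag) {
    agg <- tapply(flag, exons$gene_id, any)
    out <- stats::setNames(rep(FALSE, nrow(gene_scores)), gene_scores$gene_id)
    out[names(agg)] <- agg
    out
  }
  genes <- gene_scores
  genes$step2_gene <- unname(by_gene(exons$step2) & genes$step1)
  genes$final <- unname(by_gene(exons$final_call))
  funnel <- c(genes_tested = nrow(genes),
              step1 = sum(genes$step1),
              step2 = sum(genes$step2_gene),
              final = sum(genes$final),
              exons_tested = nrow(exons),
              exons_step2 = sum(exons$step2),
              exons_removed_step3 = sum(exons$step3_removed),
              exons_final = sum(exons$final_call))
  list(genes = genes, exons = exons, funnel = funnel)
}
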