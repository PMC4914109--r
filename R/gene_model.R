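#' Fit the per-gene additive probe/sample model by median polish
#'
#' Decomposes a gene's log2 probe-by-sample block as
#' \deqn{y_{pj} = \mu + \alpha_p + \beta_j + \varepsilon_{pj}}
#' with probe effects \eqn{\alpha_p}, sample effects \eqn{\beta_j} and
#' residuals \eqn{\varepsilon_{pj}}, using Tukey's median polish
#' (alternating row/column median sweeps).  The median fit is robust to
#' outlying probes and replicates; its residuals are the raw material for
#' the MUF score.  The decomposition identity holds exactly at every
#' iteration; convergence is declared when every row and column median of
#' the residual matrix is at most `tol` in absolute value.
#'
#' @param y numeric matrix, probes (genomic order) x samples, log2 scale.
#' @param gene_id optional gene identifier carried on the result.
#' @param tol convergence tolerance on residual row/column medians
#'   (default 1e-6).
#' @param max_iter maximum number of sweep pairs (default 200); on
#'   non-convergence the last iterate is returned with `converged = FALSE`
#'   and a warning.
#' @return An object of class `gene_fit`: list with `gene_id`, `overall`
#'   (\eqn{\mu}), `probe_effects`, `sample_effects`, `residuals`,
#'   `converged`, `iterations`.
#' @export
fit_gene_model <- function(y, gene_id = NULL, tol = 1e-6, max_iter = 200) {
  y <- as.matrix(y)
  if (nrow(y) < 2 || ncol(y) < 2)
    igems_validation_error("igems_bad_parameter",
      "gene model needs at least 2 probes and 2 samples")
  if (anyNA(y) || any(!is.finite(y)))
    igems_error("igems_non_finite", "non-finite value in gene submatrix")
  fit <- .median_polish_cpp(y, tol, as.integer(max_iter))
  if (!fit$converged)
    warning(sprintf("median polish for %s did not converge in %d iterations",
                    gene_id %||% "gene", max_iter))
  r <- fit$residuals
  dimnames(r) <- dimnames(y)
  structure(list(gene_id = gene_id, overall = fit$overall,
                 probe_effects = stats::setNames(fit$alpha, rownames(y)),
                 sample_effects = stats::setNames(fit$beta, colnames(y)),
                 residuals = r, converged = fit$converged,
                 iterations = fit$iterations),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("gene_fit%s: %d probes x %d samples, %d iteration(s)%s\n",
              if (is.null(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              nrow(x$residuals), ncol(x$residuals), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Per-probe condition difference of median residuals
#'
#' For each probe (genomic order) takes the median of the model residuals
#' over the group-A samples minus the median over the group-B samples.
#' Medians over biological replicates make the difference robust to single
#' outlying arrays.  This vector is what the MUF score summarizes and what
#' the empirical null pool is built from.
#'
#' @param fit a [fit_gene_model()] result.
#' @param groups named character vector sample_id -> `"A"`/`"B"` (an
#'   `aeu_dataset$groups`), or a design data.frame with `sample_id`/`group`.
#' @return Named numeric vector `d`, one entry per probe in genomic order.
#' @export
residual_difference <- function(fit, groups) {
  stopifnot(inherits(fit, "gene_fit"))
  groups <- as_group_vector(groups)
  r <- fit$residuals
  ga <- colnames(r)[groups[colnames(r)] == "A"]
  gb <- colnames(r)[groups[colnames(r)] == "B"]
  if (length(ga) < 2 || length(gb) < 2)
    igems_validation_error("igems_small_group",
      "residual_difference needs at least two samples per group")
  apply(r[, ga, drop = FALSE], 1, stats::median) -
    apply(r[, gb, drop = FALSE], 1, stats::median)
}

as_group_vector <- function(groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(groups$group, groups$sample_id)
  if (is.null(names(groups)) || !all(groups %in% c("A", "B")))
    igems_validation_error("igems_bad_group",
      "groups must be a named vector of 'A'/'B' labels")
  groups
}

#' MUF score: maximum absolute partial sum of residual differences
#'
#' Scans the per-probe condition differences `d` in genomic order and
#' returns the largest absolute running (prefix) sum
#' \eqn{\max_k |\sum_{p \le k} d_p|} — the "Material Unaccounted For"
#' statistic.  A persistent, consistent local run of same-signed residual
#' differences (the signature of an alternatively used exon) accumulates
#' into a large score, whereas unstructured noise cancels.  The `"window"`
#' variant instead takes the maximum over all contiguous windows,
#' \eqn{\max_k S_k - \min_k S_k} with \eqn{S_0 = 0}.
#'
#' @param d numeric vector of residual differences in genomic order.
#' @param variant `"prefix"` (default) or `"window"`.
#' @return A single non-negative number.
#' @export
muf_score <- function(d, variant = c("prefix", "window")) {
  variant <- match.arg(variant)
  if (length(d) == 0)
    igems_validation_error("igems_bad_parameter", "empty residual-difference vector")
  if (anyNA(d) || any(!is.finite(d)))
    igems_error("igems_non_finite", "non-finite residual difference")
  s <- cumsum(d)
  if (variant == "prefix") max(abs(s)) else max(s, 0) - min(s, 0)
}

#' Per-probe residual profile for a gene
#'
#' One row per probe in genomic order, with the group-wise median residuals
#' and their difference `d` — the quantities plotted when inspecting a
#' candidate AEU gene.
#'
#' @inheritParams residual_difference
#' @param annotation optional annotation rows for this gene's probes (used
#'   to attach probe-set ids); matched by probe_id.
#' @return data.frame with columns `probe_id`, `genomic_index`,
#'   (`probeset_id` when annotation is given,) `median_residual_A`,
#'   `median_residual_B`, `d`.
#' @export
residual_profile <- function(fit, groups, annotation = NULL) {
  stopifnot(inherits(fit, "gene_fit"))
  groups <- as_group_vector(groups)
  r <- fit$residuals
  ga <- colnames(r)[groups[colnames(r)] == "A"]
  gb <- colnames(r)[groups[colnames(r)] == "B"]
  ma <- apply(r[, ga, drop = FALSE], 1, stats::median)
  mb <- apply(r[, gb, drop = FALSE], 1, stats::median)
  out <- data.frame(probe_id = rownames(r),
                    genomic_index = seq_len(nrow(r)),
                    median_residual_A = ma,
                    median_residual_B = mb,
                    d = ma - mb,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(annotation)) {
    idx <- match(out$probe_id, annotation$probe_id)
    out$genomic_index <- annotation$genomic_index[idx]
    out$probeset_id <- annotation$probeset_id[idx]
    out <- out[, c("probe_id", "genomic_index", "probeset_id",
                   "median_residual_A", "median_residual_B", "d")]
  }
  out
}

#' Fit the additive model for every gene of a dataset
#'
#' @param dataset an [aeu_dataset] (probes already ordered by gene and
#'   genomic index).
#' @param tol,max_iter passed to [fit_gene_model()].
#' @return Named list of `gene_fit` objects, one per gene.
#' @export
fit_all_genes <- function(dataset, tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(dataset, "aeu_dataset"))
  idx <- split(seq_len(nrow(dataset$expr)), dataset$annotation$gene_id)
  lapply_named(idx, function(rows, gene) {
    fit_gene_model(dataset$expr[rows, , drop = FALSE], gene_id = gene,
                   tol = tol, max_iter = max_iter)
  })
}

lapply_named <- function(x, f) {
  out <- mapply(f, x, names(x), SIMPLIFY = FALSE)
  names(out) <- names(x)
  out
}
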