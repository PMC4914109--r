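#' Pool per-gene model residuals into an empirical null resource
#'
#' The gene-size-adjusted null is built by randomly resampling from the
#' available model residuals.  Two methods are supported:
#' \describe{
#'   \item{`"permutation"` (default)}{keep every gene's residual matrix
#'     intact, grouped by gene size.  A null pseudo-gene of \eqn{n} probes
#'     picks one \eqn{n}-probe gene uniformly at random, randomly
#'     reassigns its \eqn{n_A + n_B} sample columns into pseudo-groups,
#'     and reduces each probe to its pseudo-group median difference before
#'     MUF scoring.  Because median-polish residuals are invariant to
#'     column permutation, these draws have exactly the null distribution
#'     of the observed statistic whenever samples are exchangeable within
#'     a gene — the null inherits every within-gene constraint of the fit
#'     (the bridge-like, sum-constrained character of the running sum of
#'     `d`) as well as the data's own noise distribution, with no scale
#'     estimate or re-fit.  [score_genes()] additionally purifies the pool
#'     iteratively so genes carrying genuine events cannot contaminate
#'     the null.}
#'   \item{`"differences"`}{pool the per-probe condition-median residual
#'     differences `d` across all genes and build pseudo-genes from iid
#'     draws of those.  Cheaper and simpler, but the null ignores the
#'     fit's sum constraints, which makes it markedly conservative: iid
#'     partial sums wander much farther than the constrained ones real
#'     null genes produce.}
#' }
#' The method is inferred from the input when not given: `gene_fit`
#' objects or residual matrices imply `"permutation"`, plain `d` vectors
#' imply `"differences"`.
#'
#' @param x list of per-gene inputs: `gene_fit` objects or residual
#'   matrices (for `"permutation"`), or numeric `d` vectors from
#'   [residual_difference()] (for `"differences"`).
#' @param method `"permutation"` or `"differences"`; default inferred.
#' @return Object of class `muf_null_pool`.  For `"permutation"` a list
#'   with element `by_size`: per gene size, a list holding the stacked
#'   residual matrix `resid` and the 0-based first row of each gene
#'   `gene_start`.  For `"differences"` a list with element `d`, the
#'   pooled difference vector.  Both carry attributes `method` and
#'   `n_genes`.
#' @export
build_null_pool <- function(x, method = NULL) {
  if (length(x) == 0)
    igems_validation_error("igems_bad_parameter",
      "null pool needs at least one gene")
  if (is.null(method))
    method <- if (inherits(x[[1]], "gene_fit") || is.matrix(x[[1]]))
      "permutation" else "differences"
  method <- match.arg(method, c("permutation", "differences"))
  pool <- if (method == "permutation") {
    mats <- lapply(x, function(el) {
      if (inherits(el, "gene_fit")) el$residuals else as.matrix(el)
    })
    if (any(vapply(mats, function(m) anyNA(m) || any(!is.finite(m)),
                   logical(1))))
      igems_error("igems_non_finite", "null pool contains non-finite values")
    nc <- unique(vapply(mats, ncol, integer(1)))
    if (length(nc) != 1)
      igems_validation_error("igems_bad_parameter",
        "all residual matrices must share the same samples")
    sizes <- vapply(mats, nrow, integer(1))
    by_size <- lapply(split(mats, sizes), function(group) {
      list(resid = do.call(rbind, group),
           gene_start = as.integer(
             cumsum(c(0L, vapply(group, nrow, integer(1))))[
               seq_along(group)]))
    })
    list(by_size = by_size)
  } else {
    d <- unlist(lapply(x, as.numeric), use.names = FALSE)
    if (length(d) == 0 || anyNA(d) || any(!is.finite(d)))
      igems_error("igems_non_finite", "null pool contains non-finite values")
    list(d = d)
  }
  structure(pool, n_genes = length(x), method = method,
            class = "muf_null_pool")
}

#' Sample a size-matched empirical MUF null distribution
#'
#' Draws `draws` pseudo-genes of `n_probes` probes each and reduces each
#' to its MUF score.  Because longer genes offer more partial sums, larger
#' `n_probes` produces stochastically larger null MUF values — the
#' distribution is therefore keyed by probe count ("gene size
#' adjustment").  For a `"permutation"` pool each pseudo-gene is a random
#' same-size gene under a random reassignment of its samples into
#' pseudo-groups of `n_A` and `n_B`; for a `"differences"` pool each
#' probe draws a pooled `d` value directly.
#'
#' @param pool a [build_null_pool()] result (a plain numeric vector is
#'   treated as a `"differences"` pool).
#' @param n_probes gene size the null is built for (>= 1); a
#'   `"permutation"` pool must contain genes of exactly this size.
#' @param draws number of resampled pseudo-genes (default 10000, min 100).
#' @param seed integer seed making the draw reproducible.
#' @param variant MUF variant, see [muf_score()].
#' @param n_A,n_B group sizes (required for a `"permutation"` pool).
#' @return Object of class `muf_null`: list with `n_probes`, `draws`,
#'   `mufs` (sorted ascending), `seed`, `variant`, `method`.
#' @export
sample_null_mufs <- function(pool, n_probes, draws = 10000, seed = 1,
                             variant = c("prefix", "window"),
                             n_A = NULL, n_B = NULL) {
  variant <- match.arg(variant)
  method <- attr(pool, "method") %||% "differences"
  if (is.numeric(pool) && is.null(attr(pool, "method")))
    pool <- list(d = as.numeric(pool))
  if (!is.numeric(n_probes) || n_probes < 1)
    igems_validation_error("igems_bad_parameter", "n_probes must be >= 1")
  if (draws < 100)
    igems_validation_error("igems_bad_parameter", "draws must be >= 100")
  if (method == "permutation" && (is.null(n_A) || is.null(n_B) ||
                                  n_A < 2 || n_B < 2))
    igems_validation_error("igems_bad_parameter",
      "a 'permutation' pool needs group sizes n_A and n_B (each >= 2)")
  n_probes <- as.integer(n_probes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  mufs <- if (method == "permutation") {
    stack <- pool$by_size[[as.character(n_probes)]]
    if (is.null(stack))
      igems_validation_error("igems_null_size_mismatch",
        sprintf("null pool has no genes with %d probes", n_probes))
    if (ncol(stack$resid) != n_A + n_B)
      igems_validation_error("igems_bad_parameter",
        "n_A + n_B must equal the pooled residuals' sample count")
    .null_mufs_permutation_cpp(stack$resid, stack$gene_start, n_probes,
                               as.integer(n_A), as.integer(n_B),
                               as.integer(draws), variant == "window")
  } else {
    if (length(pool$d) == 0)
      igems_validation_error("igems_bad_parameter", "empty null pool")
    .null_mufs_differences_cpp(as.numeric(pool$d), n_probes,
                               as.integer(draws), variant == "window")
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(n_probes = n_probes, draws = as.integer(draws),
                 mufs = sort(mufs), seed = as.integer(seed),
                 variant = variant, method = method),
            class = "muf_null")
}

#' Build null distributions for every gene size present in the data
#'
#' One cached distribution per distinct post-filter probe count; per-count
#' seeds are spawned deterministically from a single master seed.
#'
#' @param pool a [build_null_pool()] result.
#' @param probe_counts integer vector of gene sizes to cover (duplicates
#'   collapsed).
#' @inheritParams sample_null_mufs
#' @return Named list of `muf_null` objects, keyed by probe count.
#' @export
null_distributions <- function(pool, probe_counts, draws = 10000, seed = 1,
                               variant = c("prefix", "window"),
                               n_A = NULL, n_B = NULL) {
  variant <- match.arg(variant)
  counts <- sort(unique(as.integer(probe_counts)))
  seeds <- spawn_seeds(seed, length(counts))
  out <- mapply(function(n, s)
    sample_null_mufs(pool, n, draws, s, variant, n_A = n_A, n_B = n_B),
    counts, seeds, SIMPLIFY = FALSE)
  names(out) <- as.character(counts)
  out
}

#' Empirical tail probability of an observed MUF score
#'
#' Probability of obtaining an identical or more extreme MUF score from the
#' size-matched empirical null, with the add-one convention
#' \eqn{(\#\{null \ge obs\} + 1) / (B + 1)} so the estimate is never zero.
#' The pipeline reports this per-gene tail probability as `muf_fdr`,
#' following the pipeline's published naming.
#'
#' @param observed_muf observed MUF score(s); vectorized.
#' @param null_dist a `muf_null` object (or a plain numeric vector of null
#'   MUF draws).
#' @param n_probes when given and `null_dist` is a `muf_null`, must match
#'   its `n_probes` key (guards against using a wrong-size null).
#' @return Numeric vector of values in (0, 1].
#' @export
empirical_fdr <- function(observed_muf, null_dist, n_probes = NULL) {
  if (inherits(null_dist, "muf_null")) {
    if (!is.null(n_probes) && as.integer(n_probes) != null_dist$n_probes)
      igems_validation_error("igems_null_size_mismatch",
        sprintf("null distribution keyed for %d probes, gene has %d",
                null_dist$n_probes, as.integer(n_probes)))
    nulls <- null_dist$mufs
  } else {
    nulls <- sort(as.numeric(null_dist))
  }
  B <- length(nulls)
  n_below <- findInterval(observed_muf, nulls, left.open = TRUE)
  (B - n_below + 1) / (B + 1)
}

#' Score every gene: MUF, gene-size-adjusted empirical FDR (Step 1)
#'
#' Fits the per-gene model, computes residual differences and MUF scores,
#' builds the resampled null, and assigns each gene its empirical tail
#' probability (`muf_fdr`) plus a Benjamini-Hochberg adjusted companion
#' column (`muf_fdr_bh`).  Step-1 selection uses `muf_fdr` (the pipeline's
#' published behavior).
#'
#' With the default `"permutation"` method the null for an \eqn{n}-probe
#' gene pools sample-label permutations of all \eqn{n}-probe genes (see
#' [build_null_pool()]), which is exactly calibrated under within-gene
#' sample exchangeability.  Genes carrying genuine events would inflate
#' that pool, so the null is iteratively refined: genes whose empirical
#' FDR falls below `refine_alpha` are excluded from the pool and all
#' genes are re-scored against the purified pool, until no new gene is
#' excluded (or `max_refine` passes).  Exclusion is cumulative, so the
#' pool shrinks monotonically and the iteration terminates.  Under a
#' global null the exclusion removes genes essentially at random (a null
#' gene's observed score is a single draw from its own permutation
#' distribution, which is interchangeable with its same-size peers'), so
#' calibration is preserved; with signal present it removes precisely the
#' contaminating genes.  The `"differences"` method uses the pooled,
#' size-keyed iid null instead, without refinement.
#'
#' @param dataset a filtered [aeu_dataset].
#' @param null_draws resampling depth per gene size (default 10000).
#' @param seed master seed for the resampling.
#' @param muf_variant see [muf_score()].
#' @param null_method see [build_null_pool()]; default `"permutation"`.
#' @param refine_alpha exclusion threshold for the null refinement
#'   (default 0.01, matching the Step-1 selection threshold); `NULL`
#'   disables refinement.
#' @param max_refine maximum refinement passes after the first scoring
#'   pass (default 5).
#' @param fits optional precomputed [fit_all_genes()] result.
#' @return List with `scores` (data.frame: `gene_id`, `n_probes`, `muf`,
#'   `muf_fdr`, `muf_fdr_bh`), `fits`, `d` (list of residual-difference
#'   vectors), `pool` (the refined pool when refinement ran), `nulls`
#'   (the size-keyed null distributions actually used), and
#'   `excluded_from_null` (gene ids dropped by the refinement).
#' @export
score_genes <- function(dataset, null_draws = 10000, seed = 17,
                        muf_variant = c("prefix", "window"),
                        null_method = c("permutation", "differences"),
                        refine_alpha = 0.01, max_refine = 5, fits = NULL) {
  muf_variant <- match.arg(muf_variant)
  null_method <- match.arg(null_method)
  stopifnot(inherits(dataset, "aeu_dataset"))
  if (!is.null(refine_alpha) &&
      (!is.numeric(refine_alpha) || length(refine_alpha) != 1 ||
       refine_alpha <= 0 || refine_alpha > 1))
    igems_validation_error("igems_bad_parameter",
      "refine_alpha must be in (0, 1] or NULL")
  if (is.null(fits)) fits <- fit_all_genes(dataset)
  d <- lapply(fits, residual_difference, groups = dataset$groups)
  muf <- vapply(d, muf_score, numeric(1), variant = muf_variant)
  n_probes <- vapply(d, length, integer(1))
  n_A <- sum(dataset$groups == "A")
  n_B <- sum(dataset$groups == "B")
  if (!is.numeric(max_refine) || length(max_refine) != 1 || max_refine < 0)
    igems_validation_error("igems_bad_parameter", "max_refine must be >= 0")
  max_refine <- as.integer(max_refine)
  seeds <- spawn_seeds(seed, max_refine + 1L)

  fdr_against <- function(pool, pass_seed) {
    nulls <- null_distributions(pool, n_probes, draws = null_draws,
                                seed = pass_seed, variant = muf_variant,
                                n_A = n_A, n_B = n_B)
    fdr <- vapply(seq_along(muf), function(i) {
      empirical_fdr(muf[i], nulls[[as.character(n_probes[i])]], n_probes[i])
    }, numeric(1))
    list(fdr = fdr, nulls = nulls)
  }

  excluded <- character(0)
  if (null_method == "permutation") {
    full_pool <- build_null_pool(fits)
    pool <- full_pool
    pass <- fdr_against(pool, seeds[1])
    fdr <- pass$fdr
    nulls <- pass$nulls
    if (!is.null(refine_alpha)) {
      for (r in seq_len(max_refine)) {
        new_excl <- union(excluded, names(fits)[fdr < refine_alpha])
        if (length(new_excl) == length(excluded) ||
            length(new_excl) == length(fits))
          break
        excluded <- new_excl
        keep_fits <- fits[!(names(fits) %in% excluded)]
        pool <- build_null_pool(keep_fits)
        # sizes absent from the purified pool fall back to the full one
        missing <- setdiff(names(full_pool$by_size), names(pool$by_size))
        if (length(missing) > 0)
          pool$by_size[missing] <- full_pool$by_size[missing]
        pass <- fdr_against(pool, seeds[r + 1L])
        fdr <- pass$fdr
        nulls <- pass$nulls
      }
    }
  } else {
    pool <- build_null_pool(d)
    pass1 <- fdr_against(pool, seeds[1])
    fdr <- pass1$fdr
    nulls <- pass1$nulls
  }
  scores <- data.frame(gene_id = names(fits), n_probes = n_probes,
                       muf = muf, muf_fdr = fdr,
                       muf_fdr_bh = stats::p.adjust(fdr, method = "BH"),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(scores = scores, fits = fits, d = d, pool = pool, nulls = nulls,
       excluded_from_null = excluded)
}

#' Step-1 selection: genes with empirical MUF FDR below alpha
#'
#' @param gene_scores the `scores` data.frame from [score_genes()].
#' @param alpha selection threshold in (0, 1]; the published analyses used
#'   0.01 ("FDR below 1 percent").
#' @return Character vector of selected gene ids, ranked by ascending
#'   `muf_fdr` then descending `muf`.
#' @export
step1_select <- function(gene_scores, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    igems_validation_error("igems_bad_parameter", "alpha must be in (0, 1]")
  sel <- gene_scores[gene_scores$muf_fdr < alpha, , drop = FALSE]
  sel <- sel[order(sel$muf_fdr, -sel$muf), , drop = FALSE]
  sel$gene_id
}
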