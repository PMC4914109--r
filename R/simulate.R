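#' Simulation configuration
#'
#' Describes a synthetic two-group exon-array experiment with known
#' alternative-exon-usage truth.  Probe-level log2 values follow
#' \deqn{y_{pj} = \mu_g + a_p + 1[j \in B](\tau_g + \delta_{e(p)}) +
#'       \varepsilon_{pj}}
#' with gene baseline \eqn{\mu_g \sim N(7, 2)} (typical RMA log2 levels),
#' fixed per-probe affinities \eqn{a_p \sim N(0, 0.8)} (array physics: a
#' probe's affinity is a property of its sequence, constant across
#' samples), homoscedastic replicate noise \eqn{\varepsilon \sim
#' N(0, 0.25^2)}, and class-specific event terms:
#' \itemize{
#'   \item `cassette_up` / `cassette_down`: one internal probe-set gains
#'     \eqn{\delta_e = +\Delta} / \eqn{-\Delta} in group B (exon
#'     inclusion/exclusion);
#'   \item `utr3_extension`: the last probe-set gains \eqn{+\Delta}
#'     (differential 3'UTR usage);
#'   \item `rxrg_artifact`: the first 25 percent of probe-sets are clamped to
#'     array background in both groups while the rest of the gene shifts by
#'     \eqn{\tau_g = \Delta} — the background-5'-plus-whole-gene-DE pattern
#'     that produces false-positive AEU calls and that the Step-3 filter
#'     targets (not a true event);
#'   \item `gene_DE_only`: \eqn{\tau_g = \Delta} with all \eqn{\delta = 0}
#'     — plain differential gene expression, which must not be called AEU.
#' }
#'
#' @param n_genes number of genes (default 200).
#' @param probesets_range inclusive range of probe-sets per gene (default
#'   4-12, uniform).
#' @param probes_per_probeset probes per probe-set (default 4).
#' @param n_per_group samples per group (default 8).
#' @param gene_level_mean,gene_level_sd baseline log2 gene level
#'   distribution (default Normal(7, 2)).
#' @param affinity_sd SD of fixed per-probe affinities (default 0.8 log2).
#' @param noise_sd replicate noise SD (default 0.25 log2).
#' @param background array background level (default 3.0 log2).
#' @param effect_size event magnitude \eqn{\Delta} in log2 (default 1.0).
#' @param fractions named fractions of genes per event class; any subset of
#'   `cassette_up`, `cassette_down`, `utr3_extension`, `rxrg_artifact`,
#'   `gene_DE_only`; must sum to at most 1.  Class counts are
#'   `round(fraction * n_genes)`, assigned to randomly chosen genes.
#' @param noise_df degrees of freedom for heavy-tailed (scaled t) noise;
#'   `Inf` (default) gives Gaussian noise.
#' @param seed RNG seed.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 200, probesets_range = c(4, 12),
                       probes_per_probeset = 4, n_per_group = 8,
                       gene_level_mean = 7, gene_level_sd = 2,
                       affinity_sd = 0.8, noise_sd = 0.25, background = 3,
                       effect_size = 1, fractions = numeric(0),
                       noise_df = Inf, seed = 1) {
  classes <- c("cassette_up", "cassette_down", "utr3_extension",
               "rxrg_artifact", "gene_DE_only")
  fr <- stats::setNames(rep(0, length(classes)), classes)
  if (length(fractions) > 0) {
    if (is.null(names(fractions)) || !all(names(fractions) %in% classes))
      igems_validation_error("igems_bad_parameter",
        sprintf("fractions must be named among: %s",
                paste(classes, collapse = ", ")))
    fr[names(fractions)] <- fractions
  }
  if (any(fr < 0) || sum(fr) > 1)
    igems_validation_error("igems_bad_parameter",
      "class fractions must be non-negative and sum to at most 1")
  if (effect_size < 0)
    igems_validation_error("igems_bad_parameter", "effect_size must be >= 0")
  if (noise_sd <= 0)
    igems_validation_error("igems_bad_parameter", "noise_sd must be > 0")
  if (n_genes < 1 || n_per_group < 2 || probes_per_probeset < 1 ||
      probesets_range[1] < 2 || probesets_range[2] < probesets_range[1])
    igems_validation_error("igems_bad_parameter", "infeasible simulation sizes")
  structure(list(n_genes = as.integer(n_genes),
                 probesets_range = as.integer(probesets_range),
                 probes_per_probeset = as.integer(probes_per_probeset),
                 n_per_group = as.integer(n_per_group),
                 gene_level_mean = gene_level_mean,
                 gene_level_sd = gene_level_sd,
                 affinity_sd = affinity_sd, noise_sd = noise_sd,
                 background = background, effect_size = effect_size,
                 fractions = fr, noise_df = noise_df,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a probe-level dataset with known AEU truth
#'
#' @param config a [sim_config()].
#' @return List with `dataset` (an [aeu_dataset]) and `truth`: a list of
#'   `genes` (data.frame `gene_id`, `class`, `is_true_aeu_gene`) and
#'   `exons` (data.frame `gene_id`, `probeset_id`, `rank_in_gene`,
#'   `is_true_AEU`, `is_artifact`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ppp <- config$probes_per_probeset
  n_grp <- config$n_per_group
  samples <- c(sprintf("A%02d", seq_len(n_grp)), sprintf("B%02d", seq_len(n_grp)))
  in_b <- rep(c(FALSE, TRUE), each = n_grp)

  # deterministic class counts, random gene assignment
  counts <- round(config$fractions * n)
  if (sum(counts) > n)
    igems_validation_error("igems_bad_parameter", "infeasible class fractions")
  class_of <- rep("null", n)
  assign_idx <- sample.int(n, sum(counts))
  class_of[assign_idx] <- rep(names(counts), counts)

  ps_sizes <- seq.int(config$probesets_range[1], config$probesets_range[2])
  n_ps <- ps_sizes[sample.int(length(ps_sizes), n, replace = TRUE)]
  gene_ids <- sprintf("g%04d", seq_len(n))
  mu <- stats::rnorm(n, config$gene_level_mean, config$gene_level_sd)

  rnoise <- function(len) {
    if (is.finite(config$noise_df)) {
      df <- config$noise_df
      config$noise_sd * stats::rt(len, df) / sqrt(df / (df - 2))
    } else {
      stats::rnorm(len, 0, config$noise_sd)
    }
  }

  expr_list <- vector("list", n)
  ann_list <- vector("list", n)
  exon_truth <- vector("list", n)
  for (g in seq_len(n)) {
    m <- n_ps[g]
    cls <- class_of[g]
    np <- m * ppp
    a <- stats::rnorm(np, 0, config$affinity_sd)
    ps_of_probe <- rep(seq_len(m), each = ppp)
    tau <- if (cls %in% c("rxrg_artifact", "gene_DE_only")) config$effect_size else 0
    delta_ps <- rep(0, m)
    target_ps <- NA_integer_
    artifact_ps <- integer(0)
    if (cls == "cassette_up" || cls == "cassette_down") {
      internal <- seq(2L, max(2L, m - 1L))  # safe for tiny genes
      target_ps <- internal[sample.int(length(internal), 1)]
      delta_ps[target_ps] <- if (cls == "cassette_up") config$effect_size else -config$effect_size
    } else if (cls == "utr3_extension") {
      target_ps <- m
      delta_ps[m] <- config$effect_size
    } else if (cls == "rxrg_artifact") {
      artifact_ps <- seq_len(ceiling(0.25 * m))
    }
    shift_b <- tau + delta_ps[ps_of_probe]          # per probe, group B only
    y <- outer(mu[g] + a, rep(0, 2 * n_grp), "+") +
      outer(shift_b, as.numeric(in_b)) +
      matrix(rnoise(np * 2 * n_grp), nrow = np)
    if (length(artifact_ps) > 0) {
      cl <- ps_of_probe %in% artifact_ps
      y[cl, ] <- config$background +
        matrix(rnoise(sum(cl) * 2 * n_grp), nrow = sum(cl))
    }
    dimnames(y) <- list(sprintf("%s_ps%02d_p%d", gene_ids[g],
                                ps_of_probe, rep(seq_len(ppp), m)),
                        samples)
    expr_list[[g]] <- y
    ann_list[[g]] <- data.frame(
      probe_id = rownames(y), gene_id = gene_ids[g],
      probeset_id = sprintf("%s_ps%02d", gene_ids[g], ps_of_probe),
      genomic_index = seq_len(np), stringsAsFactors = FALSE)
    exon_truth[[g]] <- data.frame(
      gene_id = gene_ids[g],
      probeset_id = sprintf("%s_ps%02d", gene_ids[g], seq_len(m)),
      rank_in_gene = seq_len(m),
      is_true_AEU = seq_len(m) %in% target_ps,
      is_artifact = seq_len(m) %in% artifact_ps,
      stringsAsFactors = FALSE)
  }

  expr <- do.call(rbind, expr_list)
  annotation <- do.call(rbind, ann_list)
  design <- data.frame(sample_id = samples,
                       group = ifelse(in_b, "B", "A"),
                       stringsAsFactors = FALSE)
  truth_genes <- data.frame(
    gene_id = gene_ids, class = class_of,
    is_true_aeu_gene = class_of %in% c("cassette_up", "cassette_down",
                                       "utr3_extension"),
    stringsAsFactors = FALSE)
  list(dataset = aeu_dataset(expr, annotation, design),
       truth = list(genes = truth_genes,
                    exons = do.call(rbind, exon_truth)))
}

#' Write a simulated dataset and its truth tables to a directory
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_dataset(sim$dataset, dir)
  paths$truth_genes <- file.path(dir, "truth_genes.tsv")
  paths$truth_exons <- file.path(dir, "truth_exons.tsv")
  utils::write.table(sim$truth$genes, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$exons, paths$truth_exons, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Score pipeline calls against simulation truth
#'
#' Gene-level and exon-level sensitivity, specificity and observed
#' false-discovery proportion.  `gene_DE_only` genes and `rxrg_artifact`
#' genes/exons count as negatives.  With zero calls the false-discovery
#' proportion is 0 by convention.  Also reports Step-3 diagnostics: how
#' many artifact exons reached Step 2 and what fraction of those were
#' removed, and how many true exons with expression above the gene median
#' in at least one group were removed.
#'
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param exons the final exon table (from [run_pipeline()] /
#'   [assemble_results()]); must cover the same gene and probe-set universe
#'   as the truth up to probe-sets dropped by the size filter.
#' @return Named list of metrics.
#' @export
evaluate_calls <- function(truth, exons) {
  if (!all(exons$gene_id %in% truth$genes$gene_id) ||
      !all(exons$probeset_id %in% truth$exons$probeset_id))
    igems_error("igems_universe_mismatch",
                "exon table refers to genes/probe-sets absent from the truth")
  te <- truth$exons[match(exons$probeset_id, truth$exons$probeset_id), ]
  tg <- truth$genes

  called_genes <- unique(exons$gene_id[exons$final_call])
  gene_called <- tg$gene_id %in% called_genes
  gene_true <- tg$is_true_aeu_gene
  gene_tp <- sum(gene_called & gene_true)
  gene_fp <- sum(gene_called & !gene_true)
  prop <- function(num, den) if (den > 0) num / den else 0

  exon_called <- exons$final_call
  exon_true <- te$is_true_AEU

  art_step2 <- te$is_artifact & exons$step2
  art_removed <- art_step2 & exons$step3_removed
  true_above <- exon_true & exons$step2 &
    (!exons$below_median_A | !exons$below_median_B)
  true_above_removed <- true_above & exons$step3_removed

  de_only_called <- sum(gene_called & tg$class == "gene_DE_only")

  list(
    gene_sensitivity = prop(gene_tp, sum(gene_true)),
    gene_specificity = prop(sum(!gene_called & !gene_true), sum(!gene_true)),
    gene_fdp = prop(gene_fp, sum(gene_called)),
    genes_called = sum(gene_called),
    exon_sensitivity = prop(sum(exon_called & exon_true), sum(exon_true)),
    exon_specificity = prop(sum(!exon_called & !exon_true), sum(!exon_true)),
    exon_fdp = prop(sum(exon_called & !exon_true), sum(exon_called)),
    artifact_exons_step2 = sum(art_step2),
    artifact_exons_removed = sum(art_removed),
    artifact_removal_rate = prop(sum(art_removed), sum(art_step2)),
    true_above_median_removed = sum(true_above_removed),
    de_only_genes_called = de_only_called,
    de_only_gene_rate = prop(de_only_called, sum(tg$class == "gene_DE_only"))
  )
}
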