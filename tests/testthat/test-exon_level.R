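test_that("probe-set summaries are per-set medians with a genomic-rank map", {
  ds <- toy_dataset(n_genes = 2, n_ps = 3, ppp = 3)
  ps <- probeset_summaries(ds)
  expect_identical(names(ps), c("summaries", "map"))
  expect_identical(names(ps$map), c("probeset_id", "gene_id", "rank_in_gene",
                                    "n_probes"))
  expect_identical(rownames(ps$summaries), ps$map$probeset_id)
  expect_identical(ps$map$rank_in_gene, rep(1:3, 2))
  expect_identical(ps$map$n_probes, rep(3L, 6))
  rows <- ds$annotation$probeset_id == "g01_ps02"
  expect_equal(unname(ps$summaries["g01_ps02", ]),
               unname(apply(ds$expr[rows, ], 2, stats::median)))
})

test_that("gene summaries reproduce the additive model's gene track", {
  ds <- toy_dataset()
  fits <- fit_all_genes(ds)
  gs <- gene_summaries(fits)
  expect_identical(dim(gs), c(3L, 8L))
  expect_equal(unname(gs["g02", ]),
               unname(fits$g02$overall + fits$g02$sample_effects))
})

test_that("the splicing index matches a hand-computed example and flips sign", {
  groups <- make_groups(2, 2)
  # one gene, gene-level values all zero, one exon shifted by +1 in group A
  sums <- rbind(g1_e1 = c(1, 1, 0, 0), g1_e2 = c(0, 0, 0, 0))
  colnames(sums) <- names(groups)
  map <- data.frame(probeset_id = rownames(sums), gene_id = "g1",
                    rank_in_gene = 1:2, n_probes = 3L,
                    stringsAsFactors = FALSE)
  gene_sum <- matrix(0, 1, 4, dimnames = list("g1", names(groups)))
  si <- splicing_index(list(summaries = sums, map = map), gene_sum, groups)
  expect_equal(unname(si), c(1, 0))
  swapped <- stats::setNames(ifelse(groups == "A", "B", "A"), names(groups))
  expect_equal(splicing_index(list(summaries = sums, map = map),
                              gene_sum, swapped),
               -si)
  only_a <- stats::setNames(rep("A", 4), names(groups))
  expect_error(splicing_index(list(summaries = sums, map = map),
                              gene_sum, only_a),
               class = "igems_small_group")
})

test_that("SI thresholds are the interpolated tail quantiles", {
  si <- as.numeric(1:20)
  thr <- si_thresholds(si, q = 0.10)
  expect_equal(unname(thr),
               unname(stats::quantile(si, c(0.1, 0.9), type = 7)))
  expect_identical(names(thr), c("lower", "upper"))
  expect_error(si_thresholds(si, q = 0.5), class = "igems_bad_parameter")
  expect_error(si_thresholds(si, q = 0), class = "igems_bad_parameter")
  expect_error(si_thresholds(si[1:5]), class = "igems_bad_parameter")
})

test_that("step 2 flags tails inclusively and a collapsed distribution flags nothing", {
  si <- c(a = -2, b = -1, c = 0, d = 1, e = 2)
  flags <- step2_select(si, c(lower = -1, upper = 1))
  expect_identical(unname(flags), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(unname(step2_select(si, c(lower = 0, upper = 0))),
                   rep(FALSE, 5))
  # about 2q of a continuous sample lands in its own tails
  set.seed(31)
  big <- stats::rnorm(5000)
  frac <- mean(step2_select(big, si_thresholds(big, 0.10)))
  expect_gt(frac, 0.18); expect_lt(frac, 0.22)
})

test_that("ordinary-t fallback matches the textbook pooled t on [1,2,3] vs [2,3,4]", {
  x <- rbind(ps1 = c(1, 2, 3, 2, 3, 4))
  colnames(x) <- names(make_groups(3, 3))
  res <- moderated_t_test(x, make_groups(3, 3))
  expect_identical(res$method, "ordinary")
  expect_equal(abs(res$t), sqrt(1.5), tolerance = 1e-12)   # |t| = 1.2247...
  expect_identical(res$df, 4)
  expect_equal(res$p, 2 * stats::pt(-sqrt(1.5), 4), tolerance = 1e-12)
  expect_equal(res$effect, -1)
})

test_that("a zero-variance zero-effect probe-set gets t = 0, p = 1", {
  x <- rbind(flat = rep(5, 6))
  colnames(x) <- names(make_groups(3, 3))
  res <- moderated_t_test(x, make_groups(3, 3))
  expect_identical(res$t, 0)
  expect_identical(res$p, 1)
  one_a <- stats::setNames(c("A", rep("B", 5)), colnames(x))
  expect_error(moderated_t_test(x, one_a),
               class = "igems_small_group")
})

test_that("with enough probe-sets the moderated test shrinks variances", {
  set.seed(32)
  x <- matrix(stats::rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("ps%02d", 1:30), names(make_groups(4, 4))))
  x[1, 5:8] <- x[1, 5:8] + 3
  res <- moderated_t_test(x, make_groups(4, 4))
  expect_identical(unique(res$method), "eBayes")
  expect_true(all(res$df > 6))          # prior df added to the residual df
  expect_lt(res$p[1], 0.01)
  expect_equal(res$fdr, brute_bh(res$p))
  expect_lt(res$effect[1], 0)           # effect is mean A - mean B
})

test_that("gene group medians summarize probe-level values per condition", {
  ds <- toy_dataset(n_genes = 2)
  gm <- gene_group_medians(ds)
  expect_identical(colnames(gm), c("A", "B"))
  rows <- ds$annotation$gene_id == "g02"
  sa <- names(ds$groups)[ds$groups == "A"]
  expect_equal(gm["g02", "A"], stats::median(ds$expr[rows, sa]))
})

test_that("step 3 removes only below-median, non-DE-context flagged exons", {
  exons <- data.frame(
    gene_id = rep("g1", 4), probeset_id = paste0("e", 1:4),
    rank_in_gene = 1:4,
    mean_A = c(1, 1, 9, 1), mean_B = c(1, 1, 9, 8),
    step2 = c(TRUE, TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  gm <- matrix(c(5, 5), 1, 2, dimnames = list("g1", c("A", "B")))
  de <- data.frame(probeset_id = paste0("e", 1:4),
                   fdr = c(0.5, 0.001, 0.5, 0.5), stringsAsFactors = FALSE)
  out <- step3_filter(exons, gm, de, de_alpha = 0.01)
  # e1: below both medians, is first exon -> its own fdr 0.5 (not DE) -> removed
  # e2: below both, predecessor e1 fdr 0.5 (not DE) -> removed
  # e3: above both medians -> kept
  # e4: below in A only -> kept
  expect_identical(out$step3_removed, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$below_median_A, c(TRUE, TRUE, FALSE, TRUE))
  # a DE predecessor rescues the exon
  de2 <- de; de2$fdr[1] <- 0.001
  out2 <- step3_filter(exons, gm, de2, de_alpha = 0.01)
  expect_false(out2$step3_removed[2])
  # unflagged exons are never removed
  exons3 <- exons; exons3$step2 <- FALSE
  out3 <- step3_filter(exons3, gm, de, de_alpha = 0.01)
  expect_false(any(out3$step3_removed))
  expect_error(step3_filter(exons, gm, de, de_alpha = 0),
               class = "igems_bad_parameter")
})

test_that("assembled results keep the funnel monotone and final calls consistent", {
  gs <- data.frame(gene_id = c("g1", "g2"), n_probes = 8L, muf = c(3, 1),
                   muf_fdr = c(0.001, 0.4), muf_fdr_bh = c(0.002, 0.4),
                   step1 = c(TRUE, FALSE), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2"), probeset_id = c("e1", "e2", "e3"),
    rank_in_gene = c(1L, 2L, 1L), step2 = c(TRUE, FALSE, TRUE),
    step3_removed = c(FALSE, FALSE, FALSE), stringsAsFactors = FALSE)
  res <- assemble_results(gs, exons)
  expect_identical(res$exons$final_call, c(TRUE, FALSE, FALSE))
  expect_identical(res$genes$final, c(TRUE, FALSE))
  f <- res$funnel
  expect_true(f[["step1"]] >= f[["step2"]])
  expect_true(f[["step2"]] >= f[["final"]])
  expect_identical(f[["exons_final"]], 1L)
})
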