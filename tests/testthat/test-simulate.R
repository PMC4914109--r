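test_that("sim_config validates fractions, sizes and noise", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(fractions = c(bogus = 0.1)),
               class = "igems_bad_parameter")
  expect_error(sim_config(fractions = c(cassette_up = 0.7,
                                        gene_DE_only = 0.5)),
               class = "igems_bad_parameter")
  expect_error(sim_config(fractions = c(cassette_up = -0.1)),
               class = "igems_bad_parameter")
  expect_error(sim_config(noise_sd = 0), class = "igems_bad_parameter")
  expect_error(sim_config(effect_size = -1), class = "igems_bad_parameter")
  expect_error(sim_config(probesets_range = c(1, 4)),
               class = "igems_bad_parameter")
  expect_error(sim_config(probesets_range = c(6, 4)),
               class = "igems_bad_parameter")
  expect_error(sim_config(n_per_group = 1), class = "igems_bad_parameter")
})

test_that("class counts are deterministic and truth tables agree", {
  cfg <- sim_config(n_genes = 50, seed = 3,
                    fractions = c(cassette_up = 0.10, cassette_down = 0.10,
                                  utr3_extension = 0.10,
                                  rxrg_artifact = 0.10, gene_DE_only = 0.10))
  sim <- simulate_dataset(cfg)
  tab <- table(sim$truth$genes$class)
  for (cls in c("cassette_up", "cassette_down", "utr3_extension",
                "rxrg_artifact", "gene_DE_only"))
    expect_identical(unname(tab[cls]), 5L)
  expect_identical(unname(tab["null"]), 25L)
  # each true-AEU gene carries exactly one true exon; others none
  ex <- sim$truth$exons
  per_gene <- tapply(ex$is_true_AEU, ex$gene_id, sum)
  tg <- sim$truth$genes
  expect_true(all(per_gene[tg$gene_id[tg$is_true_aeu_gene]] == 1))
  expect_true(all(per_gene[tg$gene_id[!tg$is_true_aeu_gene]] == 0))
  # artifact exons only appear in rxrg genes, as the first 25% of probe-sets
  art_genes <- unique(ex$gene_id[ex$is_artifact])
  expect_setequal(art_genes, tg$gene_id[tg$class == "rxrg_artifact"])
  for (g in art_genes) {
    rk <- ex$rank_in_gene[ex$gene_id == g & ex$is_artifact]
    expect_identical(rk, seq_len(ceiling(0.25 * max(ex$rank_in_gene[ex$gene_id == g]))))
  }
})

test_that("a degenerate probe-set range yields genes of exactly that size", {
  sim <- simulate_dataset(sim_config(n_genes = 20, probesets_range = c(8, 8),
                                     seed = 2))
  per_gene <- table(unique(sim$truth$exons[c("gene_id", "probeset_id")])$gene_id)
  expect_true(all(per_gene == 8))
  sizes <- table(sim$dataset$annotation$gene_id)
  expect_true(all(sizes == 8 * 4))
})

test_that("simulation is reproducible from its seed alone", {
  cfg <- sim_config(n_genes = 30, seed = 9,
                    fractions = c(cassette_up = 0.2))
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$expr, s2$dataset$expr)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(sim_config(n_genes = 30, seed = 10,
                                    fractions = c(cassette_up = 0.2)))
  expect_false(identical(s1$dataset$expr, s3$dataset$expr))
})

test_that("event classes shape the expression in the stated direction", {
  cfg <- sim_config(n_genes = 40, seed = 5, noise_sd = 0.05, effect_size = 2,
                    fractions = c(cassette_up = 0.25, rxrg_artifact = 0.25,
                                  gene_DE_only = 0.25))
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  tg <- sim$truth$genes
  ex <- sim$truth$exons
  b <- names(ds$groups)[ds$groups == "B"]
  a <- names(ds$groups)[ds$groups == "A"]
  # cassette_up: the true exon's probes sit ~effect_size higher in B
  g_up <- tg$gene_id[tg$class == "cassette_up"][1]
  ps_up <- ex$probeset_id[ex$gene_id == g_up & ex$is_true_AEU]
  rows <- ds$annotation$probeset_id == ps_up
  expect_equal(mean(ds$expr[rows, b]) - mean(ds$expr[rows, a]), 2,
               tolerance = 0.15)
  # other exons of the same gene are not shifted
  rows0 <- ds$annotation$gene_id == g_up & ds$annotation$probeset_id != ps_up
  expect_equal(mean(ds$expr[rows0, b]) - mean(ds$expr[rows0, a]), 0,
               tolerance = 0.15)
  # rxrg: artifact probe-sets are clamped to background in BOTH groups,
  # the remainder of the gene is shifted in B
  g_art <- tg$gene_id[tg$class == "rxrg_artifact"][1]
  ps_art <- ex$probeset_id[ex$gene_id == g_art & ex$is_artifact]
  ra <- ds$annotation$probeset_id %in% ps_art
  expect_equal(mean(ds$expr[ra, ]), cfg$background, tolerance = 0.15)
  expect_equal(mean(ds$expr[ra, b]) - mean(ds$expr[ra, a]), 0,
               tolerance = 0.15)
  rb <- ds$annotation$gene_id == g_art & !ds$annotation$probeset_id %in% ps_art
  expect_equal(mean(ds$expr[rb, b]) - mean(ds$expr[rb, a]), 2,
               tolerance = 0.15)
  # gene_DE_only: every probe-set shifted equally
  g_de <- tg$gene_id[tg$class == "gene_DE_only"][1]
  rd <- ds$annotation$gene_id == g_de
  shift_by_ps <- tapply(seq_len(nrow(ds$expr))[rd],
                        ds$annotation$probeset_id[rd], function(i)
                          mean(ds$expr[i, b]) - mean(ds$expr[i, a]))
  expect_true(all(abs(shift_by_ps - 2) < 0.3))
})

test_that("simulations survive a write round trip", {
  sim <- simulate_dataset(sim_config(n_genes = 5, seed = 1))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  back <- load_dataset(paths$expr, paths$annot, paths$design)
  expect_equal(back$expr, sim$dataset$expr)
  tg <- utils::read.delim(paths$truth_genes, stringsAsFactors = FALSE)
  expect_identical(tg$gene_id, sim$truth$genes$gene_id)
  expect_identical(tg$class, sim$truth$genes$class)
})

test_that("evaluate_calls computes the toy confusion metrics by hand", {
  truth <- list(
    genes = data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                       class = c("cassette_up", "null", "gene_DE_only",
                                 "rxrg_artifact"),
                       is_true_aeu_gene = c(TRUE, FALSE, FALSE, FALSE),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("g1", "g1", "g2", "g3", "g4"),
                       probeset_id = paste0("e", 1:5),
                       rank_in_gene = c(1L, 2L, 1L, 1L, 1L),
                       is_true_AEU = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                       is_artifact = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                       stringsAsFactors = FALSE))
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g4"),
    probeset_id = paste0("e", 1:5),
    step2 = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    step3_removed = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    below_median_A = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    below_median_B = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    final_call = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  m <- evaluate_calls(truth, exons)
  expect_equal(m$gene_sensitivity, 1)           # g1 called
  expect_equal(m$gene_fdp, 0.5)                 # g2 is a false call
  expect_equal(m$gene_specificity, 2 / 3)       # g3, g4 clean of 3 negatives
  expect_equal(m$exon_sensitivity, 1)
  expect_equal(m$exon_fdp, 0.5)
  expect_identical(m$artifact_exons_step2, 1L)
  expect_equal(m$artifact_removal_rate, 1)
  expect_identical(m$true_above_median_removed, 0L)
  expect_identical(m$de_only_genes_called, 0L)
  # zero calls: FDP is 0 by convention, not NaN
  none <- exons; none$final_call <- FALSE
  m0 <- evaluate_calls(truth, none)
  expect_equal(m0$gene_fdp, 0)
  expect_equal(m0$exon_fdp, 0)
  # foreign probe-sets are a hard error
  bad <- exons; bad$probeset_id[1] <- "ghost"
  expect_error(evaluate_calls(truth, bad), class = "igems_universe_mismatch")
})
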