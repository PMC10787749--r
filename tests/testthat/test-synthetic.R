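test_that("cohort generation is deterministic and honors the empty case", {
  a <- generate_cohort(50, seed = 11)
  b <- generate_cohort(50, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(50, seed = 12)))

  empty <- generate_cohort(0, seed = 1)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("sample_id", "ses", "sex", "race", "age", "pregnancy",
                    "plate", "batch", "bmi", "waist", "perceived_stress",
                    "smoking", "alcohol", "financial_stress", "insurance",
                    "fasting_hours") %in% colnames(empty)))
  expect_error(generate_cohort(-1), "nonnegative")
})

test_that("cohort marginals match the configured copula", {
  cfg <- cohort_config(ses_bmi_corr = -0.3)
  tab <- generate_cohort(2000, cfg, seed = 1)
  expect_lt(abs(mean(tab$ses)), 0.1)            # standardized composite
  expect_lt(abs(cor(tab$ses, tab$bmi) - (-0.3)), 0.06)
  expect_identical(nlevels(tab$alcohol), 4L)
  expect_false(anyNA(tab))
})

test_that("network generator plants recoverable true edges", {
  de <- sprintf("g%04d", 51:100)                # no TFs among DE genes
  cfg <- network_config(de_genes = de, n_true_tfs = 5, targets_per_tf = 10,
                        true_grn_conf = 0.9, decoy_grn_range = c(0, 0.4),
                        decoy_ppi_range = c(0, 0.7),
                        n_decoy_grn = 500, n_decoy_ppi = 500)
  nets <- generate_networks(20, 200, cfg, seed = 3)
  planted <- nets$truth$planted_grn
  expect_identical(nrow(planted), 50L)
  expect_true(all(planted$confidence == 0.9))
  key <- paste(nets$grn$tf, nets$grn$target)
  expect_true(all(paste(planted$tf, planted$target) %in% key))

  ## decoys below 0.4: a strict 0.4 filter keeps exactly the planted edges
  surviving <- nets$grn[nets$grn$confidence > 0.4, ]
  expect_setequal(paste(surviving$tf, surviving$target),
                  paste(planted$tf, planted$target))
  expect_identical(generate_networks(20, 200, cfg, seed = 3)$grn, nets$grn)
})

test_that("network generator edge cases", {
  cfg0 <- network_config(n_true_tfs = 0, n_decoy_grn = 0, n_decoy_ppi = 0)
  nets <- generate_networks(1, 1, cfg0, seed = 1)
  expect_identical(nrow(nets$grn), 0L)          # empty GRN allowed
  expect_error(generate_networks(0, 10, network_config(n_true_tfs = 2)),
               "zero transcription factors")
  ## no self-loops, unique pairs, scores in range
  big <- generate_networks(10, 50, network_config(
    de_genes = sprintf("g%04d", 11:20), n_decoy_grn = 400,
    n_decoy_ppi = 400), seed = 2)
  expect_true(all(big$grn$tf != big$grn$target))
  expect_false(anyDuplicated(paste(big$grn$tf, big$grn$target)) > 0)
  expect_true(all(big$ppi$score >= 0 & big$ppi$score <= 1))
  key <- paste(pmin(big$ppi$protein_a, big$ppi$protein_b),
               pmax(big$ppi$protein_a, big$ppi$protein_b))
  expect_false(anyDuplicated(key) > 0)
})

test_that("ontology generator builds a 3-level annotated forest", {
  genes <- sprintf("g%04d", 1:200)
  ont <- generate_ontology(1, 2, genes, seed = 5)
  expect_identical(nrow(ont$nodes), 15L)        # 1 + 2 + 4 + 8
  expect_identical(max(ont$nodes$level), 3L)
  ## superset mode: children-union within parent annotation
  for (p in ont$nodes$id[ont$nodes$level < 3]) {
    kids <- ont$parent_edges$child[ont$parent_edges$parent == p]
    expect_true(all(unlist(ont$annotations[kids]) %in% ont$annotations[[p]]))
  }
  leaves <- ont$nodes$id[ont$nodes$level == 3]
  expect_true(all(lengths(ont$annotations[leaves]) >= 5))
  expect_identical(generate_ontology(1, 2, genes, seed = 5), ont)
  expect_error(generate_ontology(1, 2, genes[1:3],
                                 ontology_config(min_genes = 5)),
               "fewer genes")
  ## planted sets end up in the first leaves
  ont2 <- generate_ontology(1, 2, genes,
                            ontology_config(planted_leaf_sets =
                                              list(genes[1:10])), seed = 5)
  first_leaf <- ont2$nodes$id[ont2$nodes$level == 3][1]
  expect_true(all(genes[1:10] %in% ont2$annotations[[first_leaf]]))
})

test_that("count generator is deterministic and library factors scale means", {
  sam <- generate_cohort(4, seed = 2)
  genes <- sprintf("g%04d", 1:3000)
  truth <- ground_truth(genes)
  cfg1 <- counts_config(lib_factors = rep(1, 4), batch_effect_sd = 0,
                        sex_effect_sd = 0)
  cfg2 <- counts_config(lib_factors = c(2, 1, 1, 1), batch_effect_sd = 0,
                        sex_effect_sd = 0)
  c1 <- generate_counts(sam, truth, cfg1, seed = 8)
  c2 <- generate_counts(sam, truth, cfg2, seed = 8)
  expect_identical(generate_counts(sam, truth, cfg1, seed = 8), c1)
  ## doubling one sample's library factor doubles its expected column sum
  expect_lt(abs(colSums(c2)[1] / colSums(c1)[1] - 2), 0.1)
  expect_lt(abs(colSums(c2)[2] / colSums(c1)[2] - 1), 0.1)
  expect_true(all(c1 >= 0))
})

test_that("ground truth validates its invariants", {
  genes <- sprintf("g%04d", 1:10)
  expect_error(ground_truth(genes, de_genes = genes[1],
                            effect_sizes = c(g0001 = 0)),
               "nonzero effect")
  expect_error(ground_truth(genes, de_genes = genes[1],
                            effect_sizes = c(g0001 = 1),
                            mediated_fraction = c(g0001 = 1.2)),
               "\\[0, 1\\]")
})
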