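toy_network <- function() {
  list(
    grn = data.frame(
      tf = c("t1", "t2", "t3", "g1"),
      target = c("g1", "g1", "g2", "g2"),
      confidence = c(0.9, 0.4, 0.41, 0.5), stringsAsFactors = FALSE),
    ppi = data.frame(
      protein_a = c("g1", "g1"), protein_b = c("p1", "p2"),
      score = c(0.8, 0.7), stringsAsFactors = FALSE),
    tf_universe = c("t1", "g1"))
}

test_that("set derivation matches hand enumeration with strict thresholds", {
  net <- toy_network()
  de <- make_de_table(c("g1", "g2", "g3"), sig = c("g1", "g2"),
                      direction = c("up", "down"))
  sets <- derive_sets(de, net$grn, net$ppi, net$tf_universe)
  expect_setequal(sets$set_a, c("g1", "g2"))
  ## t2 at exactly 0.4 excluded (strict >), t3 at 0.41 and g1 at 0.5 included
  expect_setequal(sets$set_d, c("t1", "t3", "g1"))
  ## g1 is DE, in the TF universe, and a source with an above-threshold edge
  expect_identical(sets$set_b, "g1")
  ## p2 at exactly 0.7 excluded (strict >)
  expect_identical(sets$set_c, "p1")
  ## direction tags propagate from recruiting genes
  expect_identical(unname(sets$tags$d[["t1"]]), "up")    # recruits via g1
  expect_identical(unname(sets$tags$d[["t3"]]), "down")  # recruits via g2
  expect_identical(unname(sets$tags$d[["g1"]]), "down")
  expect_identical(unname(sets$tags$c[["p1"]]), "up")    # via DE TF g1 (up)
  tab <- as.data.frame(sets)
  expect_setequal(tab$set, c("A", "B", "C", "D"))
})

test_that("a TF recruited by both directions carries both tags", {
  grn <- data.frame(tf = c("t1", "t1"), target = c("g1", "g2"),
                    confidence = 0.9, stringsAsFactors = FALSE)
  ppi <- data.frame(protein_a = character(0), protein_b = character(0),
                    score = numeric(0))
  de <- make_de_table(c("g1", "g2"), sig = c("g1", "g2"),
                      direction = c("up", "down"))
  sets <- derive_sets(de, grn, ppi, tf_universe = "t1")
  expect_identical(unname(sets$tags$d[["t1"]]), "down|up")
})

test_that("empty DE input and threshold monotonicity behave correctly", {
  net <- toy_network()
  de_none <- make_de_table(c("g1", "g2", "g3"))
  sets0 <- derive_sets(de_none, net$grn, net$ppi, net$tf_universe)
  expect_identical(lengths(sets0[c("set_a", "set_b", "set_c", "set_d")]),
                   c(set_a = 0L, set_b = 0L, set_c = 0L, set_d = 0L))

  de <- make_de_table(c("g1", "g2", "g3"), sig = c("g1", "g2"))
  for (thr in c(0, 0.3, 0.45, 0.6, 0.95)) {
    lo <- derive_sets(de, net$grn, net$ppi, net$tf_universe,
                      tf_threshold = thr, ppi_threshold = thr)
    hi <- derive_sets(de, net$grn, net$ppi, net$tf_universe,
                      tf_threshold = min(thr + 0.2, 1),
                      ppi_threshold = min(thr + 0.2, 1))
    expect_true(all(hi$set_d %in% lo$set_d))
    expect_true(all(hi$set_c %in% lo$set_c))
  }
  ## removing all PPI edges empties Set C and nothing else
  no_ppi <- derive_sets(de, net$grn, net$ppi[0, ], net$tf_universe)
  full <- derive_sets(de, net$grn, net$ppi, net$tf_universe)
  expect_identical(no_ppi$set_c, character(0))
  expect_identical(no_ppi[c("set_a", "set_b", "set_d")],
                   full[c("set_a", "set_b", "set_d")])
  ## unknown targets are skipped with a warning
  grn2 <- rbind(net$grn, data.frame(tf = "t9", target = "unknown_gene",
                                    confidence = 0.9))
  expect_warning(derive_sets(de, grn2, net$ppi, net$tf_universe),
                 "outside the DE universe")
})

test_that("planted true regulators are recovered exactly as Set D", {
  genes <- sprintf("g%04d", 1:200)
  de_genes <- genes[51:100]                    # no TFs among DE genes
  cfg <- network_config(de_genes = de_genes, n_true_tfs = 5,
                        targets_per_tf = 10, true_grn_conf = 0.9,
                        decoy_grn_range = c(0, 0.4),
                        decoy_ppi_range = c(0, 0.7),
                        n_decoy_grn = 1000, n_decoy_ppi = 500)
  nets <- generate_networks(20, 200, cfg, seed = 17)
  de <- make_de_table(genes, sig = de_genes)
  sets <- suppressWarnings(
    derive_sets(de, nets$grn, nets$ppi, nets$tf_universe))
  expect_setequal(sets$set_d, nets$truth$true_tfs)
})

test_that("pathway contribution counts match a brute-force scan", {
  enr <- data.frame(pathway = c("P1", "P2", "P3"), stringsAsFactors = FALSE)
  enr$contributing_genes <- list(c("a", "b"), c("b", "c", "b"), c("b"))
  counts <- count_pathway_contributions(enr, c("a", "b", "c", "z"))
  expect_identical(counts, c(a = 1L, b = 3L, c = 1L, z = 0L))
  ## brute force over (molecule, pathway) pairs
  for (m in names(counts)) {
    want <- sum(vapply(enr$contributing_genes,
                       function(g) m %in% g, logical(1)))
    expect_identical(unname(counts[m]), as.integer(want))
  }
})

test_that("layer assignment follows the pathway-count bins", {
  counts <- c(hub = 11L, mid = 6L, few = 2L, single = 1L, deep = 25L)
  lm_ <- assign_layers(counts)
  got <- setNames(lm_$layer, lm_$molecule)
  expect_identical(got[c("hub", "mid", "few", "single", "deep")],
                   c(hub = 1L, mid = 2L, few = 3L, single = 4L, deep = 1L))
  ## bin boundaries: 10 -> 2, 5 -> 3
  expect_identical(assign_layers(c(x = 10L))$layer, 2L)
  expect_identical(assign_layers(c(x = 5L))$layer, 3L)
  expect_error(assign_layers(c(x = 0L)), "positive")
})
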