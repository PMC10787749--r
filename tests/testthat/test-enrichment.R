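tiny_ontology <- function() {
  list(P1 = sprintf("g%02d", 1:10), P2 = sprintf("g%02d", 6:15),
       P3 = sprintf("g%02d", 90:99))
}

test_that("ORA p-values equal closed-form hypergeometric values", {
  universe <- sprintf("g%02d", 1:99)
  ## complete draw of one pathway
  res <- ora(sprintf("g%02d", 1:10), universe, tiny_ontology())
  expect_equal(res$p_value[res$pathway == "P1"],
               hyper_tail_oracle(10, 10, 99, 10), tolerance = 1e-12)
  expect_identical(res$overlap[res$pathway == "P1"], 10L)
  ## disjoint query: one-sided p = 1
  expect_equal(res$p_value[res$pathway == "P3"], 1)
  expect_error(ora(c("g01", "nope"), universe, tiny_ontology()),
               "outside the universe.*nope")
})

test_that("ORA p is monotone nonincreasing in overlap at fixed margins", {
  universe <- sprintf("u%02d", 1:30)
  ont <- list(PW = universe[1:8])
  p_prev <- 1.01
  for (k in 0:8) {
    query <- c(universe[seq_len(k)], universe[9:(16 - k)])  # size 8 always
    p <- ora(query, universe, ont)$p_value
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
})

test_that("Cramer's V matches the direct chi-square formula", {
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(cramers_v(matrix(c(5, 5, 5, 5), 2)), 0)
  tab <- matrix(c(8, 3, 2, 7), 2)              # ((8,2),(3,7)) row-wise
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  expect_equal(cramers_v(tab), sqrt(chi2 / n), tolerance = 1e-12)
  expect_equal(cramers_v(t(tab)), cramers_v(tab))   # transposition invariant
  expect_error(cramers_v(matrix(0, 2, 2)), "positive")
})

test_that("parent pooling applies the most-significant-child rule", {
  ont <- list(parent_edges = data.frame(
    parent = c("root", "root", "mid"), child = c("mid", "leafB", "leafA"),
    stringsAsFactors = FALSE))
  res <- data.frame(pathway = c("leafA", "leafB"), overlap = c(3L, 2L),
                    query_size = 5L, pathway_size = c(10L, 8L),
                    universe_size = 100L, p_value = c(0.003, 0.20),
                    q_value = c(0.006, 0.20), cramers_v = c(0.4, 0.1),
                    contributing_genes = I(list(c("a", "b", "c"), c("d", "e"))),
                    stringsAsFactors = FALSE)
  pooled <- pool_to_parents(res, ont)
  root <- pooled[pooled$pathway == "root", ]
  expect_equal(root$p_value, 0.003)            # transitive via 3 levels
  expect_identical(root$source_child, "leafA")
  expect_setequal(root$contributing_genes[[1]], c("a", "b", "c", "d", "e"))
  mid <- pooled[pooled$pathway == "mid", ]
  expect_equal(mid$p_value, 0.003)
  expect_identical(mid$q_value, 0.006)         # q inherited from best child
  ## tested children retained; untested nodes with no tested descendants absent
  expect_true(all(c("leafA", "leafB") %in% pooled$pathway))
  expect_false("orphan" %in% pooled$pathway)
  ## pooled parent p never exceeds any tested descendant p
  expect_true(all(root$p_value <= res$p_value))
})

test_that("pooling over generated hierarchies equals brute-force minima", {
  genes <- sprintf("g%04d", 1:300)
  ont <- generate_ontology(2, 2, genes, seed = 31)
  leaves <- ont$nodes$id[ont$nodes$level == 3]
  p <- withr::with_seed(32, setNames(runif(length(leaves)), leaves))
  res <- data.frame(pathway = leaves, overlap = 1L, query_size = 10L,
                    pathway_size = 5L, universe_size = 300L,
                    p_value = unname(p), q_value = unname(p),
                    cramers_v = 0,
                    contributing_genes = I(as.list(leaves)),
                    stringsAsFactors = FALSE)
  pooled <- pool_to_parents(res, ont)
  ## brute force: descendants via repeated edge expansion
  kids_of <- split(ont$parent_edges$child, ont$parent_edges$parent)
  descend <- function(nd) {
    out <- character(0); frontier <- nd
    repeat {
      frontier <- unlist(kids_of[frontier], use.names = FALSE)
      if (length(frontier) == 0) break
      out <- c(out, frontier)
    }
    out
  }
  for (nd in ont$nodes$id[ont$nodes$level < 3]) {
    want <- min(p[intersect(descend(nd), leaves)])
    expect_equal(pooled$p_value[pooled$pathway == nd &
                                  pooled$node_type == "pooled"], want)
  }
  ## cycles are rejected
  bad <- list(parent_edges = data.frame(parent = c("a", "b"),
                                        child = c("b", "a")))
  expect_error(pool_to_parents(res[1, ], bad), "cycle")
})

test_that("combined enrichment splits contributions across lists", {
  universe <- sprintf("g%02d", 1:40)
  ont <- list(PW = universe[1:10])
  ## identical lists: symmetric halves
  res <- combined_enrichment(list(l1 = universe[1:6], l2 = universe[1:6]),
                             universe, ont)
  expect_equal(res$contrib_l1, 0.5)
  expect_equal(res$contrib_l2, 0.5)
  ## exclusive hit
  res2 <- combined_enrichment(list(l1 = universe[1:5], l2 = universe[20:24]),
                              universe, ont)
  expect_equal(res2$contrib_l1, 1)
  expect_equal(res2$contrib_l2, 0)
  ## 3 lists, one shared gene: hand-computed fractions
  ## pathway overlap = {g01 (in all 3), g02 (only l1)} -> l1: (1/3+1)/2,
  ## l2 and l3: (1/3)/2
  res3 <- combined_enrichment(
    list(l1 = c("g01", "g02"), l2 = c("g01", "g20"), l3 = c("g01", "g21")),
    universe, ont)
  expect_equal(res3$contrib_l1, (1 / 3 + 1) / 2, tolerance = 1e-12)
  expect_equal(res3$contrib_l2, (1 / 3) / 2, tolerance = 1e-12)
  expect_equal(res3$contrib_l3, (1 / 3) / 2, tolerance = 1e-12)
  expect_equal(res3$contrib_l1 + res3$contrib_l2 + res3$contrib_l3, 1)
  expect_error(combined_enrichment(list(a = character(0)), universe, ont),
               "empty")
})
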