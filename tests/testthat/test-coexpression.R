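test_that("soft power selection matches the degree-regression oracle", {
  blocks <- make_block_matrix(3, 20, 100, noise_sd = 0.5, seed = 13)
  p1 <- pick_soft_power(blocks$matrix, candidate_powers = c(2, 4, 6, 8))
  p2 <- pick_soft_power(blocks$matrix, candidate_powers = c(2, 4, 6, 8))
  expect_identical(as.numeric(p1), as.numeric(p2))     # deterministic
  expect_identical(as.numeric(pick_soft_power(blocks$matrix, 6)), 6)

  r <- abs(cor(t(blocks$matrix))); diag(r) <- 0
  fits <- attr(p1, "fits")
  for (pw in c(2, 4, 6, 8)) {
    expect_equal(unname(fits[as.character(pw)]),
                 unname(scale_free_fit_oracle(rowSums(r^pw))),
                 tolerance = 1e-10)
  }
  expect_error(pick_soft_power(blocks$matrix[1:5, ]), "10 genes")
  expect_error(pick_soft_power(blocks$matrix, c(2, 4)), "3 candidate")
})

test_that("planted blocks are recovered and labels are size-ordered", {
  skip_if_not_installed("mclust")
  blocks <- make_block_matrix(3, 50, 200, noise_sd = 0.3, seed = 1)
  ms <- detect_modules(blocks$matrix, power = 6, min_module_size = 20)
  ari <- mclust::adjustedRandIndex(ms$assignment, blocks$labels)
  expect_gt(ari, 0.8)
  sizes <- table(ms$assignment[ms$assignment > 0])
  expect_true(all(diff(as.integer(sizes)) <= 0) || length(sizes) == 1)
  ## gene-order invariance: permuting rows permutes labels only
  perm <- withr::with_seed(2, sample(nrow(blocks$matrix)))
  ms2 <- detect_modules(blocks$matrix[perm, ], power = 6,
                        min_module_size = 20)
  expect_equal(mclust::adjustedRandIndex(ms2$assignment[rownames(blocks$matrix)],
                                         ms$assignment), 1)
})

test_that("duplicated genes co-assign and noise yields no giant module", {
  blocks <- make_block_matrix(2, 30, 150, noise_sd = 0.4, seed = 3)
  x <- blocks$matrix
  x["g0031", ] <- x["g0001", ]                 # duplicate profile
  ms <- detect_modules(x, power = 6, min_module_size = 10)
  expect_identical(ms$assignment[["g0001"]], ms$assignment[["g0031"]])
  expect_error(detect_modules(x, 6, min_module_size = 1), "at least 2")

  noise <- withr::with_seed(4, matrix(rnorm(100 * 200), 100, 200,
                                      dimnames = list(sprintf("g%04d", 1:100),
                                                      NULL)))
  msn <- detect_modules(noise, power = 6, min_module_size = 10)
  biggest <- if (any(msn$assignment > 0))
    max(table(msn$assignment[msn$assignment > 0])) else 0
  expect_lt(biggest, 10)                       # < 10% of genes
})

test_that("eigengenes match an SVD oracle and the sign convention", {
  x <- withr::with_seed(5, matrix(rnorm(40), 5, 8,
                                  dimnames = list(sprintf("g%d", 1:5),
                                                  sprintf("s%d", 1:8))))
  e <- module_eigengene(x, rownames(x))
  xs <- t(scale(t(x)))
  v <- svd(xs)$v[, 1]; v <- v / sd(v)
  if (cor(v, colMeans(xs)) < 0) v <- -v
  expect_equal(unname(e), v, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sd(e), 1, tolerance = 1e-12)
  expect_gte(cor(e, colMeans(xs)), 0)

  ## identical members: eigengene is the standardized common profile
  common <- matrix(rep(x[1, ], 4), 4, 8, byrow = TRUE,
                   dimnames = list(sprintf("h%d", 1:4), colnames(x)))
  ec <- module_eigengene(common, rownames(common))
  expect_equal(abs(cor(ec, x[1, ])), 1, tolerance = 1e-10)
  expect_equal(attr(ec, "var_explained"), 1, tolerance = 1e-10)
  expect_error(module_eigengene(x, character(0)), "empty module")
})

test_that("eigengene-exposure association is calibrated and exact", {
  n <- 100
  sam <- generate_cohort(n, seed = 6)
  ## a perfect eigengene: p numerically zero
  eig <- cbind(ME1 = scale(sam$ses)[, 1],
               ME2 = withr::with_seed(7, rnorm(n)))
  rownames(eig) <- sam$sample_id
  res <- module_ses_association(eig, sam, "ses")
  expect_lt(res$p_value[res$module == "ME1"], 1e-10)
  ## null calibration: independent eigengenes, fraction p<0.05 in [0.01, 0.10]
  null_eig <- withr::with_seed(8, matrix(rnorm(n * 200), n, 200,
                                         dimnames = list(sam$sample_id,
                                                         paste0("ME", 1:200))))
  null_res <- module_ses_association(null_eig, sam, "ses", c("sex", "age"))
  frac <- mean(null_res$p_value < 0.05)
  expect_gte(frac, 0.01); expect_lte(frac, 0.10)
})

test_that("module DE enrichment matches Fisher behavior on small tables", {
  genes <- sprintf("g%02d", 1:20)
  assignment <- setNames(rep(c(1L, 2L), each = 10), genes)
  ## balanced table: OR 1, p > 0.5
  de <- make_de_table(genes, sig = genes[c(1:5, 11:15)], direction = "up")
  res <- module_deg_enrichment(assignment, de, directions = "up")
  expect_equal(res$odds_ratio[res$module == 1], 1, tolerance = 1e-8)
  expect_gt(res$p_value[res$module == 1], 0.5)
  ## no DE genes in the requested direction: p = 1 everywhere
  res_dn <- module_deg_enrichment(assignment, de, directions = "down")
  expect_true(all(res_dn$p_value == 1))
  ## oracle agreement on an unbalanced configuration
  de2 <- make_de_table(genes, sig = genes[1:8], direction = "up")
  res2 <- module_deg_enrichment(assignment, de2, directions = "up")
  expect_equal(res2$p_value[res2$module == 1],
               fisher_greater_oracle(8, 2, 0, 10), tolerance = 1e-10)
  expect_error(module_deg_enrichment(assignment[1:10], de), "universes differ")
})
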