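#' Draw random gene sets matched in size to an observed set
#'
#' Uniform without-replacement samples from the gene universe, one per
#' replicate, each seeded from the master seed by a counter-based schedule
#' (so individual replicates can be reproduced).
#'
#' @param universe Gene identifiers to draw from.
#' @param size Genes per replicate (<= length of universe).
#' @param n_replicates Number of replicates (default 1000).
#' @param seed Master seed.
#' @return List of character vectors.
#' @export
random_gene_sets <- function(universe, size, n_replicates = 1000, seed = 1L) {
  if (size > length(universe))
    stop("`size` exceeds the universe size")
  seeds <- derive_seeds(seed, n_replicates)
  lapply(seeds, function(s) withr::with_seed(s, sample(universe, size)))
}

#' Derive regulator sets for each null replicate
#'
#' Applies the same Set B/C/D derivation used for the observed DE genes to
#' every random replicate (identical networks and thresholds).
#'
#' @param replicates List of gene sets (each playing the role of Set A).
#' @param grn,ppi,tf_universe,tf_threshold,ppi_threshold As in
#'   [derive_sets()].
#' @return List of `regulator_sets`, one per replicate.
#' @export
derive_null_sets <- function(replicates, grn, ppi, tf_universe,
                             tf_threshold = 0.4, ppi_threshold = 0.7) {
  ## prefilter once; derive_sets_core re-filters but on the reduced tables
  strong_grn <- grn[grn$confidence > tf_threshold, , drop = FALSE]
  strong_ppi <- ppi[ppi$score > ppi_threshold, , drop = FALSE]
  lapply(replicates, function(genes)
    derive_sets_core(genes, NULL, strong_grn, strong_ppi, tf_universe,
                     tf_threshold, ppi_threshold))
}

#' Per-gene empirical p-values against null-derived sets
#'
#' For each gene in an observed set S, counts the replicates whose derived
#' S contains the gene and reports the add-one smoothed empirical p-value
#' `(appearances + 1) / (n_replicates + 1)`. A small p means the molecule
#' is rarely recruited by chance (specific to the observed DE signal).
#'
#' @param observed A `regulator_sets` object from [derive_sets()].
#' @param null_sets List of `regulator_sets` from [derive_null_sets()].
#' @return data.frame with `molecule`, `set`, `appearances`, `empirical_p`.
#' @export
empirical_pvalues <- function(observed, null_sets) {
  n_rep <- length(null_sets)
  if (n_rep < 1L) stop("at least one null replicate is required")
  lab <- c(a = "A", b = "B", c = "C", d = "D")
  rows <- lapply(names(lab), function(s) {
    genes <- observed[[paste0("set_", s)]]
    if (length(genes) == 0L) return(NULL)
    pool <- unlist(lapply(null_sets, function(r)
      unique(r[[paste0("set_", s)]])))
    tab <- table(pool)
    app <- as.integer(tab[match(genes, names(tab))])
    app[is.na(app)] <- 0L
    data.frame(molecule = genes, set = lab[[s]], appearances = app,
               empirical_p = (app + 1) / (n_rep + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(molecule = character(0), set = character(0),
                      appearances = integer(0), empirical_p = numeric(0))
  rownames(out) <- NULL
  out
}

#' Fisher's method for combining p-values
#'
#' `statistic = -2 * sum(log(p))`, chi-square with `2k` degrees of freedom.
#'
#' @param p_values p-values in (0, 1\].
#' @return List: `statistic`, `df`, `p_value`.
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0L) stop("no p-values to combine")
  if (any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Randomization test of the observed regulator sets
#'
#' Draws `n_replicates` random gene sets equal in size to the observed Set
#' A, derives Sets B/C/D from each with the same networks and thresholds,
#' computes per-gene empirical p-values and combines them per set with
#' Fisher's method.
#'
#' @param observed A `regulator_sets` from [derive_sets()].
#' @param universe Gene universe to sample from (typically all tested
#'   genes).
#' @param grn,ppi,tf_universe As in [derive_sets()]; thresholds are taken
#'   from `observed`.
#' @param n_replicates Number of random sets (default 1000).
#' @param seed Master seed.
#' @return List: `per_gene` (data.frame from [empirical_pvalues()]),
#'   `per_set` (data.frame `set`, `fisher_statistic`, `df`, `combined_p`,
#'   `n_genes`), `n_replicates`, `seed`.
#' @export
randomization_test <- function(observed, universe, grn, ppi, tf_universe,
                               n_replicates = 1000, seed = 1L) {
  reps <- random_gene_sets(universe, length(observed$set_a), n_replicates,
                           seed)
  null_sets <- derive_null_sets(reps, grn, ppi, tf_universe,
                                observed$tf_threshold,
                                observed$ppi_threshold)
  per_gene <- empirical_pvalues(observed, null_sets)
  per_set <- do.call(rbind, lapply(unique(per_gene$set), function(s) {
    p <- per_gene$empirical_p[per_gene$set == s]
    fc <- fisher_combine(p)
    data.frame(set = s, fisher_statistic = fc$statistic, df = fc$df,
               combined_p = fc$p_value, n_genes = length(p),
               stringsAsFactors = FALSE)
  }))
  list(per_gene = per_gene, per_set = per_set,
       n_replicates = n_replicates, seed = as.integer(seed))
}
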