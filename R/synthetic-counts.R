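#' Settings for the negative-binomial count generator
#'
#' Counts follow the standard RNA-seq noise model: gene `g` in sample `i` is
#' negative binomial with
#' `log2 mean = baseline_g + effect_g * ((1 - f_g) * ses_i + f_g * bmi_path_i)
#'  + batch and covariate offsets`, scaled by a per-sample library factor.
#' `f_g` is the gene's planted mediated fraction and `bmi_path` is the
#' standardized BMI divided by the structural SES->BMI coefficient, so the
#' expected expression change per SD of SES equals `effect_g` in total, of
#' which the fraction `f_g` travels through BMI (closed-form mediation truth
#' `ACME/total = f_g`).
#'
#' @param baseline_mean,baseline_sd Log2 baseline abundance distribution.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   per-gene NB dispersion (1/size).
#' @param lib_size_sdlog Log-normal sd of per-sample library scale factors.
#' @param lib_factors Optional explicit per-sample library scale factors
#'   (overrides `lib_size_sdlog`).
#' @param batch_effect_sd SD of per-(gene, batch) log2 offsets.
#' @param sex_effect_sd SD of per-gene log2 offsets applied to male samples.
#' @param module_loading_range Range of per-gene log2 loadings on the
#'   latent factor of the gene's planted co-expression module. The default
#'   yields within-module correlations around 0.7-0.85 on the log-CPM
#'   scale, emulating a tight co-expression cluster.
#' @return A named list of class `counts_config`.
#' @export
counts_config <- function(baseline_mean = 5, baseline_sd = 1.5,
                          dispersion_meanlog = log(0.1),
                          dispersion_sdlog = 0.5,
                          lib_size_sdlog = 0.15,
                          lib_factors = NULL,
                          batch_effect_sd = 0.2,
                          sex_effect_sd = 0.1,
                          module_loading_range = c(0.8, 1.4)) {
  structure(as.list(environment()), class = "counts_config")
}

#' Assemble a ground-truth object for the count generator
#'
#' @param genes All gene identifiers.
#' @param de_genes Genes with a true SES effect.
#' @param effect_sizes Named signed log2 fold change per SD of SES for
#'   `de_genes` (nonzero).
#' @param mediated_fraction Named fraction in \[0,1\] of each DE gene's SES
#'   effect routed through BMI; genes absent default to 0.
#' @param module_assignment Optional named integer module labels for a subset
#'   of genes (planted co-expression blocks).
#' @param true_tfs Planted modulating TF identifiers.
#' @param pathway_truth Optional named list pathway id -> gene set.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(genes, de_genes = character(0),
                         effect_sizes = numeric(0),
                         mediated_fraction = numeric(0),
                         module_assignment = integer(0),
                         true_tfs = character(0),
                         pathway_truth = list()) {
  stopifnot(all(de_genes %in% genes),
            all(names(effect_sizes) %in% genes),
            all(de_genes %in% names(effect_sizes)))
  if (any(effect_sizes[de_genes] == 0))
    stop("every DE gene must have a nonzero effect size")
  if (length(mediated_fraction) &&
      (any(mediated_fraction < 0) || any(mediated_fraction > 1)))
    stop("`mediated_fraction` must lie in [0, 1]")
  structure(list(genes = genes, de_genes = de_genes,
                 effect_sizes = effect_sizes,
                 mediated_fraction = mediated_fraction,
                 module_assignment = module_assignment,
                 true_tfs = true_tfs, pathway_truth = pathway_truth),
            class = "ground_truth")
}

#' Generate a negative-binomial count matrix with planted SES effects
#'
#' @param samples A cohort table from [generate_cohort()] (needs columns
#'   `ses`, `bmi`, `sex`, `batch` and attribute `ses_bmi_corr` unless
#'   overridden via `ses_bmi_corr`).
#' @param truth A [ground_truth()] object fixing gene ids, effects,
#'   mediated fractions and module structure.
#' @param config A [counts_config()].
#' @param seed Integer seed.
#' @param ses_bmi_corr Structural SES->BMI coefficient; defaults to the
#'   attribute carried by `samples`.
#' @return Integer matrix (genes x samples) with dimnames.
#' @export
generate_counts <- function(samples, truth, config = counts_config(),
                            seed = 1L, ses_bmi_corr = NULL) {
  cfg <- config
  genes <- truth$genes
  n_g <- length(genes)
  n_s <- nrow(samples)
  a <- ses_bmi_corr %||% attr(samples, "ses_bmi_corr")

  eff <- setNames(numeric(n_g), genes)
  eff[names(truth$effect_sizes)] <- truth$effect_sizes
  medfrac <- setNames(numeric(n_g), genes)
  if (length(truth$mediated_fraction))
    medfrac[names(truth$mediated_fraction)] <- truth$mediated_fraction
  if (any(medfrac > 0) && (is.null(a) || a == 0))
    stop("mediated fractions require a nonzero SES->BMI coefficient")

  withr::with_seed(as.integer(seed), {
    baseline <- rnorm(n_g, cfg$baseline_mean, cfg$baseline_sd)
    dispersion <- rlnorm(n_g, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
    if (any(dispersion <= 0)) stop("dispersion must be positive")
    lib <- cfg$lib_factors %||% rlnorm(n_s, 0, cfg$lib_size_sdlog)
    if (length(lib) != n_s) stop("`lib_factors` must match the sample count")

    ses <- samples$ses
    if (n_s > 0 && any(medfrac > 0)) {
      bmi_z <- (samples$bmi - mean(samples$bmi)) / sd(samples$bmi)
      bmi_path <- bmi_z / a
    } else bmi_path <- rep(0, n_s)

    exposure_term <- outer(eff * (1 - medfrac), ses) +
      outer(eff * medfrac, bmi_path)

    logmu <- matrix(baseline, n_g, n_s) + exposure_term

    if (cfg$batch_effect_sd > 0 && n_s > 0) {
      batches <- factor(samples$batch)
      shift <- matrix(rnorm(n_g * nlevels(batches), 0, cfg$batch_effect_sd),
                      n_g, nlevels(batches))
      logmu <- logmu + shift[, as.integer(batches), drop = FALSE]
    }
    if (cfg$sex_effect_sd > 0 && n_s > 0) {
      sex_eff <- rnorm(n_g, 0, cfg$sex_effect_sd)
      logmu <- logmu + outer(sex_eff, as.numeric(samples$sex == "male"))
    }
    if (length(truth$module_assignment) && n_s > 0) {
      mods <- truth$module_assignment
      mods <- mods[names(mods) %in% genes & mods > 0]
      for (m in unique(mods)) {
        member <- names(mods)[mods == m]
        f_m <- rnorm(n_s)
        load <- runif(length(member), cfg$module_loading_range[1],
                      cfg$module_loading_range[2])
        logmu[member, ] <- logmu[member, , drop = FALSE] + outer(load, f_m)
      }
    }

    mu <- sweep(2^logmu, 2, lib, `*`)
    counts <- matrix(rnbinom(n_g * n_s, mu = mu, size = rep(1 / dispersion, n_s)),
                     n_g, n_s, dimnames = list(genes, samples$sample_id))
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Simulate a complete synthetic study with planted ground truth
#'
#' Convenience wrapper assembling cohort, ground truth, networks, ontology
#' and counts into one coherent study: DE genes with signed effects and
#' mediated fractions, planted co-expression modules, true modulating TFs
#' wired onto DE targets, DE TFs with protein partners, and DE genes planted
#' into the first ontology leaves.
#'
#' @param n_samples,n_genes,n_tfs Study dimensions.
#' @param n_de Number of DE genes (half up, half down).
#' @param effect_size Absolute log2 fold change per SD of SES for DE genes.
#' @param mediated_fraction Fraction of each DE gene's effect routed through
#'   BMI (scalar, applied to all DE genes).
#' @param n_modules,module_size Planted co-expression blocks.
#' @param n_de_tfs Number of DE genes drawn from the TF universe (Set B
#'   truth).
#' @param cohort,network,ontology,counts Config objects (defaults used when
#'   `NULL`); the network config's `de_genes` and the ontology's planted
#'   leaf sets are filled in automatically.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return List with `samples`, `counts`, `grn`, `ppi`, `tf_universe`,
#'   `ontology`, `truth`.
#' @export
simulate_study <- function(n_samples = 300, n_genes = 1000, n_tfs = 50,
                           n_de = 60, effect_size = 0.8,
                           mediated_fraction = 0.3,
                           n_modules = 3, module_size = 50,
                           n_de_tfs = 5,
                           cohort = NULL, network = NULL, ontology = NULL,
                           counts = NULL, seed = 1L) {
  seeds <- derive_seeds(seed, 6)
  genes <- gene_ids(n_genes)
  tfs <- genes[seq_len(n_tfs)]

  samples <- generate_cohort(n_samples, cohort %||% cohort_config(),
                             seed = seeds[1])

  de <- withr::with_seed(seeds[2], {
    de_tf <- sample(tfs, min(n_de_tfs, n_tfs, n_de))
    de_other <- sample(setdiff(genes[-seq_len(n_tfs)], de_tf),
                       n_de - length(de_tf))
    sort(c(de_tf, de_other))
  })
  signs <- rep(c(1, -1), length.out = length(de))
  eff <- setNames(signs * effect_size, de)
  medfrac <- setNames(rep(mediated_fraction, length(de)), de)

  mod_assign <- withr::with_seed(seeds[3], {
    pool <- setdiff(genes, de)
    member <- sample(pool, min(n_modules * module_size, length(pool)))
    setNames(rep(seq_len(n_modules), each = module_size,
                 length.out = length(member)), member)
  })

  truth <- ground_truth(genes, de_genes = de, effect_sizes = eff,
                        mediated_fraction = medfrac,
                        module_assignment = mod_assign)

  netcfg <- network %||% network_config(n_decoy_grn = 5 * n_genes,
                                        n_decoy_ppi = 5 * n_genes)
  netcfg$de_genes <- de
  nets <- generate_networks(n_tfs, n_genes, netcfg, seed = seeds[4])
  truth$true_tfs <- nets$truth$true_tfs

  ontcfg <- ontology %||% ontology_config()
  if (length(ontcfg$planted_leaf_sets) == 0) {
    up <- names(eff)[eff > 0]; down <- names(eff)[eff < 0]
    ontcfg$planted_leaf_sets <- list(up[seq_len(min(15, length(up)))],
                                     down[seq_len(min(15, length(down)))])
  }
  ont <- generate_ontology(max(1, n_genes %/% 500), 3, genes, ontcfg,
                           seed = seeds[5])
  truth$pathway_truth <- ont$annotations

  cm <- generate_counts(samples, truth, counts %||% counts_config(),
                        seed = seeds[6])

  list(samples = samples, counts = cm, grn = nets$grn, ppi = nets$ppi,
       tf_universe = nets$tf_universe, ontology = ont, truth = truth)
}
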