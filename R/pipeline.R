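#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `inputs` (paths to counts, metadata, grn, ppi, gmt,
#' hierarchy files) or `synthetic` (arguments for [simulate_study()]) must
#' be supplied.
#'
#' @param inputs Named list of input file paths: `counts`, `metadata`,
#'   `grn`, `ppi`, `gmt`, `hierarchy`, optionally `tf_universe` (one id per
#'   line; defaults to the regulatory network's source TFs).
#' @param synthetic Named list of [simulate_study()] arguments.
#' @param outdir Output directory for all artifacts.
#' @param alpha FDR threshold used throughout.
#' @param tf_threshold,ppi_threshold Regulatory / interaction score cutoffs.
#' @param layer_bin_edges Layer thresholds, see [assign_layers()].
#' @param exposure Exposure column name.
#' @param covariates Covariate columns for the linear models.
#' @param mediators Mediator columns; `NULL` skips the mediation stage.
#' @param filter `list(min_cpm, min_sample_frac)` low-count filter.
#' @param coexpression `list(candidate_powers, min_module_size,
#'   merge_height)`.
#' @param n_sim Monte-Carlo draws per mediation model.
#' @param n_replicates Randomization replicates.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, synthetic = NULL,
                            outdir = tempfile("sesnet_run_"),
                            alpha = 0.05, tf_threshold = 0.4,
                            ppi_threshold = 0.7,
                            layer_bin_edges = c(10, 5, 1),
                            exposure = "ses",
                            covariates = c("sex", "race", "age", "pregnancy",
                                           "plate", "fasting_hours",
                                           "anti_inflammatory_use",
                                           "recent_symptoms",
                                           "recent_illness"),
                            mediators = c("bmi", "waist", "perceived_stress",
                                          "smoking", "alcohol",
                                          "financial_stress", "insurance"),
                            filter = list(min_cpm = 0.5,
                                          min_sample_frac = 0.5),
                            coexpression = list(candidate_powers = c(1:10, 12, 14, 16),
                                                min_module_size = 20,
                                                merge_height = NULL),
                            n_sim = 1000, n_replicates = 1000, seed = 1L) {
  if (is.null(inputs) == is.null(synthetic))
    stop("supply exactly one of `inputs` or `synthetic`")
  assert_prob(alpha); assert_prob(tf_threshold); assert_prob(ppi_threshold)
  if (!is.null(inputs)) {
    need <- c("counts", "metadata", "grn", "ppi", "gmt", "hierarchy")
    missing <- setdiff(need, names(inputs))
    if (length(missing))
      stop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the [pipeline_config()] arguments.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  lst <- vapply(df, is.list, logical(1))
  for (j in which(lst))
    df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or generate inputs; low-count filter, TMM
#' normalization, log-CPM, batch adjustment; per-gene differential
#' expression for the exposure; co-expression modules with eigengene
#' association and DE enrichment; over-representation analysis of the DE
#' genes with parent-child pooling; upstream regulator sets; combined
#' enrichment of DE and regulator lists; pathway-contribution layers;
#' per-gene mediation with layer summaries (skipped when no mediators are
#' configured); and the set-level randomization test. All artifacts are
#' written to `config$outdir` as TSV/JSON together with a `manifest.json`
#' recording the configuration and output checksums; reruns with an
#' unchanged configuration are bit-identical.
#'
#' @param config A [pipeline_config()], or a YAML path understood by
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 4)
  out <- list()

  ## ---- load or generate -------------------------------------------------
  dat <- run_stage("load", {
    if (!is.null(cfg$synthetic)) {
      do.call(simulate_study, c(cfg$synthetic, list(seed = seeds[1])))
    } else {
      grn <- read_edge_list(cfg$inputs$grn, "grn")
      tf_universe <- if (!is.null(cfg$inputs$tf_universe))
        readLines(cfg$inputs$tf_universe) else sort(unique(grn$tf))
      list(counts = read_counts(cfg$inputs$counts),
           samples = read_metadata(cfg$inputs$metadata),
           grn = grn,
           ppi = read_edge_list(cfg$inputs$ppi, "ppi"),
           tf_universe = tf_universe,
           ontology = list(annotations = read_gmt(cfg$inputs$gmt),
                           parent_edges = read_hierarchy(cfg$inputs$hierarchy)),
           truth = NULL)
    }
  })
  if (!setequal(colnames(dat$counts), dat$samples$sample_id))
    stop("pipeline stage `load` failed: counts and metadata sample ids differ")
  dat$samples <- dat$samples[match(colnames(dat$counts),
                                   dat$samples$sample_id), , drop = FALSE]

  ## ---- normalize --------------------------------------------------------
  norm <- run_stage("normalize", {
    filtered <- filter_low_counts(dat$counts, cfg$filter$min_cpm,
                                  cfg$filter$min_sample_frac)
    factors <- tmm_factors(filtered)
    lc <- log_cpm(filtered, factors)
    design <- build_design(dat$samples, c(cfg$exposure, cfg$covariates))
    adj <- if ("batch" %in% colnames(dat$samples))
      batch_adjust(lc, dat$samples$batch, design) else lc
    list(filtered = filtered, factors = factors, matrix = adj)
  })
  write_tsv(data.frame(sample = names(norm$factors),
                       norm_factor = unname(norm$factors)),
            file.path(cfg$outdir, "norm_factors.tsv"))
  out$norm <- norm

  ## ---- differential expression -----------------------------------------
  de <- run_stage("de", differential_expression(
    norm$matrix, dat$samples, cfg$exposure, cfg$covariates, cfg$alpha))
  write_tsv(de, file.path(cfg$outdir, "de_results.tsv"))
  out$de <- de

  ## ---- co-expression modules -------------------------------------------
  modules <- run_stage("modules", {
    power <- pick_soft_power(norm$matrix, cfg$coexpression$candidate_powers)
    ms <- detect_modules(norm$matrix, power,
                         cfg$coexpression$min_module_size,
                         cfg$coexpression$merge_height)
    if (any(ms$assignment > 0)) {
      eig <- module_eigengenes(norm$matrix, ms)
      assoc <- module_ses_association(eig, dat$samples, cfg$exposure,
                                      cfg$covariates, cfg$alpha)
      enr <- module_deg_enrichment(ms, de)
    } else {
      eig <- NULL; assoc <- NULL; enr <- NULL
    }
    list(module_set = ms, eigengenes = eig, association = assoc,
         deg_enrichment = enr)
  })
  write_tsv(data.frame(gene = names(modules$module_set$assignment),
                       module = unname(modules$module_set$assignment)),
            file.path(cfg$outdir, "modules.tsv"))
  if (!is.null(modules$eigengenes)) {
    write_tsv(data.frame(sample = rownames(modules$eigengenes),
                         modules$eigengenes, check.names = FALSE),
              file.path(cfg$outdir, "eigengenes.tsv"))
    write_tsv(modules$association, file.path(cfg$outdir, "module_ses.tsv"))
    write_tsv(modules$deg_enrichment,
              file.path(cfg$outdir, "module_deg_enrichment.tsv"))
  }
  out$modules <- modules

  ## ---- enrichment of DE genes ------------------------------------------
  universe <- de$gene
  set_a_genes <- de$gene[de$q_value < cfg$alpha]
  enr_de <- run_stage("enrich", {
    res <- ora(set_a_genes, universe, dat$ontology, cfg$alpha)
    pooled <- pool_to_parents(res, dat$ontology)
    list(ora = res, pooled = pooled)
  })
  write_tsv(enr_de$ora, file.path(cfg$outdir, "enrichment_de.tsv"))
  write_tsv(enr_de$pooled, file.path(cfg$outdir, "enrichment_pooled.tsv"))
  out$enrichment <- enr_de

  ## ---- upstream regulator sets -----------------------------------------
  sets <- run_stage("upstream", suppressWarnings(
    derive_sets(de, dat$grn, dat$ppi, dat$tf_universe, cfg$tf_threshold,
                cfg$ppi_threshold, cfg$alpha)))
  write_tsv(as.data.frame(sets), file.path(cfg$outdir, "regulator_sets.tsv"))
  out$sets <- sets

  ## ---- combined enrichment + layers ------------------------------------
  layers <- run_stage("layers", {
    lists <- list(up = de$gene[de$direction == "up"],
                  down = de$gene[de$direction == "down"],
                  tf = union(sets$set_b, sets$set_d),
                  neighbor = sets$set_c)
    lists <- lists[lengths(lists) > 0]
    comb_universe <- union(universe, unlist(lists))
    comb <- combined_enrichment(lists, comb_universe, dat$ontology,
                                cfg$alpha)
    pooled <- pool_to_parents(comb[, setdiff(colnames(comb),
                                             grep("^contrib_", colnames(comb),
                                                  value = TRUE))],
                              dat$ontology)
    sig <- pooled[pooled$q_value < cfg$alpha, , drop = FALSE]
    molecules <- unique(c(sets$set_a, sets$set_b, sets$set_c, sets$set_d))
    counts <- count_pathway_contributions(sig, molecules)
    lm_ <- assign_layers(counts[counts > 0], cfg$layer_bin_edges)
    list(combined = comb, pooled = pooled, significant = sig,
         layer_map = lm_)
  })
  write_tsv(layers$combined, file.path(cfg$outdir, "combined_enrichment.tsv"))
  write_tsv(layers$layer_map, file.path(cfg$outdir, "layers.tsv"))
  out$layers <- layers

  ## ---- mediation --------------------------------------------------------
  if (!is.null(cfg$mediators) && length(cfg$mediators)) {
    med <- run_stage("mediate", {
      genes <- intersect(layers$layer_map$molecule, rownames(norm$matrix))
      if (length(genes) == 0L) genes <- intersect(set_a_genes,
                                                  rownames(norm$matrix))
      res <- mediate_genome(norm$matrix, dat$samples, cfg$mediators,
                            genes = genes, exposure = cfg$exposure,
                            covariates = cfg$covariates, n_sim = cfg$n_sim,
                            seed = seeds[2])
      summ <- suppressMessages(
        layer_mediation_summary(res, layers$layer_map, cfg$alpha))
      list(per_gene = res, per_layer = summ)
    })
    write_tsv(med$per_gene, file.path(cfg$outdir, "mediation.tsv"))
    write_tsv(med$per_layer,
              file.path(cfg$outdir, "mediation_layer_summary.tsv"))
    out$mediation <- med
  } else message("no mediators configured; mediation stage skipped")

  ## ---- randomization ----------------------------------------------------
  rand <- run_stage("randomize", randomization_test(
    sets, universe, dat$grn, dat$ppi, dat$tf_universe,
    n_replicates = cfg$n_replicates, seed = seeds[3]))
  write_tsv(rand$per_gene, file.path(cfg$outdir, "randomization_genes.tsv"))
  jsonlite::write_json(rand$per_set,
                       file.path(cfg$outdir, "randomization_sets.json"),
                       auto_unbox = TRUE, digits = NA)
  out$randomization <- rand
  out$truth <- dat$truth

  ## ---- manifest ----------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$outdir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("sesnet")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("inputs", "synthetic", "outdir"))],
    synthetic = !is.null(cfg$synthetic),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(cfg$outdir, files))), files)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out$manifest <- manifest
  invisible(out)
}
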