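#' Settings for the synthetic regulatory / protein-interaction generator
#'
#' Networks emulate a blood-tissue gene regulatory network (TF -> target
#' edges scored by confidence in \[0,1\]) and a protein-protein interaction
#' resource (undirected scored edges). Ground truth is planted so downstream
#' set derivation can recover it: `n_true_tfs` modulating TFs are each wired
#' to `targets_per_tf` differentially expressed targets at confidence
#' `true_grn_conf`; every DE transcription factor receives one high-confidence
#' outgoing regulatory edge plus `ppi_neighbors_per_tf` protein partners at
#' `true_ppi_score`. Decoy edges get scores drawn uniformly from the
#' configured ranges.
#'
#' @param de_genes Character vector of genes carrying a true SES effect
#'   (targets for planted wiring). May be empty.
#' @param n_true_tfs Number of planted modulating TFs (recoverable as Set D).
#' @param targets_per_tf DE targets wired per true TF.
#' @param true_grn_conf Confidence of planted regulatory edges.
#' @param true_ppi_score Score of planted protein-interaction edges.
#' @param ppi_neighbors_per_tf Planted protein partners per DE TF.
#' @param n_decoy_grn,n_decoy_ppi Decoy edge counts.
#' @param decoy_grn_range,decoy_ppi_range Uniform score ranges for decoys.
#' @return A named list of class `network_config`.
#' @export
network_config <- function(de_genes = character(0),
                           n_true_tfs = 5,
                           targets_per_tf = 10,
                           true_grn_conf = 0.9,
                           true_ppi_score = 0.9,
                           ppi_neighbors_per_tf = 5,
                           n_decoy_grn = 2000,
                           n_decoy_ppi = 2000,
                           decoy_grn_range = c(0, 1),
                           decoy_ppi_range = c(0, 1)) {
  stopifnot(all(decoy_grn_range >= 0), all(decoy_grn_range <= 1),
            all(decoy_ppi_range >= 0), all(decoy_ppi_range <= 1),
            true_grn_conf >= 0, true_grn_conf <= 1,
            true_ppi_score >= 0, true_ppi_score <= 1)
  structure(as.list(environment()), class = "network_config")
}

gene_ids <- function(n_genes) sprintf("g%04d", seq_len(n_genes))

#' Generate scored regulatory and protein-interaction networks
#'
#' The TF universe is the first `n_tfs` gene identifiers (transcription
#' factors are genes). Planted true edges are laid down first; decoy edges
#' are added afterwards, deduplicated against the planted set, with no
#' self-loops. Deterministic given `seed`.
#'
#' @param n_tfs Number of transcription factors (>= 1).
#' @param n_genes Total number of genes (>= 1); TFs are the first `n_tfs`.
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return A list with elements `grn` (data.frame tf, target, confidence),
#'   `ppi` (data.frame protein_a, protein_b, score), `tf_universe`, and
#'   `truth` (list: `true_tfs`, `planted_grn`, `planted_ppi`).
#' @export
generate_networks <- function(n_tfs, n_genes, config = network_config(),
                              seed = 1L) {
  cfg <- config
  if (cfg$n_true_tfs > 0 && n_tfs < 1)
    stop("cannot plant true regulators with zero transcription factors")
  stopifnot(n_tfs >= 1, n_genes >= 1)
  genes <- gene_ids(n_genes)
  tfs <- genes[seq_len(min(n_tfs, n_genes))]
  de_genes <- intersect(cfg$de_genes, genes)
  de_tfs <- intersect(de_genes, tfs)

  withr::with_seed(as.integer(seed), {
    ## planted modulating TFs (Set D truth): wired onto DE targets
    n_true <- min(cfg$n_true_tfs, length(setdiff(tfs, de_genes)))
    true_tfs <- character(0)
    grn <- data.frame(tf = character(0), target = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE)
    if (n_true > 0 && length(de_genes) > 0) {
      true_tfs <- sample(setdiff(tfs, de_genes), n_true)
      planted <- do.call(rbind, lapply(true_tfs, function(tf) {
        tg <- sample(setdiff(de_genes, tf),
                     min(cfg$targets_per_tf, length(setdiff(de_genes, tf))))
        data.frame(tf = tf, target = tg, confidence = cfg$true_grn_conf,
                   stringsAsFactors = FALSE)
      }))
      grn <- planted
    }
    ## DE TFs (Set B truth) need >= 1 above-threshold outgoing edge
    if (length(de_tfs) > 0) {
      tg <- vapply(de_tfs, function(tf) sample(setdiff(genes, tf), 1),
                   character(1))
      grn <- rbind(grn, data.frame(tf = de_tfs, target = tg,
                                   confidence = cfg$true_grn_conf,
                                   stringsAsFactors = FALSE))
    }
    planted_grn <- grn

    ## decoy regulatory edges
    if (cfg$n_decoy_grn > 0) {
      dtf <- sample(tfs, cfg$n_decoy_grn, replace = TRUE)
      dtg <- sample(genes, cfg$n_decoy_grn, replace = TRUE)
      keep <- dtf != dtg
      decoy <- data.frame(tf = dtf[keep], target = dtg[keep],
                          confidence = runif(sum(keep), cfg$decoy_grn_range[1],
                                             cfg$decoy_grn_range[2]),
                          stringsAsFactors = FALSE)
      grn <- rbind(grn, decoy)
    }
    grn <- grn[!duplicated(grn[c("tf", "target")]), , drop = FALSE]

    ## planted protein partners of DE TFs (Set C truth)
    ppi <- data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    if (length(de_tfs) > 0 && cfg$ppi_neighbors_per_tf > 0) {
      ppi <- do.call(rbind, lapply(de_tfs, function(tf) {
        nb <- sample(setdiff(genes, tf),
                     min(cfg$ppi_neighbors_per_tf, n_genes - 1L))
        data.frame(protein_a = tf, protein_b = nb,
                   score = cfg$true_ppi_score, stringsAsFactors = FALSE)
      }))
    }
    planted_ppi <- ppi

    if (cfg$n_decoy_ppi > 0) {
      pa <- sample(genes, cfg$n_decoy_ppi, replace = TRUE)
      pb <- sample(genes, cfg$n_decoy_ppi, replace = TRUE)
      keep <- pa != pb
      ppi <- rbind(ppi, data.frame(
        protein_a = pa[keep], protein_b = pb[keep],
        score = runif(sum(keep), cfg$decoy_ppi_range[1], cfg$decoy_ppi_range[2]),
        stringsAsFactors = FALSE))
    }
    ## unordered pair uniqueness
    key <- paste(pmin(ppi$protein_a, ppi$protein_b),
                 pmax(ppi$protein_a, ppi$protein_b))
    ppi <- ppi[!duplicated(key), , drop = FALSE]
    rownames(grn) <- rownames(ppi) <- NULL

    list(grn = grn, ppi = ppi, tf_universe = tfs,
         truth = list(true_tfs = sort(true_tfs),
                      planted_grn = planted_grn, planted_ppi = planted_ppi))
  })
}
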