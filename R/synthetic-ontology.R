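#' Settings for the synthetic pathway ontology generator
#'
#' @param min_genes,max_genes Leaf annotation size range.
#' @param superset If `TRUE` (default) every parent's annotation is the union
#'   of its children's plus `extra_parent_genes` extra genes; if `FALSE`
#'   parents carry exactly the union.
#' @param extra_parent_genes Extra genes added to each internal node in
#'   superset mode.
#' @param planted_leaf_sets Optional list of gene vectors; the i-th vector is
#'   force-included in the i-th leaf's annotation (used to plant enrichment
#'   signal).
#' @return A named list of class `ontology_config`.
#' @export
ontology_config <- function(min_genes = 5, max_genes = 20, superset = TRUE,
                            extra_parent_genes = 3,
                            planted_leaf_sets = list()) {
  stopifnot(min_genes >= 1, max_genes >= min_genes)
  structure(as.list(environment()), class = "ontology_config")
}

#' Generate a three-level hierarchical pathway ontology
#'
#' Builds a forest of `n_roots` trees, each with exactly 3 levels below the
#' root and `branching` children per node, mirroring the hierarchical
#' organization of curated pathway databases (each pathway is a node with
#' parent-child relations). Leaves are annotated with randomly drawn gene
#' sets; internal nodes with (a superset of) the union of their children.
#' Deterministic given `seed`.
#'
#' @param n_roots Number of root pathways.
#' @param branching Children per node (>= 1).
#' @param genes Character vector of annotatable gene identifiers.
#' @param config An [ontology_config()].
#' @param seed Integer seed.
#' @return A list of class `pathway_ontology` with `nodes` (data.frame id,
#'   name, level), `parent_edges` (data.frame parent, child), and
#'   `annotations` (named list of gene sets).
#' @export
generate_ontology <- function(n_roots, branching, genes,
                              config = ontology_config(), seed = 1L) {
  stopifnot(n_roots >= 1, branching >= 1)
  cfg <- config
  if (length(genes) < cfg$min_genes)
    stop("fewer genes than `min_genes` per leaf annotation")

  ids_by_level <- list(sprintf("P%d", seq_len(n_roots)))
  edges <- list()
  for (lvl in 1:3) {
    parents <- ids_by_level[[lvl]]
    kids <- unlist(lapply(parents, function(p)
      sprintf("%s.%d", p, seq_len(branching))))
    edges[[lvl]] <- data.frame(parent = rep(parents, each = branching),
                               child = kids, stringsAsFactors = FALSE)
    ids_by_level[[lvl + 1L]] <- kids
  }
  parent_edges <- do.call(rbind, edges)
  nodes <- data.frame(
    id = unlist(ids_by_level),
    name = paste("pathway", unlist(ids_by_level)),
    level = rep(0:3, times = lengths(ids_by_level)),
    stringsAsFactors = FALSE)

  leaves <- ids_by_level[[4L]]
  annotations <- withr::with_seed(as.integer(seed), {
    ann <- setNames(vector("list", nrow(nodes)), nodes$id)
    for (i in seq_along(leaves)) {
      size <- sample(cfg$min_genes:min(cfg$max_genes, length(genes)), 1)
      set <- sample(genes, size)
      if (i <= length(cfg$planted_leaf_sets))
        set <- union(cfg$planted_leaf_sets[[i]], set)
      ann[[leaves[i]]] <- sort(unique(set))
    }
    for (lvl in 3:1) {
      for (p in ids_by_level[[lvl]]) {
        kids <- parent_edges$child[parent_edges$parent == p]
        u <- sort(unique(unlist(ann[kids])))
        if (cfg$superset && cfg$extra_parent_genes > 0) {
          pool <- setdiff(genes, u)
          u <- sort(union(u, sample(pool, min(cfg$extra_parent_genes,
                                              length(pool)))))
        }
        ann[[p]] <- u
      }
    }
    ann
  })
  structure(list(nodes = nodes, parent_edges = parent_edges,
                 annotations = annotations),
            class = "pathway_ontology")
}
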