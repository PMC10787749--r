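#' Cramer's V for a contingency table
#'
#' `sqrt(chi2 / (n * min(rows - 1, cols - 1)))` with the uncorrected
#' chi-square statistic; for a 2x2 table this equals the absolute phi
#' coefficient. Tables with an empty margin (no association measurable)
#' return 0.
#'
#' @param table Nonnegative count matrix with a positive total.
#' @return Value in \[0,1\].
#' @export
cramers_v <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative")
  n <- sum(table)
  if (n <= 0) stop("table total must be positive")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(0)
  chi2 <- suppressWarnings(
    unname(chisq.test(table, correct = FALSE)$statistic))
  v <- sqrt(chi2 / (n * (min(dim(table)) - 1)))
  min(max(v, 0), 1)
}

#' Over-representation analysis against a pathway ontology
#'
#' One-sided hypergeometric test per pathway: the probability of drawing at
#' least the observed overlap when `query_size` genes are sampled from the
#' universe. Pathway annotations are intersected with the universe first;
#' pathways with no annotated universe genes are skipped. BH q-values are
#' computed across all tested pathways and Cramer's V on the 2x2
#' query x pathway membership table.
#'
#' @param query Gene set of interest (must be a subset of `universe`).
#' @param universe Background gene set.
#' @param ontology A `pathway_ontology` (see [generate_ontology()]) or a
#'   named list of pathway gene sets.
#' @param alpha FDR threshold carried in the result attributes.
#' @return data.frame with `pathway`, `overlap`, `query_size`,
#'   `pathway_size`, `universe_size`, `p_value`, `q_value`, `cramers_v`,
#'   and a list-column `contributing_genes`.
#' @export
ora <- function(query, universe, ontology, alpha = 0.05) {
  annotations <- if (!is.null(ontology$annotations))
    ontology$annotations else ontology
  query <- unique(query)
  universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query gene(s) outside the universe: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(annotations), function(pw) {
    ann <- intersect(annotations[[pw]], universe)
    if (length(ann) == 0L) return(NULL)
    hits <- intersect(query, ann)
    k <- length(hits)
    kk <- length(ann)
    p <- phyper(k - 1, kk, n_u - kk, n_q, lower.tail = FALSE)
    tab <- matrix(c(k, n_q - k, kk - k, n_u - n_q - kk + k), 2, byrow = TRUE)
    data.frame(pathway = pw, overlap = k, query_size = n_q,
               pathway_size = kk, universe_size = n_u, p_value = p,
               cramers_v = cramers_v(tab),
               contributing_genes = I(list(sort(hits))),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(pathway = character(0), overlap = integer(0),
                      query_size = integer(0), pathway_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      q_value = numeric(0), cramers_v = numeric(0),
                      contributing_genes = I(list())))
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[, c("pathway", "overlap", "query_size", "pathway_size",
                 "universe_size", "p_value", "q_value", "cramers_v",
                 "contributing_genes")]
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  out
}

# Kahn's algorithm: errors if the parent->child edge set has a cycle.
assert_acyclic <- function(parent_edges) {
  edges <- parent_edges
  repeat {
    if (nrow(edges) == 0L) return(invisible(TRUE))
    roots <- setdiff(edges$parent, edges$child)
    if (length(roots) == 0L)
      stop("cycle detected in pathway hierarchy")
    edges <- edges[!(edges$parent %in% roots), , drop = FALSE]
  }
}

# Map each node to its ancestors within `levels` steps.
ancestors_within <- function(parent_edges, nodes, levels) {
  assert_acyclic(parent_edges)
  parent_of <- split(parent_edges$parent, parent_edges$child)
  lapply(setNames(nodes, nodes), function(nd) {
    anc <- character(0)
    frontier <- nd
    for (i in seq_len(levels)) {
      frontier <- setdiff(unique(unlist(parent_of[frontier])), NA)
      if (length(frontier) == 0L) break
      anc <- union(anc, frontier)
    }
    anc
  })
}

#' Pool child enrichment results up to parent pathways
#'
#' Applies the "most significant child" rule: each ancestor within `levels`
#' steps of a tested pathway takes the minimum p-value over its tested
#' descendants (itself included when tested) and inherits that descendant's
#' q-value; contributing genes are unioned. Child results are retained
#' alongside (`node_type = "tested"`), pooled ancestors are added with
#' `node_type = "pooled"`. Ancestors with no tested descendants are absent.
#'
#' @param results An [ora()] result.
#' @param ontology A `pathway_ontology` with `parent_edges`.
#' @param levels Number of hierarchy levels to pool across (default 3).
#' @return data.frame like `results` plus columns `node_type` and
#'   `source_child` (the most significant descendant of a pooled node).
#' @export
pool_to_parents <- function(results, ontology, levels = 3) {
  parent_edges <- ontology$parent_edges
  tested <- results$pathway
  anc <- ancestors_within(parent_edges, tested, levels)
  pool <- list()
  for (i in seq_along(tested)) {
    for (a in anc[[tested[i]]]) pool[[a]] <- union(pool[[a]], tested[i])
  }
  ## a tested ancestor also pools over itself
  for (a in names(pool)) if (a %in% tested) pool[[a]] <- union(pool[[a]], a)

  idx <- setNames(seq_along(tested), tested)
  pooled_rows <- lapply(names(pool), function(a) {
    kids <- pool[[a]]
    best <- kids[which.min(results$p_value[idx[kids]])]
    genes <- sort(unique(unlist(results$contributing_genes[idx[kids]])))
    data.frame(pathway = a, overlap = length(genes),
               query_size = results$query_size[1],
               pathway_size = NA_integer_,
               universe_size = results$universe_size[1],
               p_value = results$p_value[idx[best]],
               q_value = results$q_value[idx[best]],
               cramers_v = results$cramers_v[idx[best]],
               contributing_genes = I(list(genes)),
               node_type = "pooled", source_child = best,
               stringsAsFactors = FALSE)
  })
  child <- results
  child$node_type <- "tested"
  child$source_child <- child$pathway
  out <- rbind(child, do.call(rbind, pooled_rows))
  rownames(out) <- NULL
  out
}

#' Combined enrichment of multiple labeled gene lists
#'
#' Runs over-representation analysis on the union of the lists and reports,
#' per pathway, the fractional contribution of each list: a gene present in
#' several lists is split equally among them, and contributions are
#' normalized by the pathway overlap so they sum to 1.
#'
#' @param lists Named list of gene sets (may overlap).
#' @param universe Background gene set containing the union.
#' @param ontology Pathway ontology or named annotation list.
#' @param alpha FDR threshold.
#' @return An [ora()] result with one `contrib_<label>` column per list.
#' @export
combined_enrichment <- function(lists, universe, ontology, alpha = 0.05) {
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("`lists` must be named")
  union_set <- unique(unlist(lists))
  if (length(union_set) == 0L) stop("the union of the gene lists is empty")
  res <- ora(union_set, universe, ontology, alpha)
  membership <- vapply(lists, function(l) union_set %in% l,
                       logical(length(union_set)))
  membership <- matrix(membership, nrow = length(union_set),
                       dimnames = list(union_set, names(lists)))
  w <- membership / pmax(rowSums(membership), 1)
  contrib <- t(vapply(seq_len(nrow(res)), function(i) {
    hits <- res$contributing_genes[[i]]
    if (length(hits) == 0L) return(rep(0, length(lists)))
    colSums(w[hits, , drop = FALSE]) / length(hits)
  }, numeric(length(lists))))
  colnames(contrib) <- paste0("contrib_", names(lists))
  cbind(res, as.data.frame(contrib))
}
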