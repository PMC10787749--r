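# Core set derivation from an already-significant gene list. `directions`
# is an optional named vector ("up"/"down") over set_a genes. Networks are
# assumed pre-validated; no warnings are emitted here (the randomization
# module calls this once per replicate).
derive_sets_core <- function(set_a, directions, grn, ppi, tf_universe,
                             tf_threshold, ppi_threshold) {
  strong_grn <- grn[grn$confidence > tf_threshold, , drop = FALSE]
  strong_ppi <- ppi[ppi$score > ppi_threshold, , drop = FALSE]

  hit <- strong_grn$target %in% set_a
  set_d <- sort(unique(strong_grn$tf[hit]))

  ## Set B: DE genes in the TF universe that act as a source with at least
  ## one above-threshold regulatory edge.
  sources <- unique(strong_grn$tf)
  set_b <- sort(intersect(intersect(set_a, tf_universe), sources))

  ## Set C: protein partners of Set B at above-threshold interaction score.
  a_in <- strong_ppi$protein_a %in% set_b
  b_in <- strong_ppi$protein_b %in% set_b
  set_c <- sort(unique(c(strong_ppi$protein_b[a_in], strong_ppi$protein_a[b_in])))

  tags <- NULL
  if (!is.null(directions)) {
    tag_d <- vapply(set_d, function(tf) {
      tg <- strong_grn$target[strong_grn$tf == tf & hit]
      collapse_tags(directions[tg])
    }, character(1))
    tag_b <- vapply(set_b, function(g) collapse_tags(directions[g]),
                    character(1))
    tag_c <- vapply(set_c, function(p) {
      nb <- c(strong_ppi$protein_a[strong_ppi$protein_b == p],
              strong_ppi$protein_b[strong_ppi$protein_a == p])
      collapse_tags(unlist(strsplit(tag_b[intersect(nb, set_b)], "\\|")))
    }, character(1))
    tags <- list(a = vapply(set_a, function(g) collapse_tags(directions[g]),
                            character(1)),
                 b = tag_b, c = tag_c, d = tag_d)
  }
  structure(list(set_a = sort(set_a), set_b = set_b, set_c = set_c,
                 set_d = set_d, tags = tags,
                 tf_threshold = tf_threshold, ppi_threshold = ppi_threshold),
            class = "regulator_sets")
}

#' Derive the four upstream regulator sets
#'
#' From differential expression results and scored networks: Set A, the
#' DE genes (`q < alpha`); Set B, DE transcription factors that act as a
#' source with at least one above-threshold edge in the regulatory network;
#' Set C, protein partners of Set B members at interaction score strictly
#' above `ppi_threshold`; Set D, transcription factors with at least one
#' regulatory edge of confidence strictly above `tf_threshold` onto a Set A
#' gene. Both thresholds use strict inequality (a score of exactly 0.4 or
#' 0.7 does not qualify). Each recruited molecule carries the DE direction
#' tag(s) of the gene(s) that recruited it.
#'
#' @param de A [differential_expression()] result.
#' @param grn Regulatory edges: data.frame `tf`, `target`,
#'   `confidence` in \[0,1\].
#' @param ppi Undirected protein edges: data.frame `protein_a`,
#'   `protein_b`, `score` in \[0,1\].
#' @param tf_universe Identifiers of known transcription factors.
#' @param tf_threshold Regulatory confidence cutoff (default 0.4, "medium
#'   or greater confidence").
#' @param ppi_threshold Interaction score cutoff (default 0.7, "at least
#'   high confidence").
#' @param alpha FDR threshold defining Set A.
#' @param warn_unknown Warn about (and skip) regulatory edges whose target
#'   is outside the DE gene universe.
#' @return A `regulator_sets` object: `set_a` .. `set_d` plus direction
#'   `tags`; see [as.data.frame.regulator_sets()].
#' @export
derive_sets <- function(de, grn, ppi, tf_universe, tf_threshold = 0.4,
                        ppi_threshold = 0.7, alpha = 0.05,
                        warn_unknown = TRUE) {
  assert_prob(tf_threshold); assert_prob(ppi_threshold)
  if (any(grn$confidence < 0 | grn$confidence > 1))
    stop("regulatory confidences must lie in [0, 1]")
  if (any(ppi$score < 0 | ppi$score > 1))
    stop("interaction scores must lie in [0, 1]")
  unknown <- !(grn$target %in% de$gene)
  if (any(unknown)) {
    if (warn_unknown)
      warning(sum(unknown), " regulatory edge(s) with targets outside the ",
              "DE universe skipped")
    grn <- grn[!unknown, , drop = FALSE]
  }
  set_a <- de$gene[de$q_value < alpha]
  directions <- setNames(de$direction, de$gene)
  derive_sets_core(set_a, directions, grn, ppi, tf_universe,
                   tf_threshold, ppi_threshold)
}

#' Flatten regulator sets to a table
#'
#' @param x A `regulator_sets` object.
#' @param ... Unused.
#' @return data.frame with `molecule`, `set` (A/B/C/D), `direction`.
#' @export
as.data.frame.regulator_sets <- function(x, ...) {
  lab <- c(a = "A", b = "B", c = "C", d = "D")
  rows <- lapply(names(lab), function(s) {
    mols <- x[[paste0("set_", s)]]
    if (length(mols) == 0L) return(NULL)
    data.frame(molecule = mols, set = lab[[s]],
               direction = if (is.null(x$tags)) NA_character_ else
                 unname(x$tags[[s]][mols]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(molecule = character(0), set = character(0),
                      direction = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count enriched-pathway contributions per molecule
#'
#' For each molecule, the number of (significant) pathways whose
#' contributing gene sets contain it. Pass in the post-pooling rows you
#' consider significant; contributing genes are deduplicated within each
#' pathway row.
#'
#' @param enrichment An enrichment result with a `contributing_genes`
#'   list-column (e.g. significant rows of [pool_to_parents()] or
#'   [combined_enrichment()] output).
#' @param molecules Character vector of molecules to score.
#' @return Named integer vector (zeros included; drop them before
#'   [assign_layers()]).
#' @export
count_pathway_contributions <- function(enrichment, molecules) {
  molecules <- unique(molecules)
  counts <- setNames(integer(length(molecules)), molecules)
  for (genes in enrichment$contributing_genes) {
    hit <- molecules %in% unique(genes)
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

#' Assign molecules to relevance layers by pathway contribution count
#'
#' Layer 1 (innermost): molecules contributing to more than
#' `bin_edges[1]` enriched pathways; layer 4 (outermost): exactly
#' `bin_edges[3]` pathway. The middle bins default to 6-10 (layer 2) and
#' 2-5 (layer 3).
#'
#' @param counts Named positive integer vector of pathway counts.
#' @param bin_edges Decreasing thresholds, default `c(10, 5, 1)`: layer k
#'   holds counts strictly above `bin_edges[k]` (layer 4 = the remainder,
#'   i.e. exactly `bin_edges[3]` under the default).
#' @return data.frame with `molecule`, `pathway_count`, `layer`.
#' @export
assign_layers <- function(counts, bin_edges = c(10, 5, 1)) {
  if (length(counts) && any(counts <= 0))
    stop("pathway counts must be positive; drop zero-count molecules first")
  stopifnot(length(bin_edges) == 3, all(diff(bin_edges) < 0))
  layer <- ifelse(counts > bin_edges[1], 1L,
                  ifelse(counts > bin_edges[2], 2L,
                         ifelse(counts > bin_edges[3], 3L, 4L)))
  data.frame(molecule = names(counts), pathway_count = as.integer(counts),
             layer = layer, stringsAsFactors = FALSE, row.names = NULL)
}
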