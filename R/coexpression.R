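# Scale-free topology fit: R^2 of the log10(frequency) ~ log10(connectivity)
# regression over binned connectivities, signed by the slope.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2L) return(0)
  bins <- cut(k, breaks = n_bins)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 2L) return(0)
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Choose the soft-thresholding power for co-expression adjacency
#'
#' Evaluates the scale-free-topology fit of the unsigned adjacency
#' `|cor|^power` over candidate powers and returns the smallest power whose
#' signed fit reaches `target_fit`, or the power with maximal fit when none
#' does. Deterministic.
#'
#' @param matrix Normalized expression (genes x samples), >= 10 genes.
#' @param candidate_powers Integer candidates (>= 3 values).
#' @param target_fit Signed R^2 target (default 0.8).
#' @return The chosen power, with the per-candidate fits as attribute
#'   `fits`.
#' @export
pick_soft_power <- function(matrix, candidate_powers = c(1:10, 12, 14, 16),
                            target_fit = 0.8) {
  if (nrow(matrix) < 10L)
    stop("scale-free fit undefined for fewer than 10 genes")
  if (length(candidate_powers) == 1L) {
    out <- candidate_powers
    attr(out, "fits") <- setNames(NA_real_, candidate_powers)
    return(out)
  }
  if (length(candidate_powers) < 3L)
    stop("supply at least 3 candidate powers (or exactly one)")
  r <- abs(cor(t(matrix)))
  diag(r) <- 0
  fits <- vapply(candidate_powers,
                 function(p) scale_free_fit(rowSums(r^p)), numeric(1))
  names(fits) <- candidate_powers
  hit <- which(fits >= target_fit)
  out <- if (length(hit)) candidate_powers[hit[1]] else
    candidate_powers[which.max(fits)]
  attr(out, "fits") <- fits
  out
}

# Topological overlap dissimilarity of an unsigned adjacency matrix.
tom_dissimilarity <- function(adj) {
  diag(adj) <- 0
  l <- adj %*% adj
  k <- rowSums(adj)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  1 - tom
}

#' Detect co-expression modules by topological overlap clustering
#'
#' Unsigned adjacency `|cor|^power`, topological overlap dissimilarity,
#' average-linkage hierarchical clustering, and a static cut. By default
#' the cut height is placed in the middle of the largest gap between
#' consecutive dendrogram merge heights — the natural static separation
#' between within-module and between-module merges; when no gap reaches
#' `min_gap` the dendrogram shows no module structure and every gene is
#' left unassigned. Passing a numeric `merge_height` cuts at that absolute
#' height instead. Clusters smaller than `min_module_size` are unassigned
#' (label 0); surviving modules are renamed 1, 2, ... in decreasing size
#' order.
#'
#' @param matrix Normalized expression (genes x samples).
#' @param power Soft-thresholding power (>= 1).
#' @param min_module_size Minimum genes per module (>= 2).
#' @param merge_height Absolute static cut height, or `NULL` (default) for
#'   the largest-gap rule.
#' @param min_gap Minimum dendrogram-height gap accepted as evidence of
#'   module structure under the automatic rule.
#' @return List of class `module_set`: `assignment` (named integer, 0 =
#'   unassigned), `power`, `cut_height` (NA when no structure was found),
#'   `tree` (the hclust object).
#' @export
detect_modules <- function(matrix, power, min_module_size = 20,
                           merge_height = NULL, min_gap = 0.01) {
  stopifnot(power >= 1)
  if (min_module_size < 2L) stop("`min_module_size` must be at least 2")
  adj <- abs(cor(t(matrix)))^power
  diss <- tom_dissimilarity(adj)
  d <- stats::as.dist(diss)
  tree <- hclust(d, method = "average")
  if (is.null(merge_height)) {
    h <- sort(tree$height)
    gaps <- diff(h)
    cut_height <- if (length(gaps) == 0L || max(gaps) < min_gap)
      NA_real_ else h[which.max(gaps)] + max(gaps) / 2
  } else cut_height <- merge_height
  raw <- if (is.na(cut_height))
    seq_len(nrow(matrix)) else cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  assignment <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord))
      assignment[raw == as.integer(ord[i])] <- i
  }
  names(assignment) <- rownames(matrix)
  structure(list(assignment = assignment, power = power,
                 cut_height = cut_height, tree = tree),
            class = "module_set")
}

#' Module eigengene
#'
#' First right-singular vector of the gene-standardized module submatrix,
#' scaled to unit variance, with the sign chosen so that its correlation
#' with the module's mean expression profile is positive.
#'
#' @param matrix Normalized expression (genes x samples).
#' @param member_genes Gene ids of the module (>= 1, present in `matrix`).
#' @return Numeric per-sample vector (variance 1) with attribute
#'   `var_explained`.
#' @export
module_eigengene <- function(matrix, member_genes) {
  if (length(member_genes) == 0L) stop("empty module")
  missing <- setdiff(member_genes, rownames(matrix))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(head(missing, 5), collapse = ", "))
  x <- matrix[member_genes, , drop = FALSE]
  xs <- t(scale(t(x)))
  xs[!is.finite(xs)] <- 0  # zero-variance genes contribute nothing
  sv <- svd(xs)
  v <- sv$v[, 1]
  if (sd(v) == 0) stop("degenerate module: eigengene has zero variance")
  v <- v / sd(v)
  m <- colMeans(xs)
  if (sd(m) > 0 && cor(v, m) < 0) v <- -v
  names(v) <- colnames(matrix)
  attr(v, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  v
}

#' Eigengenes for all detected modules
#'
#' @param matrix Normalized expression (genes x samples).
#' @param module_set A [detect_modules()] result (or named assignment
#'   vector).
#' @return Samples x modules matrix of eigengenes (columns `ME1`, `ME2`, ...).
#' @export
module_eigengenes <- function(matrix, module_set) {
  assignment <- if (inherits(module_set, "module_set"))
    module_set$assignment else module_set
  mods <- sort(unique(assignment[assignment > 0]))
  if (length(mods) == 0L) stop("no assigned modules")
  out <- vapply(mods, function(m)
    module_eigengene(matrix, names(assignment)[assignment == m]),
    numeric(ncol(matrix)))
  colnames(out) <- paste0("ME", mods)
  rownames(out) <- colnames(matrix)
  out
}

#' Eigengene-exposure association
#'
#' Models each module eigengene as a linear function of the exposure with
#' the same covariate adjustment as the per-gene differential expression,
#' with BH correction across modules.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @param samples Metadata table aligned to the rows.
#' @param exposure,covariates,alpha As in [differential_expression()].
#' @return data.frame with `module`, `beta`, `se`, `t_stat`, `p_value`,
#'   `q_value`, `direction`.
#' @export
module_ses_association <- function(eigengenes, samples, exposure = "ses",
                                   covariates = character(0), alpha = 0.05) {
  res <- differential_expression(t(eigengenes), samples, exposure,
                                 covariates, alpha)
  names(res)[names(res) == "gene"] <- "module"
  res$degenerate <- NULL
  res
}

#' Module enrichment for differentially expressed genes
#'
#' One-sided (greater) Fisher exact test of the 2x2 table
#' (in module vs not) x (DE in the given direction vs not), per module and
#' direction, with BH correction across all module x direction tests.
#'
#' @param module_set A [detect_modules()] result (or assignment vector).
#' @param de A [differential_expression()] result over the identical gene
#'   universe.
#' @param directions Directions to test (default both `"up"` and `"down"`).
#' @return data.frame with `module`, `direction`, `overlap`, `odds_ratio`,
#'   `p_value`, `q_value`.
#' @export
module_deg_enrichment <- function(module_set, de,
                                  directions = c("up", "down")) {
  assignment <- if (inherits(module_set, "module_set"))
    module_set$assignment else module_set
  if (!setequal(names(assignment), de$gene))
    stop("module and DE gene universes differ")
  mods <- sort(unique(assignment[assignment > 0]))
  rows <- list()
  for (dir in directions) {
    de_set <- de$gene[de$direction == dir]
    for (m in mods) {
      in_mod <- names(assignment)[assignment == m]
      a <- length(intersect(in_mod, de_set))
      b <- length(in_mod) - a
      cc <- length(de_set) - a
      d <- length(assignment) - a - b - cc
      ft <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                        alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, direction = dir, overlap = a,
        odds_ratio = unname(ft$estimate), p_value = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out
}
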