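#' Filter genes with low counts
#'
#' Retains genes whose counts-per-million reach `min_cpm` in at least
#' `min_sample_frac` of samples; the sample set is unchanged. With
#' `min_cpm = 0` the filter is the identity.
#'
#' @param counts Nonnegative integer matrix (genes x samples).
#' @param min_cpm CPM threshold (>= 0).
#' @param min_sample_frac Minimum fraction of samples at or above the
#'   threshold (in \[0,1\]).
#' @return Filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_cpm = 0.5, min_sample_frac = 0.5) {
  stopifnot(min_cpm >= 0, min_sample_frac >= 0, min_sample_frac <= 1)
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    warning("empty count matrix; nothing to filter")
    return(counts)
  }
  cpm <- sweep(counts, 2, colSums(counts), `/`) * 1e6
  keep <- rowMeans(cpm >= min_cpm) >= min_sample_frac
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Per-sample scale factors by the weighted trimmed mean of M-values:
#' log-ratios (M) and log-abundances (A) of library-size-scaled counts
#' against a reference sample, doubly trimmed (`trim_m` on each M tail,
#' `trim_a` on each A tail), averaged with inverse asymptotic binomial
#' variance weights. Genes with a zero count in either sample are excluded
#' from the M/A computation. The reference defaults to the sample whose
#' upper-quartile CPM is closest to the mean upper-quartile. Factors are
#' renormalized to geometric mean 1. Computed via edgeR's TMM implementation.
#'
#' @param counts Count matrix (genes x samples), positive column sums.
#' @param trim_m Fraction of M-values trimmed from each tail.
#' @param trim_a Fraction of A-values trimmed from each tail.
#' @param ref Reference sample id or index; `NULL` for the upper-quartile
#'   convention.
#' @return Named positive numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  counts <- as.matrix(counts)
  zero <- colSums(counts) <= 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero] %||% which(zero), collapse = ", "))
  ref_idx <- NULL
  if (!is.null(ref)) {
    ref_idx <- if (is.character(ref)) match(ref, colnames(counts)) else as.integer(ref)
    if (is.na(ref_idx)) stop("reference sample not found: ", ref)
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref_idx,
                              logratioTrim = trim_m, sumTrim = trim_a,
                              doWeighting = TRUE)
  setNames(as.numeric(f), colnames(counts))
}

#' Log2 counts-per-million on effective library sizes
#'
#' `log2((count + prior_count) / (lib_size * factor + 2 * prior_count) * 1e6)`,
#' monotone in the count.
#'
#' @param counts Count matrix (genes x samples).
#' @param factors Per-sample normalization factors aligned to the columns
#'   (e.g. from [tmm_factors()]); defaults to all 1.
#' @param prior_count Offset avoiding log of zero.
#' @return Numeric matrix of log2 CPM values with `norm_factors` attribute.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- setNames(rep(1, ncol(counts)), colnames(counts))
  if (length(factors) != ncol(counts))
    stop("`factors` must have one entry per sample")
  if (!is.null(names(factors)) && !is.null(colnames(counts))) {
    if (!setequal(names(factors), colnames(counts)))
      stop("sample names of `factors` do not match the count matrix")
    factors <- factors[colnames(counts)]
  }
  eff_lib <- colSums(counts) * factors
  out <- log2(sweep(counts + prior_count, 2, eff_lib + 2 * prior_count, `/`) * 1e6)
  attr(out, "norm_factors") <- factors
  out
}

#' Empirical-Bayes batch adjustment preserving the covariate design
#'
#' Parametric empirical-Bayes location-scale batch correction (the ComBat
#' model), followed by a per-gene re-centering step that restores each
#' gene's grand mean exactly; batch contrasts are unaffected by the
#' re-centering. With a single batch the input is returned unchanged. Genes
#' with zero variance within some batch are passed through unadjusted.
#'
#' @param matrix Normalized expression matrix (genes x samples).
#' @param batch Batch labels, one per sample (>= 2 samples per batch).
#' @param design Optional model matrix of covariates whose effects must be
#'   preserved (no batch columns).
#' @return Adjusted matrix of the same shape.
#' @export
batch_adjust <- function(matrix, batch, design = NULL) {
  batch <- factor(batch)
  if (length(batch) != ncol(matrix))
    stop("`batch` must have one label per sample")
  if (nlevels(batch) < 2L) return(matrix)
  sizes <- table(batch)
  if (any(sizes < 2L))
    stop("batch(es) with a single sample: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  within_var_ok <- rep(TRUE, nrow(matrix))
  for (b in levels(batch)) {
    v <- apply(matrix[, batch == b, drop = FALSE], 1, var)
    within_var_ok <- within_var_ok & v > 0
  }
  out <- matrix
  if (any(within_var_ok)) {
    sub <- matrix[within_var_ok, , drop = FALSE]
    adj <- suppressMessages(
      sva::ComBat(dat = sub, batch = batch, mod = design, par.prior = TRUE))
    adj <- adj - rowMeans(adj) + rowMeans(sub)  # exact grand-mean restoration
    out[within_var_ok, ] <- adj
  }
  attr(out, "norm_factors") <- attr(matrix, "norm_factors")
  out
}
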