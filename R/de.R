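#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement.
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @return q-values in \[0,1\], same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

# Build a full-rank design matrix from metadata columns; error names the
# collinear columns if rank-deficient.
build_design <- function(samples, columns) {
  missing <- setdiff(columns, colnames(samples))
  if (length(missing))
    stop("metadata column(s) not found: ", paste(missing, collapse = ", "))
  df <- samples[, columns, drop = FALSE]
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
    if (is.ordered(df[[j]])) df[[j]] <- as.integer(df[[j]]) - 1L
  }
  constant <- vapply(df, function(x) length(unique(x)) < 2L, logical(1))
  df <- df[, !constant, drop = FALSE]
  design <- model.matrix(~ ., data = df)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  design
}

#' Per-gene linear model for a continuous exposure
#'
#' Ordinary least squares of normalized expression on the exposure plus
#' covariates, gene by gene, with an unmoderated two-sided t-test on the
#' exposure coefficient and Benjamini-Hochberg q-values across all tested
#' genes. "Up" means a positive association between the exposure and
#' expression. Genes with zero residual variance are reported with
#' `beta = 0, p = 1` and flagged degenerate rather than dropped, keeping
#' gene universes aligned across downstream modules.
#'
#' @param matrix Normalized expression (genes x samples), e.g. from
#'   [log_cpm()] / [batch_adjust()].
#' @param samples Metadata table aligned to the columns.
#' @param exposure Name of the continuous exposure column (default `"ses"`).
#' @param covariates Character vector of covariate column names.
#' @param alpha FDR threshold for direction calls.
#' @return data.frame with columns `gene`, `beta`, `se`, `t_stat`,
#'   `p_value`, `q_value`, `direction` (up/down/ns), `degenerate`.
#' @export
differential_expression <- function(matrix, samples, exposure = "ses",
                                    covariates = character(0), alpha = 0.05) {
  if (ncol(matrix) != nrow(samples))
    stop("sample count mismatch between matrix and metadata")
  design <- build_design(samples, c(exposure, covariates))
  col <- which(colnames(design) == exposure)
  if (length(col) != 1L)
    stop("exposure column must be continuous and present in the design")

  fit <- limma::lmFit(matrix, design)
  beta <- fit$coefficients[, col]
  se <- fit$stdev.unscaled[, col] * fit$sigma
  t_stat <- beta / se
  p <- 2 * pt(-abs(t_stat), df = fit$df.residual)

  ## constant genes (near-zero outcome variance) are degenerate; genes fitted
  ## perfectly by the design (zero residual, nonzero variance) are not
  rv <- rowSums((matrix - rowMeans(matrix))^2) / max(1, ncol(matrix) - 1)
  p[!is.finite(p) & fit$sigma == 0 & abs(beta) > 0] <- 0
  degenerate <- !is.finite(p) | !is.finite(beta) | rv < 1e-20
  beta[degenerate] <- 0
  se[degenerate] <- NA_real_
  t_stat[degenerate] <- 0
  p[degenerate] <- 1

  q <- bh_fdr(p)
  direction <- ifelse(q < alpha & beta > 0, "up",
                      ifelse(q < alpha & beta < 0, "down", "ns"))
  data.frame(gene = rownames(matrix), beta = unname(beta), se = unname(se),
             t_stat = unname(t_stat), p_value = unname(p),
             q_value = unname(q), direction = unname(direction),
             degenerate = unname(degenerate), stringsAsFactors = FALSE,
             row.names = NULL)
}
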