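#' Counterfactual mediation for a single outcome
#'
#' Fits the mediator model `M ~ X + C` (linear for a continuous mediator,
#' logistic for a binary one) and the outcome model `Y ~ X + M + C`
#' (linear; expression outcomes are continuous), then draws model
#' coefficients from their asymptotic sampling distribution
#' (quasi-Bayesian approximation) to estimate the average causal mediation
#' effect (ACME), average direct effect (ADE), total effect, percentile
#' confidence intervals and a two-sided Monte-Carlo p-value for the ACME.
#' For a binary mediator the mediated effect integrates the change in the
#' mediator's probability over the observed covariate distribution.
#' `prop_mediated = acme / total` may be negative (suppression: the
#' indirect and direct paths pull in opposite directions) and is flagged
#' undefined when `|total|` is below `total_tol`.
#'
#' The Monte-Carlo p-value uses add-one smoothing
#' (`2 * min(#draws <= 0, #draws >= 0 + 1) / (n_sim + 1)`, capped at 1) so
#' downstream Fisher combination never receives an exact zero.
#'
#' @param outcome Numeric outcome vector (continuous).
#' @param exposure Numeric exposure vector.
#' @param mediator Numeric mediator vector (continuous, or binary 0/1).
#' @param covariates Optional data.frame of covariates.
#' @param n_sim Monte-Carlo draws (>= 100).
#' @param seed Integer seed (results are deterministic given it).
#' @param treat_value,control_value Exposure values contrasted (default a
#'   one-unit change 0 -> 1).
#' @param total_tol `prop_mediated` is flagged undefined when the absolute
#'   total effect falls below this.
#' @return One-row data.frame: `acme`, `ade`, `total`, `prop_mediated`,
#'   `prop_defined`, `ci_low`, `ci_high` (ACME 95% CI), `p_acme`,
#'   `mediator_type`, `n_sim`, `seed`.
#' @export
mediate_single <- function(outcome, exposure, mediator, covariates = NULL,
                           n_sim = 1000, seed = 1L, treat_value = 1,
                           control_value = 0, total_tol = 1e-8) {
  n <- length(outcome)
  if (length(exposure) != n || length(mediator) != n)
    stop("outcome, exposure and mediator must be aligned")
  if (n_sim < 100) stop("`n_sim` must be at least 100")
  if (length(unique(outcome)) <= 2L)
    stop("binary outcomes are unsupported (expression outcomes are continuous)")

  cmat <- NULL
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cdf <- as.data.frame(covariates)
    for (j in seq_along(cdf)) {
      if (is.character(cdf[[j]])) cdf[[j]] <- factor(cdf[[j]])
      if (is.ordered(cdf[[j]])) cdf[[j]] <- as.integer(cdf[[j]]) - 1L
    }
    keep <- !vapply(cdf, function(x) length(unique(x)) < 2L, logical(1))
    if (any(keep))
      cmat <- model.matrix(~ ., data = cdf[, keep, drop = FALSE])[, -1, drop = FALSE]
  }

  if (var(mediator) == 0) {
    ## a constant mediator carries no indirect path: ACME is exactly 0
    fit <- lm(outcome ~ cbind(exposure = exposure, cmat))
    ade <- unname(coef(fit)[2]) * (treat_value - control_value)
    return(data.frame(acme = 0, ade = ade, total = ade, prop_mediated = 0,
                      prop_defined = abs(ade) >= total_tol, ci_low = 0,
                      ci_high = 0, p_acme = 1, mediator_type = "constant",
                      n_sim = as.integer(n_sim), seed = as.integer(seed),
                      stringsAsFactors = FALSE))
  }
  binary <- length(unique(mediator)) == 2L
  if (binary) mediator <- as.numeric(mediator == max(mediator))

  xm <- cbind(exposure = exposure, cmat)
  xo <- cbind(exposure = exposure, mediator = mediator, cmat)

  med_fit <- if (binary)
    glm(mediator ~ xm, family = binomial()) else lm(mediator ~ xm)
  out_fit <- lm(outcome ~ xo)
  if (any(is.na(coef(med_fit))) || any(is.na(coef(out_fit))))
    stop("rank-deficient mediator or outcome model")

  draws <- withr::with_seed(as.integer(seed), {
    md <- MASS::mvrnorm(n_sim, coef(med_fit), vcov(med_fit))
    od <- MASS::mvrnorm(n_sim, coef(out_fit), vcov(out_fit))
    list(md = md, od = od)
  })
  a_col <- 2L                      # exposure coefficient in mediator model
  b_col <- 3L                      # mediator coefficient in outcome model
  c_col <- 2L                      # exposure coefficient in outcome model
  dx <- treat_value - control_value

  if (!binary) {
    acme_s <- draws$md[, a_col] * draws$od[, b_col] * dx
  } else {
    base <- cbind(rep(1, n), 0, cmat)  # exposure column zeroed; added per draw
    acme_s <- vapply(seq_len(n_sim), function(s) {
      g <- draws$md[s, ]
      eta0 <- base %*% g + g[a_col] * control_value
      eta1 <- base %*% g + g[a_col] * treat_value
      draws$od[s, b_col] * mean(plogis(eta1) - plogis(eta0))
    }, numeric(1))
  }
  ade_s <- draws$od[, c_col] * dx
  total_s <- acme_s + ade_s

  acme <- mean(acme_s); ade <- mean(ade_s); total <- mean(total_s)
  ci <- unname(quantile(acme_s, c(0.025, 0.975)))
  p_acme <- min(1, 2 * (min(sum(acme_s <= 0), sum(acme_s >= 0)) + 1) /
                  (n_sim + 1))
  defined <- abs(total) >= total_tol
  data.frame(acme = acme, ade = ade, total = total,
             prop_mediated = if (defined) acme / total else NA_real_,
             prop_defined = defined, ci_low = ci[1], ci_high = ci[2],
             p_acme = p_acme,
             mediator_type = if (binary) "binary" else "continuous",
             n_sim = as.integer(n_sim), seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

# Coerce a metadata mediator column to numeric (ordered categories become
# 0-based scores, e.g. the four alcohol categories -> 0..3).
coerce_mediator <- function(x, name) {
  if (is.numeric(x)) return(x)
  if (is.ordered(x)) return(as.integer(x) - 1L)
  if (is.factor(x) || is.character(x)) {
    u <- unique(as.character(x))
    if (length(u) == 2L) return(as.numeric(factor(x, levels = sort(u))) - 1)
  }
  stop("cannot coerce mediator column `", name,
       "` to numeric (unordered multi-level factor)")
}

#' Genome-wide mediation across genes and mediators
#'
#' Applies [mediate_single()] to each (gene, mediator) pair with a
#' deterministic per-pair seed schedule fanned out from the master seed.
#' Ordered-category mediators (e.g. the four alcohol consumption
#' categories) are entered as numeric scores 0, 1, 2, 3.
#'
#' @param matrix Normalized expression (genes x samples).
#' @param samples Metadata table aligned to the columns.
#' @param mediators Mediator column names in `samples`.
#' @param genes Genes to mediate (default: all rows).
#' @param exposure Exposure column (default `"ses"`).
#' @param covariates Covariate column names.
#' @param n_sim,seed As in [mediate_single()].
#' @return data.frame with one row per (gene, mediator) pair.
#' @export
mediate_genome <- function(matrix, samples, mediators,
                           genes = rownames(matrix), exposure = "ses",
                           covariates = character(0), n_sim = 1000,
                           seed = 1L) {
  missing_m <- setdiff(mediators, colnames(samples))
  if (length(missing_m))
    stop("unknown mediator column(s): ", paste(missing_m, collapse = ", "))
  genes <- intersect(genes, rownames(matrix))
  if (length(genes) == 0L) stop("no requested genes present in the matrix")
  covs <- if (length(covariates))
    samples[, covariates, drop = FALSE] else NULL
  grid <- expand.grid(gene = genes, mediator = mediators,
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gene[i]; m <- grid$mediator[i]
    res <- mediate_single(outcome = matrix[g, ],
                          exposure = samples[[exposure]],
                          mediator = coerce_mediator(samples[[m]], m),
                          covariates = covs, n_sim = n_sim,
                          seed = seeds[i])
    cbind(data.frame(gene = g, mediator = m, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize mediation per relevance layer
#'
#' Per (layer, mediator) cell: the median of the defined mediated
#' proportions (winsorized to `[-winsor, winsor]` to tame near-zero total
#' effects; negative medians indicate suppression), an aggregated adjusted
#' p-value (Fisher combination of the genes' ACME p-values within the cell,
#' BH-adjusted across cells), and gene counts. Genes with undefined
#' proportions are excluded and counted. Empty cells are omitted with a
#' message.
#'
#' @param results A [mediate_genome()] result.
#' @param layers An [assign_layers()] result covering the summarized genes.
#' @param alpha Significance level carried as attribute.
#' @param winsor Winsorization bound for mediated proportions.
#' @return data.frame with `layer`, `mediator`, `median_prop_mediated`,
#'   `fisher_p`, `aggregated_q`, `n_genes`, `n_excluded`.
#' @export
layer_mediation_summary <- function(results, layers, alpha = 0.05,
                                    winsor = 5) {
  lay <- setNames(layers$layer, layers$molecule)
  res <- results[results$gene %in% names(lay), , drop = FALSE]
  if (nrow(res) < nrow(results))
    message(nrow(results) - nrow(res), " mediation row(s) without a layer dropped")
  res$layer <- lay[res$gene]
  cells <- unique(res[, c("layer", "mediator")])
  cells <- cells[order(cells$layer, cells$mediator), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- res[res$layer == cells$layer[i] & res$mediator == cells$mediator[i], ]
    ok <- sub$prop_defined & is.finite(sub$prop_mediated)
    if (!any(ok)) {
      message("layer ", cells$layer[i], " x ", cells$mediator[i],
              ": no defined mediated proportions; cell omitted")
      return(NULL)
    }
    ratios <- pmin(pmax(sub$prop_mediated[ok], -winsor), winsor)
    fc <- fisher_combine(sub$p_acme)
    data.frame(layer = cells$layer[i], mediator = cells$mediator[i],
               median_prop_mediated = median(ratios),
               fisher_p = fc$p_value, n_genes = sum(ok),
               n_excluded = sum(!ok), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(layer = integer(0), mediator = character(0),
                      median_prop_mediated = numeric(0), fisher_p = numeric(0),
                      aggregated_q = numeric(0), n_genes = integer(0),
                      n_excluded = integer(0)))
  out <- do.call(rbind, rows)
  out$aggregated_q <- bh_fdr(out$fisher_p)
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  out
}
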