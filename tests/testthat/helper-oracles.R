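# Independent brute-force oracles used across tests. These re-derive the
# expected quantities from first principles (enumeration, closed forms) and
# never call the code paths they check.

# TMM factor by direct enumeration of M/A values: library-size-scaled
# proportions, zero-count exclusion, rank-based double trimming, inverse
# asymptotic binomial variance weights, renormalized to geometric mean 1.
tmm_factor_oracle <- function(counts, ref, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(s) {
    y_s <- counts[, s]; y_r <- counts[, ref]
    pos <- y_s > 0 & y_r > 0
    ys <- y_s[pos]; yr <- y_r[pos]
    ns <- lib[s]; nr <- lib[ref]
    m <- log2((ys / ns) / (yr / nr))
    a <- 0.5 * log2((ys / ns) * (yr / nr))
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    w <- (ns - ys) / (ns * ys) + (nr - yr) / (nr * yr)
    2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# P(overlap >= k) when drawing n genes from a universe of N containing K
# annotated genes, by summing hypergeometric point masses via choose().
hyper_tail_oracle <- function(k, K, N, n) {
  js <- max(0, n - (N - K)):min(K, n)
  mass <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(mass[js >= k])
}

# One-sided (greater) Fisher exact p for the 2x2 table ((a, b), (c, d)):
# condition on the margins and enumerate.
fisher_greater_oracle <- function(a, b, c, d) {
  hyper_tail_oracle(a, a + b, a + b + c + d, a + c)
}

# Scale-free topology fit recomputed independently from a connectivity
# vector: bin, regress log10 frequency on log10 mean connectivity.
scale_free_fit_oracle <- function(k, n_bins = 10) {
  k <- k[k > 0]
  bins <- cut(k, breaks = n_bins)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  ok <- !is.na(dk) & !is.na(pk) & pk > 0
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  -sign(coef(fit)[2]) * summary(fit)$r.squared
}

# Gaussian matrix with planted orthogonal blocks: block latent factor plus
# independent noise, the classic co-expression module testbed.
make_block_matrix <- function(n_blocks = 3, block_size = 50, n_samples = 200,
                              noise_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      f <- rnorm(n_samples)
      t(replicate(block_size, f + rnorm(n_samples, sd = noise_sd)))
    }))
    rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
    colnames(x) <- sprintf("s%04d", seq_len(ncol(x)))
    list(matrix = x,
         labels = rep(seq_len(n_blocks), each = block_size))
  })
}

# Minimal DE result table for set-derivation tests.
make_de_table <- function(genes, sig = character(0), direction = "up",
                          alpha = 0.05) {
  dirs <- setNames(rep("ns", length(genes)), genes)
  if (length(direction) == 1L) direction <- rep(direction, length(sig))
  dirs[sig] <- direction
  data.frame(gene = genes, beta = ifelse(dirs == "up", 1,
                                         ifelse(dirs == "down", -1, 0)),
             se = 0.1, t_stat = 0, p_value = ifelse(dirs == "ns", 0.9, 1e-4),
             q_value = ifelse(dirs == "ns", 0.9, 1e-3),
             direction = unname(dirs), degenerate = FALSE,
             stringsAsFactors = FALSE)
}
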