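## Split-half Gelman-Rubin R-hat from per-chain-half summary statistics.
## Each chain's post-warmup draws are split in two; R-hat compares the
## between- and within-half variances. Inputs are matrices [report x half]
## of the half sizes, sums, and sums of squares, so the full draw history
## never needs to be stored.
split_rhat_from_moments <- function(n_mat, sum_mat, sumsq_mat) {
  m <- ncol(n_mat)            # number of half-chains
  n <- n_mat[, 1]             # draws per half (equal by construction)
  means <- sum_mat / n_mat
  vars <- (sumsq_mat - n_mat * means^2) / (n_mat - 1)
  W <- rowMeans(vars)
  grand <- rowMeans(means)
  B <- n * apply(means, 1, function(x) sum((x - mean(x))^2)) / (m - 1)
  var_plus <- (n - 1) / n * W + B / n
  rhat <- sqrt(var_plus / W)
  ## Degenerate latents (e.g. zero within-half variance) are flagged
  ## converged rather than NaN.
  rhat[!is.finite(rhat)] <- 1
  rhat
}

## Evenly spaced indices selecting `k` of `n` kept iterations.
thin_indices <- function(n, k) {
  if (k >= n) return(seq_len(n))
  unique(round(seq(1, n, length.out = k)))
}
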