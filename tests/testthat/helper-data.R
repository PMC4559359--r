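# Shared fixture builders; everything is generated in code at test time.

# noiseless (or noisy) rank-A matrix with orthonormal loadings and factor
# scales chosen so the 90 %-variance rule selects the full rank
rank_factor_matrix <- function(n, p, rank, scales = c(2, 1.5, 1.3)[seq_len(rank)],
                               noise_sd = 0, seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * rank), n, rank) %*% diag(scales, rank)
  load <- qr.Q(qr(matrix(rnorm(p * rank), p, rank)))
  x <- scores %*% t(load)
  if (noise_sd > 0) x <- x + matrix(rnorm(n * p, sd = noise_sd), n, p)
  x
}

# matrix whose centred column space has exact variance shares
shared_variance_matrix <- function(n, p, shares, seed = 1) {
  set.seed(seed)
  k <- length(shares)
  raw <- scale(matrix(rnorm(n * k), n, k), scale = FALSE)
  t_ <- qr.Q(qr(raw))  # orthonormal, centred columns
  t_ <- t_ %*% diag(sqrt(shares * (n - 1)), k)
  load <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
  t_ %*% t(load)
}

# exactly uncorrelated standardised columns (sample correlation = identity)
orthonormal_columns <- function(n, p, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE)))
  scale(q) # unit variance, zero mean, exactly orthogonal
}
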