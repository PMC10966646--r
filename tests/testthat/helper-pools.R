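# Fixture builders and independent oracles shared across test files.

# Random binary-fingerprint pool with Gaussian potencies (no cluster signal).
make_random_pool <- function(n, d = 64, seed = 42) {
  withr::with_seed(seed, {
    fp <- matrix(rbinom(n * d, 1, 0.3), nrow = n)
    fp[rowSums(fp) == 0, 1] <- 1 # avoid degenerate all-zero fingerprints
    compound_pool(sprintf("c%04d", seq_len(n)), rnorm(n, 6, 1), fp)
  })
}

# Brute-force pairwise Tanimoto matrix via the scalar definition.
brute_tanimoto <- function(X, Y = X) {
  out <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(Y))) {
      a <- sum(X[i, ] * Y[j, ])
      d <- sum(X[i, ]) + sum(Y[j, ]) - a
      out[i, j] <- if (d == 0) 1 else a / d
    }
  }
  out
}

# Independent dense GP posterior: explicit solve of (K + noise I) alpha = y
# with plain solve(), mirroring the standardization and de-standardization
# conventions but none of the production factorization path.
dense_gp_oracle <- function(fp_train, y, fp_query, amp, noise, m = 0) {
  mu <- mean(y)
  s <- if (length(y) > 1) sd(y) else 0
  if (!is.finite(s) || s == 0) s <- 1
  ys <- (y - mu) / s
  K <- amp * brute_tanimoto(fp_train)
  ks <- amp * brute_tanimoto(fp_train, fp_query)
  A <- K + diag(noise, length(y))
  alpha <- solve(A, ys - m)
  mean_std <- m + drop(t(ks) %*% alpha)
  var_std <- pmax(amp - diag(t(ks) %*% solve(A, ks)), 0)
  list(mean = mean_std * s + mu, variance = var_std * s^2)
}
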