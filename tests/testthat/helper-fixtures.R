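# shared test helpers: small random objects built in code

random_bitmatrix <- function(n, n_bits, p = 0.3, seed = 1,
                             scheme_tag = "synthetic") {
  set.seed(seed)
  bit_matrix(matrix(rbinom(n * n_bits, 1, p), n, n_bits),
             scheme_tag = scheme_tag)
}

# brute-force Tanimoto, scalar loop form
tanimoto_loop <- function(a, b) {
  inter <- 0; union <- 0
  for (k in seq_along(a)) {
    if (a[k] == 1 && b[k] == 1) inter <- inter + 1
    if (a[k] == 1 || b[k] == 1) union <- union + 1
  }
  if (union == 0) 0 else inter / union
}

# brute-force one-sided pooled two-proportion p-value
ztest_loop <- function(ct, nt, cr, nr) {
  pt <- ct / nt; pr <- cr / nr
  P <- (nt * pt + nr * pr) / (nt + nr)
  den <- sqrt(P * (1 - P) * (1 / nt + 1 / nr))
  if (den == 0) return(list(z = 0, p = 0.5))
  z <- (pt - pr) / den
  list(z = z, p = 1 - pnorm(z))
}

# labeled random distance matrix (symmetric, zero diagonal)
random_distmat <- function(n, seed = 1) {
  set.seed(seed)
  d <- matrix(runif(n * n), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(LETTERS[1:n], LETTERS[1:n])
  d
}

# naive O(n^3) complete-linkage oracle: returns sorted merge heights
complete_linkage_heights_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# all-pairs counting ARI oracle
ari_pairs_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  np <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}
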