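# Independent brute-force oracles used to verify the exact-test paths.
# These enumerate null distributions directly and share no code with the
# package implementations.

# Rank-sum: enumerate every assignment of m of the pooled observations to
# the first sample; U counts pairs (x > y) with half-credit for ties.
oracle_rank_sum <- function(x, y, alternative = "two.sided") {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pool <- c(x, y)
  m <- length(x)
  obs <- u_stat(x, y)
  idx <- utils::combn(seq_along(pool), m)
  us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
  p_ge <- mean(us >= obs - 1e-12)
  p_le <- mean(us <= obs + 1e-12)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Signed-rank: enumerate all 2^n sign patterns over the magnitude ranks.
oracle_signed_rank <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_ge <- mean(ws >= obs - 1e-12)
  p_le <- mean(ws <= obs + 1e-12)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Fisher 2x2: enumerate every table with the observed margins.
oracle_fisher <- function(tab, alternative = "two.sided") {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a_obs, c1, n - c1, r1)
  switch(alternative,
         greater = sum(probs[support >= a_obs]),
         less = sum(probs[support <= a_obs]),
         two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Hypergeometric upper tail by direct summation.
oracle_hypergeom <- function(hits, set_size, universe_hits, universe_size) {
  k <- hits:min(set_size, universe_hits)
  sum(choose(universe_hits, k) *
        choose(universe_size - universe_hits, set_size - k)) /
    choose(universe_size, set_size)
}

# Step-up BH by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Ordinary equal-variance two-sample t, gene-wise.
oracle_pooled_t <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  s2 <- (rowSums((a - m1)^2) + rowSums((b - m2)^2)) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * stats::pt(-abs(tt), n1 + n2 - 2))
}
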