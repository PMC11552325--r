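# Independent oracles used across the suite. Each re-derives the quantity
# it checks by brute force or closed form, never through package code.

# Exact two-sided permutation p for the rank-sum statistic: the fraction of
# the choose(n1+n2, n1) group relabellings whose rank-sum deviates from its
# mean by at least the observed amount.
perm_ranksum_p <- function(x1, x2) {
  n1 <- length(x1); n <- n1 + length(x2)
  r <- rank(c(x1, x2))
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  combs <- utils::combn(n, n1)
  stats <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(stats - mu) >= obs - 1e-9)
}

# Benjamini-Hochberg step-up written as the textbook loop: order raw p
# ascending, take p_(i) * m / i, then enforce monotonicity from the largest
# rank down and cap at 1.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- (m / seq_len(m)) * p[o]
  if (m >= 2) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail P(overlap >= k) by exhausting all choose(N, n)
# draws of the query from the universe.
hyper_tail_enum <- function(k, K, n, N) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Pixel-union co-location oracle: for every pixel of the image, test the
# distance to every spot centre directly.
pixel_union_oracle <- function(shape, coords, diameter) {
  H <- shape[1]; W <- shape[2]
  r2 <- (diameter / 2)^2
  covered <- matrix(FALSE, H, W)
  for (y in 0:(H - 1)) for (x in 0:(W - 1)) {
    covered[y + 1, x + 1] <-
      any((x - coords$x)^2 + (y - coords$y)^2 <= r2)
  }
  covered
}

# Connected-component labelling oracle: breadth-first search from each
# unvisited foreground pixel over the 8-neighbourhood.
cc_oracle <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!bin[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            bin[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}
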