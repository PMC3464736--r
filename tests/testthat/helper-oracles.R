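# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths.

# Exhaustive scan of the entropic-correlation criterion with naive per-T sums.
yen_bruteforce <- function(probs, t_cap) {
  best_t <- NA_integer_; best_v <- -Inf
  for (T in 1:(t_cap - 1L)) {
    P <- sum(probs[1:(T + 1L)])
    if (P <= 0 || P >= 1) next
    cb <- 0; cf <- 0
    for (g in 0:T) cb <- cb + (probs[g + 1L] / P)^2
    for (g in (T + 1L):255L) cf <- cf + (probs[g + 1L] / (1 - P))^2
    v <- -log(cb) - log(cf)
    if (v > best_v) { best_v <- v; best_t <- T }
  }
  best_t
}

# Stack-based flood fill, 8-connectivity, components numbered in raster-scan
# order of first encounter.
flood_fill_labels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W); nxt <- 0L
  sr <- integer(H * W); sc <- integer(H * W)
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    top <- 1L; sr[1L] <- r0; sc[1L] <- c0; lab[r0, c0] <- nxt
    while (top > 0L) {
      r <- sr[top]; c <- sc[top]; top <- top - 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= H && cc >= 1L && cc <= W &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          top <- top + 1L; sr[top] <- rr; sc[top] <- cc
        }
      }
    }
  }
  lab
}

# Direct double-loop central-moment summation.
moments_bruteforce <- function(pix) {
  pix <- unname(as.matrix(pix))
  ub <- mean(pix[, 1L]); vb <- mean(pix[, 2L])
  mu20 <- 0; mu02 <- 0; mu11 <- 0
  for (i in seq_len(nrow(pix))) {
    du <- pix[i, 1L] - ub; dv <- pix[i, 2L] - vb
    mu20 <- mu20 + du * du
    mu02 <- mu02 + dv * dv
    mu11 <- mu11 + du * dv
  }
  c(mu20 = mu20, mu02 = mu02, mu11 = mu11)
}

random_histogram <- function(spiky = FALSE) {
  p <- if (spiky) {
    v <- numeric(256)
    k <- sample(2:8, 1L)
    # keep one mode in the deep shadows so a split below any cap exists
    v[c(sample(0:90, 1L), sample(91:255, k - 1L)) + 1L] <- runif(k)
    v
  } else runif(256)^3
  p / sum(p)
}

hist_from_probs <- function(probs) {
  structure(list(probs = probs, cum = cumsum(probs), n = 1e6L),
            class = "intensity_histogram")
}
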