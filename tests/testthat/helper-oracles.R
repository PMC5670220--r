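# Independent oracles, deliberately brute-force, used to cross-check the
# production code paths.

# O(n^2) sliding-window clustering oracle: a breakpoint is clustered iff
# some window of length `window` anchored at any breakpoint contains it
# together with >= min_n breakpoints.
oracle_clustered <- function(pos, window = 1e6, min_n = 10) {
  vapply(seq_along(pos), function(i) {
    any(vapply(pos, function(a) {
      inside <- pos >= a & pos <= a + window
      inside[i] && sum(inside) >= min_n
    }, logical(1)))
  }, logical(1))
}

# exhaustive grid search over the exposure simplex (S <= 3)
oracle_grid_exposures <- function(m, P, step = 0.05) {
  tot <- sum(m)
  S <- ncol(P)
  props <- seq(0, 1, by = step)
  grid <- expand.grid(rep(list(props), S - 1))
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(grid))) {
    p <- as.numeric(grid[i, ])
    if (sum(p) > 1 + 1e-9) next
    e <- c(p, 1 - sum(p)) * tot
    rss <- sum((m - P %*% e)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- e
    }
  }
  best
}

# exhaustive subset check for synchronous gains: any k-subset spanning
# less than `window` pmt
oracle_synchronous <- function(t, k = 4, window = 30) {
  if (length(t) < k) return(FALSE)
  any(apply(utils::combn(t, k), 2, function(x) diff(range(x)) < window))
}

# tiny deterministic signature matrix for closed-form tests: three sharply
# concentrated, nearly orthogonal profiles
tiny_P <- function(S = 3) {
  P <- matrix(1e-4, 96, S, dimnames = list(mut_category_levels(),
                                           paste0("toy", seq_len(S))))
  anchors <- list(1:5, 40:44, 80:84)
  for (s in seq_len(S)) P[anchors[[s]], s] <- 1
  sweep(P, 2, colSums(P), "/")
}
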