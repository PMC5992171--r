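# Exhaustive-enumeration oracle for the boundary dynamic program.
# Enumerates every depth-monotone-by-at-most-one path across the columns
# of a gradient image (vectorized over the 3^(nc-1) move sequences) and
# returns the minimum accumulated cost. Independent of the package's
# column-sweep recursion.
enumerate_min_cost <- function(G, alpha) {
  nr <- nrow(G); nc <- ncol(G)
  maxI <- max(G)
  moves <- as.matrix(expand.grid(rep(list(-1:1), nc - 1)))
  M <- nrow(moves)
  best <- Inf
  for (s in seq_len(nr)) {
    prev_rows <- rep(s, M)
    valid <- rep(TRUE, M)
    cost <- rep(2 * (maxI - G[s, 1]), M)
    for (k in 2:nc) {
      rows_k <- prev_rows + moves[, k - 1]
      valid <- valid & rows_k >= 1 & rows_k <= nr
      rk <- pmin(pmax(rows_k, 1L), nr)
      rk1 <- pmin(pmax(prev_rows, 1L), nr)
      a <- G[cbind(rk1, k - 1)]
      b <- G[cbind(rk, k)]
      m <- ifelse(moves[, k - 1] != 0, alpha, 1)
      cost <- cost + m * (2 * maxI - a - b)
      prev_rows <- rows_k
    }
    cost[!valid] <- Inf
    if (any(valid)) best <- min(best, min(cost[valid]))
  }
  best
}

# accumulated cost of one explicit path (1-based rows, one per column)
path_cost <- function(G, rows, alpha, maxI = max(G)) {
  cost <- 2 * (maxI - G[rows[1], 1])
  for (k in seq_along(rows)[-1]) {
    m <- if (rows[k] != rows[k - 1]) alpha else 1
    cost <- cost + m * (2 * maxI - G[rows[k - 1], k - 1] - G[rows[k], k])
  }
  cost
}
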