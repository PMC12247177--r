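## Independent oracles and small fixture builders shared across tests.
## These deliberately use naive double loops / dense algebra so they form
## a second, independent route to the quantities the package computes.

## literal double-loop transcription of Moran's I
moran_loop <- function(y, W) {
  n <- length(y)
  ybar <- mean(y)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (y[i] - ybar) * (y[j] - ybar)
  den <- sum((y - ybar)^2)
  n / sum(W) * num / den
}

## literal double-loop transcription of Geary's C
geary_loop <- function(y, W) {
  n <- length(y)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (y[i] - y[j])^2
  (n - 1) * num / (2 * sum(W) * sum((y - mean(y))^2))
}

## unit square polygon with lower-left corner (x, y)
unit_square <- function(x, y) {
  cbind(c(x, x + 1, x + 1, x), c(y, y, y + 1, y + 1))
}

## named list of unit-square polygons for an r x c grid, ids r<i>c<j>
grid_polygons <- function(rows, cols) {
  polys <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols))
    polys[[paste0("r", r, "c", c)]] <- unit_square(c - 1, r - 1)
  polys
}

## binary weight matrix of a 4-cycle 1-2-3-4-1
cycle4_w <- function() {
  W <- matrix(0, 4, 4)
  W[cbind(c(1, 2, 3, 4), c(2, 3, 4, 1))] <- 1
  W + t(W)
}

## random connected weight structure: lattice edges plus noise weights
random_weight_matrix <- function(n, seed, binary = TRUE) {
  set.seed(seed)
  W <- matrix(0, n, n)
  repeat {
    W[] <- 0
    idx <- which(upper.tri(W))
    on <- sample(idx, size = max(n, rbinom(1, length(idx), 0.15)))
    W[on] <- if (binary) 1 else runif(length(on), 0.2, 2)
    W <- W + t(W)
    if (all(rowSums(W) > 0)) break
  }
  W
}
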