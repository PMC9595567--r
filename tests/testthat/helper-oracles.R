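# Brute-force oracles used to pin expected values independently of the
# implementation paths they check.

# direct wrap-around circular convolution, O(X^2)
direct_convolve_1d <- function(occ, kern) {
  X <- length(occ)
  vapply(0:(X - 1), function(y) {
    sum(occ * kern[((y - 0:(X - 1)) %% X) + 1])
  }, numeric(1))
}

direct_convolve_2d <- function(occ, kern) {
  X <- nrow(occ)
  out <- matrix(0, X, X)
  for (y1 in 0:(X - 1)) for (y2 in 0:(X - 1)) {
    s <- 0
    for (x1 in 0:(X - 1)) for (x2 in 0:(X - 1)) {
      s <- s + occ[x1 + 1, x2 + 1] *
        kern[((y1 - x1) %% X) + 1, ((y2 - x2) %% X) + 1]
    }
    out[y1 + 1, y2 + 1] <- s
  }
  out
}

# exhaustive ordered pair-distance counts on a periodic ring
brute_pairs_1d <- function(cells, X) {
  n <- length(cells)
  counts <- integer(X)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      k <- (cells[i] - cells[j]) %% X
      counts[k + 1L] <- counts[k + 1L] + 1L
    }
  }
  counts  # index k+1 = offset k (ordered pairs, both directions counted)
}

brute_pairs_2d <- function(cx, cy, X) {
  n <- length(cx)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      dx <- min((cx[i] - cx[j]) %% X, (cx[j] - cx[i]) %% X)
      dy <- min((cy[i] - cy[j]) %% X, (cy[j] - cy[i]) %% X)
      key <- as.character(dx^2 + dy^2)
      out[[key]] <- (if (is.null(out[[key]])) 0L else out[[key]]) + 1L
    }
  }
  out  # named by squared distance in cells
}

# direct pairwise neighbour-weighted trait with the discrete wrapped kernel
brute_phi_prime <- function(cells, phi, kern_vals, X) {
  n <- length(cells)
  phiE <- pmax(phi, 0)
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != i) s <- s + phiE[j] * kern_vals[((cells[i] - cells[j]) %% X) + 1]
    }
    s
  }, numeric(1))
}

pop_cov <- function(x, y) mean(x * y) - mean(x) * mean(y)
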