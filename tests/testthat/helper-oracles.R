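# Independent oracles used to cross-check the package's fast paths.
# These deliberately avoid the implementation's recursions and butterflies.

# Background-averaged operator entry by entry from first principles:
# Omega_ij = (-1)^popcount(i) (1/2)^(N - popcount(i)) * (-1)^popcount(i & j)
oracle_bg_operator <- function(n) {
  idx <- 0:(2^n - 1)
  pc <- function(x) vapply(x, function(v) sum(index_to_bits(v, n)), numeric(1))
  o <- pc(idx)
  out <- matrix(0, 2^n, 2^n)
  for (i in idx) {
    for (j in idx) {
      shared <- sum(index_to_bits(i, n) * index_to_bits(j, n))
      out[i + 1, j + 1] <- (-1)^o[i + 1] * 0.5^(n - o[i + 1]) * (-1)^shared
    }
  }
  out
}

# Single-reference operator from the subset finite-difference definition:
# omega_i = sum over subsets j of i of (-1)^(|i| - |j|) y_j
oracle_sr_operator <- function(n) {
  idx <- 0:(2^n - 1)
  out <- matrix(0, 2^n, 2^n)
  for (i in idx) {
    bi <- index_to_bits(i, n)
    for (j in idx) {
      bj <- index_to_bits(j, n)
      if (all(bj <= bi)) {
        out[i + 1, j + 1] <- (-1)^(sum(bi) - sum(bj))
      }
    }
  }
  out
}

# Average effect of flipping position p from 0 to 1 over all backgrounds
oracle_avg_effect <- function(y, p, n) {
  idx <- 0:(2^n - 1)
  bit <- idx %/% 2^(p - 1) %% 2
  mean(y[bit == 1]) - mean(y[bit == 0])
}

# Exhaustive DFS enumeration of functional walks of length m between two
# genotypes (every visited genotype functional)
oracle_count_walks <- function(mask, n, source, target, m) {
  count <- 0L
  recurse <- function(node, steps) {
    if (steps == m) {
      if (node == target) count <<- count + 1L
      return(invisible(NULL))
    }
    for (nb in hamming_neighbors(node, n)) {
      if (mask[nb + 1]) recurse(nb, steps + 1L)
    }
  }
  if (mask[source + 1] && mask[target + 1]) recurse(source, 0L)
  count
}

# Direct (monotone) functional paths between antipodes by enumerating all
# N! position orderings; also returns which genotypes lie on >= 1 path
oracle_direct_paths <- function(mask, n) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  on_path <- logical(2^n)
  total <- 0L
  for (ord in perms(seq_len(n))) {
    nodes <- c(0, cumsum(2^(ord - 1)))
    if (all(mask[nodes + 1])) {
      total <- total + 1L
      on_path[nodes + 1] <- TRUE
    }
  }
  list(n_paths = total, on_path = on_path)
}

# Greedy forward selection of terms by SSE reduction, via dense inverse
oracle_greedy_rank <- function(spec, n) {
  inv <- build_operator(n, "background_averaged")$omega_inv
  y <- as.numeric(inv %*% spec$terms)
  remaining <- seq_len(2^n)
  chosen <- integer(0)
  yhat <- numeric(2^n)
  while (length(remaining) > 0) {
    sses <- vapply(remaining, function(i) {
      sum((y - (yhat + inv[, i] * spec$terms[i]))^2)
    }, numeric(1))
    best <- remaining[which.min(sses)]
    yhat <- yhat + inv[, best] * spec$terms[best]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  chosen - 1L
}

# quick builders
unit_landscape <- function(n, value = 1) landscape(rep(value, 2^n))

random_landscape <- function(n, seed) {
  set.seed(seed)
  landscape(stats::rnorm(2^n))
}
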