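# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# all set partitions of 1..n as label vectors (restricted growth strings)
enumerate_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) rec(c(labels, lab), max(k, lab))
  }
  rec(integer(0), 0L)
  out
}

# CRP partition probability via the sequential product form
crp_partition_prob <- function(labels, alpha) {
  p <- 1
  seen_sizes <- integer(0)
  for (i in seq_along(labels)) {
    k <- labels[i]
    if (i == 1) { seen_sizes[k] <- 1L; next }
    if (k > length(seen_sizes) || is.na(seen_sizes[k]) || seen_sizes[k] == 0) {
      p <- p * alpha / (alpha + i - 1)
      seen_sizes[k] <- 1L
    } else {
      p <- p * seen_sizes[k] / (alpha + i - 1)
      seen_sizes[k] <- seen_sizes[k] + 1L
    }
  }
  p
}

# plain-loop greedy penalized binary segmentation (recomputes costs naively)
oracle_seg_cost <- function(y) sum((y - mean(y))^2)
oracle_best_split <- function(y, min_seg) {
  m <- length(y)
  best_j <- -1L; best_red <- -Inf
  if (m < 2 * min_seg) return(list(j = best_j, red = best_red))
  parent <- oracle_seg_cost(y)
  for (j in seq(min_seg, m - min_seg)) {
    red <- parent - oracle_seg_cost(y[1:j]) - oracle_seg_cost(y[(j + 1):m])
    if (red > best_red + 1e-12) { best_red <- red; best_j <- j }
  }
  list(j = best_j, red = best_red)
}
oracle_binseg <- function(y, Q, min_seg, penalty) {
  segs <- list(c(1L, length(y)))
  cps <- integer(0)
  while (length(cps) < Q) {
    reds <- vapply(segs, function(se) {
      oracle_best_split(y[se[1]:se[2]], min_seg)$red
    }, numeric(1))
    if (all(!is.finite(reds))) break
    pick <- which.max(reds)
    if (reds[pick] <= penalty) break
    se <- segs[[pick]]
    j <- oracle_best_split(y[se[1]:se[2]], min_seg)$j + se[1] - 1L
    segs[[pick]] <- NULL
    segs <- c(segs, list(c(se[1], j)), list(c(j + 1L, se[2])))
    cps <- c(cps, j)
  }
  sort(cps)
}

# pair-count ARI numerator/denominator pieces (for the PEAR linearity oracle)
ari_pieces <- function(c1, c2) {
  n <- length(c1)
  up <- upper.tri(matrix(0, n, n))
  I1 <- (outer(c1, c1, `==`) * 1)[up]
  I2 <- (outer(c2, c2, `==`) * 1)[up]
  C <- n * (n - 1) / 2
  num <- sum(I1 * I2) - sum(I1) * sum(I2) / C
  den <- 0.5 * (sum(I1) + sum(I2)) - sum(I1) * sum(I2) / C
  c(num = num, den = den)
}

# all spanning trees of the complete graph on n vertices by edge-subset
# enumeration; returns the maximum achievable total weight
oracle_max_spanning_weight <- function(W) {
  n <- nrow(W)
  edges <- which(upper.tri(W), arr.ind = TRUE)
  m <- nrow(edges)
  combs <- utils::combn(m, n - 1)
  best <- -Inf
  for (ci in seq_len(ncol(combs))) {
    sel <- combs[, ci]
    # connectivity check by BFS over the selected edges
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (e in sel) {
      a <- edges[e, 1]; b <- edges[e, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    seen <- logical(n); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
    }
    if (all(seen)) {
      w <- sum(W[edges[sel, , drop = FALSE]])
      if (w > best) best <- w
    }
  }
  best
}

# random small cluster data for NIW checks
random_cluster <- function(n_k, p) {
  matrix(rnorm(n_k * p, sd = runif(1, 0.5, 2)), n_k, p) +
    matrix(rnorm(p, sd = 3), n_k, p, byrow = TRUE)
}
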