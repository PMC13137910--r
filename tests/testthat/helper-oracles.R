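# Independent brute-force oracles used to validate the package's statistics.
# Each one evaluates the defining formula directly and shares no code with
# the implementation it checks.

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  q
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  # two-sided p via the incomplete beta representation of the t distribution
  p <- pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, df = df, p = p)
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  sa <- sum(a); sb <- sum(b)
  num <- n * sum(a * b) - sa * sb
  den <- sqrt(n * sum(a^2) - sa^2) * sqrt(n * sum(b^2) - sb^2)
  num / den
}

oracle_hypergeom_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

oracle_size_factors <- function(counts) {
  all_pos <- apply(counts, 1, function(r) all(r > 0))
  geo <- apply(counts[all_pos, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  apply(counts[all_pos, , drop = FALSE], 2, function(col) median(col / geo))
}

# Naive Ward.D2 agglomeration: recompute every cluster pair distance each
# step with the Lance-Williams ward.D2 update; returns the sequence of
# merged member-sets and merge heights.
oracle_ward_merges <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, best[1])
    ni <- sizes[i]; nj <- sizes[j]
    newD <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      newD[k] <- sqrt(((ni + nk) * D[i, k]^2 + (nj + nk) * D[j, k]^2 -
                         nk * D[i, j]^2) / (ni + nj + nk))
    }
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]), c(newD[keep], 0))
    clusters <- c(clusters[keep], list(merged))
    sizes <- c(sizes[keep], ni + nj)
  }
  list(merges = merges, heights = heights)
}

# Member sets per merge step of an hclust tree, for comparison with the oracle.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[s, ], function(x) {
      if (x < 0) -x else sets[[x]]
    }))
    sets[[s]] <- sort(members)
  }
  sets
}

# Mean silhouette width for a binary split of a 1-d score vector.
silhouette_mean <- function(x, labels) {
  d <- as.matrix(dist(x))
  s <- vapply(seq_along(x), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- mean(d[i, !(labels == labels[i])])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
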