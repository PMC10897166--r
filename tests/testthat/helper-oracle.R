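# From-scratch brute-force oracle for the reliability statistic: explicit
# distance loops, selection sort with index tie-break, textbook Pearson
# formula. Deliberately shares no code path with the package internals.

bruteEuclidean <- function(a, b) sqrt(sum((a - b)^2))

bruteSelectNeighbors <- function(d, self, m) {
  cand <- setdiff(seq_along(d), self)
  res <- integer(m)
  for (k in seq_len(m)) {
    best <- cand[1L]
    for (j in cand) {
      if (d[j] < d[best] || (d[j] == d[best] && j < best)) best <- j
    }
    res[k] <- best
    cand <- setdiff(cand, best)
  }
  res
}

brutePearson <- function(a, b) {
  am <- sum(a) / length(a)
  bm <- sum(b) / length(b)
  den <- sqrt(sum((a - am)^2) * sum((b - bm)^2))
  if (den == 0) return(NA_real_)
  sum((a - am) * (b - bm)) / den
}

bruteReliabilityScores <- function(pre, emb, x) {
  n <- nrow(pre)
  m <- floor(x / 100 * n + 0.5)
  m <- as.integer(min(max(m, 2), n - 1))
  out <- numeric(n)
  for (i in seq_len(n)) {
    dpre <- vapply(seq_len(n), function(j) bruteEuclidean(pre[i, ], pre[j, ]),
                   numeric(1))
    demb <- vapply(seq_len(n), function(j) bruteEuclidean(emb[i, ], emb[j, ]),
                   numeric(1))
    a <- bruteSelectNeighbors(dpre, i, m)
    b <- bruteSelectNeighbors(demb, i, m)
    out[i] <- brutePearson(demb[a], demb[b])
  }
  out
}

bruteKnn <- function(pre, emb, K) {
  n <- nrow(pre)
  props <- numeric(n)
  for (i in seq_len(n)) {
    dpre <- vapply(seq_len(n), function(j) bruteEuclidean(pre[i, ], pre[j, ]),
                   numeric(1))
    demb <- vapply(seq_len(n), function(j) bruteEuclidean(emb[i, ], emb[j, ]),
                   numeric(1))
    a <- bruteSelectNeighbors(dpre, i, K)
    b <- bruteSelectNeighbors(demb, i, K)
    props[i] <- length(intersect(a, b)) / K
  }
  mean(props)
}

# Small labeled Gaussian-cluster coordinate fixture (used where raw
# coordinates, not an expression matrix, are the natural input).
makeClusterCoords <- function(n, centers, sd = 0.3, seed = 1, d = 2) {
  set.seed(seed)
  k <- nrow(centers)
  lab <- rep(seq_len(k), length.out = n)
  xy <- centers[lab, seq_len(d), drop = FALSE] +
    matrix(rnorm(n * d, sd = sd), n, d)
  rownames(xy) <- paste0("cell", seq_len(n))
  list(coords = xy, labels = setNames(paste0("cluster", lab), rownames(xy)))
}
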