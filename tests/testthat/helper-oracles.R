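# Independent brute-force oracles used to check the package's cluster
# quality criteria and graph indicators. These are deliberately naive
# (explicit loops, exhaustive enumeration) and share no code with the
# implementation under test.

bruteSilhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

bruteCH <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  z <- colMeans(x)
  between <- 0; within <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    zk <- colMeans(xi)
    between <- between + nrow(xi) * sum((zk - z)^2)
    within <- within + sum(sweep(xi, 2, zk)^2)
  }
  (between / (k - 1)) / (within / (n - k))
}

bruteDB <- function(x, labels) {
  cls <- sort(unique(labels))
  k <- length(cls)
  cent <- do.call(rbind, lapply(cls, function(cl)
    colMeans(x[labels == cl, , drop = FALSE])))
  sdiam <- sapply(seq_len(k), function(i) {
    xi <- x[labels == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  })
  db <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      best <- max(best, (sdiam[i] + sdiam[j]) / dij)
    }
    db <- db + best
  }
  db / k
}

bruteInertia <- function(x, labels) {
  tot <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    tot <- tot + sum(sweep(xi, 2, colMeans(xi))^2)
  }
  tot
}

# ---- graph oracles (adjacency-matrix based, loops only) ----

bfShortestPaths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bfGlobalEff <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  d <- bfShortestPaths(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bfLocalEff <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    vals[v] <- if (length(nb) < 2L) 0 else
      bfGlobalEff(adj[nb, nb, drop = FALSE])
  }
  mean(vals)
}

bfClustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    deg <- length(nb)
    if (deg < 2L) { cc[v] <- 0; next }
    links <- sum(adj[nb, nb]) / 2
    cc[v] <- 2 * links / (deg * (deg - 1))
  }
  mean(cc)
}

bfMaxCore <- function(adj) {
  remaining <- seq_len(nrow(adj))
  kmax <- 0L
  k <- 1L
  a <- adj
  while (length(remaining) > 0L) {
    repeat {
      deg <- rowSums(a[remaining, remaining, drop = FALSE])
      drop <- remaining[deg < k]
      if (length(drop) == 0L) break
      remaining <- setdiff(remaining, drop)
      if (length(remaining) == 0L) break
    }
    if (length(remaining) == 0L) break
    kmax <- k
    k <- k + 1L
  }
  kmax
}

bfAssortativity <- function(adj) {
  deg <- rowSums(adj)
  e <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  if (nrow(e) == 0L) return(NA_real_)
  xs <- c(deg[e[, 1]], deg[e[, 2]])
  ys <- c(deg[e[, 2]], deg[e[, 1]])
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

bfModularityQ <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    ec <- sum(adj[idx, idx]) / 2
    dc <- sum(deg[idx])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

# all set partitions of 1..n (Bell(n) of them), as membership vectors
allPartitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPartitions(n - 1L)) {
    kmax <- max(p)
    for (c in seq_len(kmax + 1L)) out[[length(out) + 1L]] <- c(p, c)
  }
  out
}

bfMaxModularity <- function(adj) {
  best <- -Inf
  for (p in allPartitions(nrow(adj)))
    best <- max(best, bfModularityQ(adj, p), na.rm = TRUE)
  best
}

# random correlation-like symmetric matrix with unit diagonal
randomFc <- function(n) {
  a <- matrix(stats::rnorm(n * n), n)
  m <- stats::cov2cor(crossprod(a) + diag(n) * 0.5)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
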