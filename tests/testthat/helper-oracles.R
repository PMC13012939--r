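# Independent oracles used across the suite: brute-force graph metrics
# (Floyd-Warshall distances, path-enumeration betweenness), a naive
# sort-based BH-FDR, a two-loop symmetric KL, and small fixture builders.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_cp <- function(adj) {
  n <- nrow(adj)
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  mean(cc)
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  f <- d[upper.tri(d)]
  f <- f[is.finite(f) & f > 0]
  if (length(f)) mean(f) else NA_real_
}

oracle_eg <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# betweenness by exhaustive enumeration of simple shortest paths
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    res <- list()
    rec <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1]] <<- path
        return(invisible())
      }
      if (length(path) - 1 >= d[s, t]) return(invisible())
      for (w in which(adj[v, ] == 1)) {
        if (!(w %in% path)) rec(c(path, w))
      }
    }
    rec(s)
    res
  }
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      sp <- Filter(function(p) length(p) - 1 == d[s, t], all_paths(s, t))
      if (!length(sp)) next
      for (v in setdiff(seq_len(n), c(s, t))) {
        cnt <- sum(vapply(sp, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + cnt / length(sp)
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cur <- Inf
  for (i in n:1) {
    cur <- min(cur, p[o[i]] * (n / i))
    adj[o[i]] <- min(1, cur)
  }
  adj
}

oracle_symkl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    s <- s + p[i] * log(p[i] / q[i]) + q[i] * log(q[i] / p[i])
  }
  s
}

# one-way ANOVA F by direct sums of squares
oracle_anova_f <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

# fixture builders -----------------------------------------------------------

graph_fixture <- function(adj, sparsity = NA_real_) {
  n <- nrow(adj)
  labels <- sprintf("V%02d", seq_len(n))
  dimnames(adj) <- list(labels, labels)
  storage.mode(adj) <- "integer"
  structure(list(labels = labels, adjacency = adj, sparsity = sparsity),
            class = "klsnet_graph")
}

random_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

random_similarity <- function(n, seed) {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2, 0.01, 0.99)
  v <- v + t(v)
  diag(v) <- 1
  dimnames(v) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
  new_similarity_matrix(v)
}

adhoc_sample_set <- function(n_roi = 5, n = 40, seed = 1) {
  set.seed(seed)
  samples <- lapply(seq_len(n_roi), function(i) rnorm(n, mean = i, sd = 1))
  names(samples) <- sprintf("roi%02d", seq_len(n_roi))
  roi_sample_set("TEST", NULL, NULL, samples)
}
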