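# Independent brute-force oracles used across the suite. These never call
# the package's own shortest-path or FDR code paths.

# all simple paths between s and t on a weighted graph (lengths 1/w)
oracle_paths <- function(w, s, t) {
  n <- nrow(w)
  res <- list()
  rec <- function(path, len) {
    v <- path[length(path)]
    if (v == t) {
      res[[length(res) + 1L]] <<- list(path = path, len = len)
      return()
    }
    for (u in seq_len(n)) {
      if (w[v, u] > 0 && !(u %in% path)) rec(c(path, u), len + 1 / w[v, u])
    }
  }
  rec(s, 0)
  res
}

oracle_betweenness <- function(w) {
  n <- nrow(w)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      ps <- oracle_paths(w, s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      sh <- ps[lens <= min(lens) * (1 + 1e-10)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        bc[v] <- bc[v] +
          mean(vapply(sh, function(p) v %in% p$path, logical(1)))
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_distance <- function(w, s, t) {
  ps <- oracle_paths(w, s, t)
  if (!length(ps)) return(Inf)
  min(vapply(ps, `[[`, numeric(1), "len"))
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(w[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- w[nb, nb, drop = FALSE]
    acc <- 0
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) acc <- acc + 2 / oracle_distance(sub, i, j)
    }
    out[v] <- acc / (k * (k - 1))
  }
  out
}

random_weighted_graph <- function(n, p_edge = 0.7) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, 0.1, 1)
    }
  }
  w
}

# literal Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
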