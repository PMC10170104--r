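# Independent oracles kept deliberately separate from the package code.

# Welch's t from the textbook formula, no stats::t.test involved.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Exhaustive hypergeometric tail: enumerate every size-n draw from 1..N,
# with 1..m the pathway members, and count draws with >= k hits.
hyper_oracle <- function(N, m, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= m) >= k)
}

# Brute-force relative betweenness: count, over all unordered pairs
# (s, t), the fraction of shortest s-t paths passing through v, then
# normalize by (n-1)(n-2)/2. Path enumeration by DFS over a BFS distance
# map; fine for <= 12 nodes.
betweenness_oracle <- function(members, edges) {
  n <- length(members)
  adj <- matrix(FALSE, n, n, dimnames = list(members, members))
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    adj[edges[i, 1], edges[i, 2]] <- TRUE
    adj[edges[i, 2], edges[i, 1]] <- TRUE
  }
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        nb <- which(adj[u, ] & is.infinite(d))
        d[nb] <- d[u] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d
  }
  all_paths <- function(s, t, d) {
    if (s == t) return(list(s))
    out <- list()
    for (u in which(adj[t, ] & d == d[t] - 1))
      for (p in all_paths(s, u, d)) out[[length(out) + 1]] <- c(p, t)
    out
  }
  cb <- stats::setNames(rep(0, n), members)
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(s)
    for (t in seq((s + 1), n)) {
      if (t <= s || is.infinite(d[t])) next
      paths <- all_paths(s, t, d)
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        cb[inner] <- cb[inner] + 1 / length(paths)
      }
    }
  }
  if (n <= 2) return(cb)
  cb / ((n - 1) * (n - 2) / 2)
}

path_def <- function(members, edges) {
  list(name = "toy", members = members,
       edges = if (length(edges)) matrix(edges, ncol = 2, byrow = TRUE)
       else matrix(character(), ncol = 2))
}
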