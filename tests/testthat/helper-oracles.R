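# Independent brute-force oracles. Everything here is written from first
# principles (explicit loops, exhaustive enumeration) and never calls the
# package's implementation paths.

oracle_rank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  if (den == 0) return(NA_real_)
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# all permutations of 1..n as rows (plain recursion)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# two-sided exhaustive permutation p-value for Spearman rho
oracle_spearman_perm_p <- function(x, y) {
  obs <- abs(oracle_spearman(x, y))
  pm <- oracle_perms(length(y))
  vals <- apply(pm, 1, function(idx) {
    r <- oracle_spearman(x, y[idx])
    if (is.na(r)) 0 else abs(r)
  })
  mean(vals >= obs - 1e-12)
}

# BFS shortest-path distances and path counts from one source
oracle_bfs <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# degree, raw betweenness (unordered pairs), component-corrected
# closeness, from explicit all-pairs BFS
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(adj, s))
  betw <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(bfs[[s]]$dist[t])) next
    d_st <- bfs[[s]]$dist[t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == d_st)
        betw[v] <- betw[v] +
          bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    dv <- bfs[[v]]$dist[-v]
    reach <- dv[is.finite(dv)]
    if (n == 1 || !length(reach)) return(0)
    nc <- length(reach) + 1
    ((nc - 1) / (n - 1)) * ((nc - 1) / sum(reach))
  }, numeric(1))
  list(degree = rowSums(adj), betweenness = betw, closeness = clo)
}

# dominant eigenvector of the adjacency, max-normalized, sign-fixed;
# meaningful on connected graphs
oracle_eigenvector <- function(adj) {
  ev <- eigen(adj, symmetric = TRUE)
  v <- ev$vectors[, 1]
  v <- v / v[which.max(abs(v))]
  v
}

oracle_modularity <- function(el, mem) {
  L <- nrow(el)
  q <- 0
  for (s in unique(mem)) {
    inside <- sum(mem[el[, 1]] == s & mem[el[, 2]] == s)
    dsum <- sum(mem[el[, 1]] == s) + sum(mem[el[, 2]] == s)
    q <- q + inside / L - (dsum / (2 * L))^2
  }
  q
}

oracle_zipi <- function(adj, mem) {
  n <- nrow(adj)
  within <- numeric(n); pi_v <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    within[i] <- sum(mem[nb] == mem[i])
    if (k > 0) pi_v[i] <- 1 - sum((table(mem[nb]) / k)^2)
  }
  zi <- numeric(n)
  for (s in unique(mem)) {
    idx <- which(mem == s)
    mu <- mean(within[idx])
    sd_p <- sqrt(mean((within[idx] - mu)^2))
    zi[idx] <- if (sd_p > 0) (within[idx] - mu) / sd_p else 0
  }
  list(zi = zi, pi = pi_v)
}

# Mann-Whitney U (first sample over second) by pair counting, exact
# two-sided p by exhaustive labeling enumeration
oracle_mw <- function(a, b, alternative = "two.sided") {
  U <- 0
  for (x in a) for (y in b) U <- U + (x > y) + 0.5 * (x == y)
  pooled <- c(a, b)
  combos <- utils::combn(length(pooled), length(a))
  null_U <- apply(combos, 2, function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    u <- 0
    for (x in aa) for (y in bb) u <- u + (x > y) + 0.5 * (x == y)
    u
  })
  mu <- length(a) * length(b) / 2
  p <- switch(alternative,
              two.sided = mean(abs(null_U - mu) >= abs(U - mu) - 1e-12),
              greater = mean(null_U >= U - 1e-12),
              less = mean(null_U <= U + 1e-12))
  list(U = U, p = p)
}

# all set partitions of 1..n via restricted growth strings
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# adjusted Rand index by pair counting
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  row_c <- sum_comb(rowSums(tab)); col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  maxi <- (row_c + col_c) / 2
  if (maxi == expected) return(1)
  (idx - expected) / (maxi - expected)
}
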