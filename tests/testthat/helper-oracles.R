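# Fixture builders and independent oracles. The oracles deliberately avoid
# the package's own code paths (and igraph): plain-R breadth-first search,
# recursive walk enumeration, triple-loop triangle censuses and dense
# linear solves.

mk_nodes <- function(ids, roles = "WHOLESALER", regions = "Central",
                     lat = 5, lon = -1, visited = TRUE) {
  data.frame(
    node_id = ids,
    name = paste("outlet", ids),
    role = rep_len(roles, length(ids)),
    latitude = rep_len(lat, length(ids)),
    longitude = rep_len(lon, length(ids)),
    region = rep_len(regions, length(ids)),
    visited = rep_len(visited, length(ids)),
    stringsAsFactors = FALSE
  )
}

mk_links <- function(buyers, suppliers, price = "UNSET") {
  data.frame(buyer_id = buyers, supplier_id = suppliers,
             price_category = rep_len(price, length(buyers)),
             stringsAsFactors = FALSE)
}

# chain R -> W -> S (retailer buys from wholesaler buys from importer)
chain_net <- function() {
  supply_network(
    mk_nodes(c("R", "W", "S"), roles = c("RETAILER", "WHOLESALER", "IMPORTER")),
    mk_links(c("R", "W"), c("W", "S"))
  )
}

# Erdos-Renyi-style random digraph as a supply_network; roles optional
random_digraph <- function(n, p = 0.3, seed = 1, loops = FALSE,
                           roles = "WHOLESALER") {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- expand.grid(b = ids, s = ids, stringsAsFactors = FALSE)
  if (!loops) pairs <- pairs[pairs$b != pairs$s, ]
  keep <- runif(nrow(pairs)) < p
  supply_network(mk_nodes(ids, roles = roles),
                 mk_links(pairs$b[keep], pairs$s[keep]))
}

# random layered DAG with retailer/importer roles for chain statistics
random_dag <- function(n_per_level = c(2, 3, 3), p = 0.6, seed = 1) {
  set.seed(seed)
  lv <- rep(seq_along(n_per_level) - 1, n_per_level)
  ids <- sprintf("d%02d", seq_along(lv))
  roles <- ifelse(lv == 0, "IMPORTER",
                  ifelse(lv == max(lv), "RETAILER", "WHOLESALER"))
  b <- character(0); s <- character(0)
  for (i in seq_along(ids)) {
    lower <- which(lv < lv[i])
    if (length(lower) == 0) next
    pick <- lower[runif(length(lower)) < p]
    if (length(pick) == 0) pick <- sample(lower, 1)
    b <- c(b, rep(ids[i], length(pick))); s <- c(s, ids[pick])
  }
  supply_network(mk_nodes(ids, roles = roles), mk_links(b, s))
}

dense_adj <- function(net) as.matrix(adjacency_matrix(net))

# walks of length n from i to j, by recursive enumeration
count_walks_oracle <- function(A, n, i, j) {
  if (n == 1) return(A[i, j])
  sum(vapply(seq_len(nrow(A)), function(m) {
    if (A[i, m] == 0) 0 else A[i, m] * count_walks_oracle(A, n - 1, m, j)
  }, numeric(1)))
}

# closed walks of length n avoiding self-loops (n > 1); self-loop count
# for n = 1 -- the loop statistic the trace computes
closed_walks_oracle <- function(A, n) {
  if (n == 1) return(sum(diag(A)))
  diag(A) <- 0
  sum(vapply(seq_len(nrow(A)), function(i) count_walks_oracle(A, n, i, i),
             numeric(1)))
}

# single-source BFS distances over an adjacency matrix (0/1)
bfs_dist_oracle <- function(A, start) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(A[u, ] > 0)) {
        if (dist[v] > d) {
          dist[v] <- d
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# chain statistics recomputed from scratch with the BFS oracle
chain_stats_oracle <- function(net) {
  A <- dense_adj(net)
  diag(A) <- 0
  ids <- net$nodes$node_id
  tops <- which(rowSums(A) == 0)
  rets <- which(net$nodes$role %in% c("RETAILER", "PHARMACY_WHOLESALER"))
  lens <- numeric(0)
  for (r in rets) {
    dist <- bfs_dist_oracle(A, r)
    for (t in setdiff(tops, r)) {
      if (is.finite(dist[t]) && dist[t] >= 1) lens <- c(lens, dist[t])
    }
  }
  Afull <- dense_adj(net)
  n_direct <- 0
  for (r in rets) for (t in setdiff(tops, r)) {
    n_direct <- n_direct + (Afull[r, t] > 0)
  }
  list(l_max = max(lens), l_min = min(lens), l_avg = mean(lens),
       n_direct = n_direct, pair_count = length(lens))
}

# triangle census by triple loop; returns the directed and undirected
# local coefficients under both directed conventions
clustering_census_oracle <- function(net) {
  A <- dense_adj(net)
  diag(A) <- 0
  A <- (A > 0) * 1
  n <- nrow(A)
  S <- A + t(A)
  U <- (S > 0) * 1
  T_dir <- numeric(n); L_und <- numeric(n)
  for (u in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != u && h != u && j != h) acc <- acc + S[u, j] * S[j, h] * S[h, u]
    }
    T_dir[u] <- acc / 2
    nb <- which(U[u, ] > 0)
    cnt <- 0
    if (length(nb) >= 2) {
      for (j in nb) for (h in nb) if (j < h) cnt <- cnt + U[j, h]
    }
    L_und[u] <- cnt
  }
  deg_tot <- rowSums(A) + colSums(A)
  deg_bi <- rowSums(A * t(A))
  d_und <- rowSums(U)
  denom_d <- deg_tot * (deg_tot - 1) - 2 * deg_bi
  denom_u <- d_und * (d_und - 1)
  list(
    directed_fagiolo = ifelse(denom_d > 0, T_dir / denom_d, 0),
    directed_printed = ifelse(denom_d > 0, T_dir / (2 * denom_d), 0),
    undirected = ifelse(denom_u > 0, 2 * L_und / denom_u, 0)
  )
}

# PageRank by dense linear solve: teleport (1-d)/N, dangling mass uniform
pagerank_solve_oracle <- function(net, d = 0.85) {
  A <- dense_adj(net)
  n <- nrow(A)
  C <- rowSums(A)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    P[i, ] <- if (C[i] == 0) rep(1 / n, n) else A[i, ] / C[i]
  }
  x <- solve(diag(n) - d * t(P), rep((1 - d) / n, n))
  stats::setNames(as.numeric(x), net$nodes$node_id)
}
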