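test_that("two-node PageRank matches the dangling-aware linear solve", {
  net <- supply_network(mk_nodes(c("A", "B")), mk_links("A", "B"))
  pr <- pagerank(net)
  expect_true(pr$converged)
  expect_equal(unname(pr$scores["A"]), 0.350877, tolerance = 1e-4)
  expect_equal(unname(pr$scores["B"]), 0.649123, tolerance = 1e-4)
  expect_equal(pr$scores, pagerank_solve_oracle(net), tolerance = 1e-8)
})

test_that("an edgeless network ranks every node equally", {
  net <- supply_network(mk_nodes(paste0("n", 1:7)), data.frame())
  pr <- pagerank(net)
  expect_equal(unname(pr$scores), rep(1 / 7, 7), tolerance = 1e-12)
  expect_equal(sum(pr$scores), 1, tolerance = 1e-9)
})

test_that("power iteration equals the dense linear solve on random networks", {
  sizes <- c(5, 12, 21, 33, 42, 50)
  for (seed in 1:6) {
    net <- random_digraph(sizes[seed], p = 0.15, seed = seed, loops = TRUE)
    pr <- pagerank(net)
    expect_equal(sum(pr$scores), 1, tolerance = 1e-9)
    expect_equal(pr$scores, pagerank_solve_oracle(net), tolerance = 1e-8)
  }
})

test_that("normalised PageRank agrees with an established implementation", {
  net <- generate_network(ghana_like_preset(seed = 6))
  pr <- pagerank(net)
  g <- supplynet:::as_igraph(net)
  ref <- igraph::page_rank(g, damping = 0.85)$vector
  expect_equal(unname(pr$scores[names(ref)]), unname(ref), tolerance = 1e-6)
})

test_that("the literal recursive variant solves its fixed point", {
  # cycle with no dangling nodes: scores sum to the node count
  cyc <- supply_network(mk_nodes(c("A", "B", "C")),
                        mk_links(c("A", "B", "C"), c("B", "C", "A")))
  pr <- pagerank(cyc, variant = "eq1_literal")
  expect_equal(sum(pr$scores), 3, tolerance = 1e-6)
  expect_equal(unname(pr$scores), rep(1, 3), tolerance = 1e-8)
  # fixed-point residual is zero: PR(A) = (1-d) + d * sum(PR(N)/C(N))
  net <- random_digraph(10, p = 0.3, seed = 2)
  pr <- pagerank(net, variant = "eq1_literal")
  A <- dense_adj(net)
  C <- rowSums(A)
  inflow <- as.numeric(t(A) %*% ifelse(C == 0, 0, pr$scores / pmax(C, 1)))
  expect_equal(unname(pr$scores), 0.15 + 0.85 * inflow, tolerance = 1e-8)
})

test_that("relabelling nodes permutes PageRank scores identically", {
  net <- random_digraph(12, p = 0.25, seed = 8)
  pr <- pagerank(net)
  perm <- sample(seq_len(12))
  nodes2 <- net$nodes[perm, ]
  net2 <- supply_network(nodes2, net$links)
  pr2 <- pagerank(net2)
  expect_equal(pr2$scores[names(pr$scores)], pr$scores, tolerance = 1e-12)
})

test_that("local clustering matches hand values on canonical motifs", {
  # undirected complete triangle
  tri <- supply_network(
    mk_nodes(c("A", "B", "C")),
    mk_links(c("A", "B", "C", "B", "C", "A"), c("B", "C", "A", "A", "B", "C"))
  )
  expect_equal(unname(local_clustering(tri, mode = "undirected")), rep(1, 3))

  # directed 3-cycle: the printed equation gives 1/4, Fagiolo 1/2
  cyc <- supply_network(mk_nodes(c("A", "B", "C")),
                        mk_links(c("A", "B", "C"), c("B", "C", "A")))
  expect_equal(unname(local_clustering(cyc, convention = "printed")),
               rep(0.25, 3))
  expect_equal(unname(local_clustering(cyc, convention = "fagiolo")),
               rep(0.5, 3))

  # chain: no triangle through the middle node
  expect_equal(unname(local_clustering(chain_net())["W"]), 0)
  expect_error(local_clustering(chain_net(), nodes = "nope"), "unknown")
})

test_that("directed clustering equals the triangle census on random digraphs", {
  for (seed in 1:50) {
    net <- random_digraph(4 + (seed %% 7), p = 0.35, seed = seed, loops = TRUE)
    want <- clustering_census_oracle(net)
    expect_identical(unname(local_clustering(net, convention = "fagiolo")),
                     unname(want$directed_fagiolo))
    expect_identical(unname(local_clustering(net, convention = "printed")),
                     unname(want$directed_printed))
    expect_identical(unname(local_clustering(net, mode = "undirected")),
                     unname(want$undirected))
  }
})

test_that("directed and undirected clustering coincide on symmetric networks", {
  for (seed in 1:5) {
    net <- random_digraph(8, p = 0.3, seed = seed)
    lp <- supplynet:::link_pairs(net)
    sym <- supply_network(net$nodes,
                          mk_links(c(lp$buyer_id, lp$supplier_id),
                                   c(lp$supplier_id, lp$buyer_id)))
    expect_equal(local_clustering(sym, mode = "directed", convention = "fagiolo"),
                 local_clustering(sym, mode = "undirected"),
                 tolerance = 1e-12)
  }
})

test_that("a lone transitive triad in a DAG matches the census exactly", {
  ids <- paste0("n", 1:10)
  net <- supply_network(
    mk_nodes(ids),
    mk_links(c("n1", "n1", "n2", "n4", "n5", "n6", "n7", "n8"),
             c("n2", "n3", "n3", "n5", "n6", "n7", "n8", "n9"))
  )
  want <- clustering_census_oracle(net)
  expect_identical(unname(local_clustering(net)), unname(want$directed_fagiolo))
  expect_equal(average_clustering(net), mean(want$directed_fagiolo))
  # every node outside the triad has zero clustering
  cl <- local_clustering(net)
  expect_true(all(cl[paste0("n", 4:10)] == 0))
})

test_that("tree-like networks have zero clustering everywhere", {
  net <- random_dag(c(1, 2, 4), p = 0, seed = 1)  # every node one supplier
  expect_equal(average_clustering(net), 0)
})

test_that("node ranking is ordered, tie-broken and carries in-degree", {
  net <- supply_network(
    mk_nodes(c("A", "B", "C")),
    mk_links(c("A", "B"), c("B", "C"))
  )
  pr <- pagerank(net)
  rk <- rank_nodes(pr, net)
  expect_equal(rk$node_id, names(sort(pr$scores, decreasing = TRUE)))
  expect_equal(rk$in_degree[rk$node_id == "C"], 1)

  # equal scores fall back to id order
  iso <- supply_network(mk_nodes(c("Z", "A", "M")), data.frame())
  rk <- rank_nodes(pagerank(iso), iso)
  expect_equal(rk$node_id, c("A", "M", "Z"))
})
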