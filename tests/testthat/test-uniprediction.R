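nbhd_methods <- c("common_neighbors", "jaccard", "cosine", "hpi", "hdi",
                  "adamic_adar", "pref_attach", "resource_alloc", "lhn")

test_that("neighborhood indices match hand-enumerated neighbor sets", {
  g4 <- cycle4()
  vals <- sapply(nbhd_methods, function(m)
    neighborhood_score(g4, m)$values["a", "c"])
  expect_equal(unname(vals[c("common_neighbors", "jaccard", "resource_alloc",
                             "pref_attach", "lhn", "hpi")]),
               c(2, 1.0, 1.0, 4, 0.5, 1.0))
  g3 <- path3()
  expect_equal(neighborhood_score(g3, "common_neighbors")$values["a", "c"], 1)
  expect_equal(neighborhood_score(g3, "cosine")$values["a", "c"], 1.0)
  expect_equal(neighborhood_score(g3, "hdi")$values["a", "c"], 1.0)
})

test_that("neighborhood indices are symmetric, zero across components, no NaN", {
  set.seed(42)
  for (rep in 1:10) {
    g <- random_er_graph(sample(5:15, 1), 0.25)
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(g$adjacency, "undirected"))$membership
    for (m in nbhd_methods) {
      S <- neighborhood_score(g, m)$values
      expect_false(any(is.na(S)))
      expect_equal(S, t(S))
      # preferential attachment is degree-only and ignores connectivity;
      # every overlap-based index vanishes across components
      if (m != "pref_attach") {
        cross <- outer(comp, comp, "!=")
        expect_true(all(S[cross] == 0))
      }
    }
  }
})

test_that("neighborhood indices equal the set-based brute force on random graphs", {
  set.seed(3)
  for (rep in 1:15) {
    g <- random_er_graph(sample(4:12, 1), 0.35)
    pairs <- which(upper.tri(g$adjacency), arr.ind = TRUE)
    for (m in nbhd_methods) {
      S <- neighborhood_score(g, m)$values
      for (r in seq_len(nrow(pairs))) {
        x <- pairs[r, 1]; y <- pairs[r, 2]
        expect_equal(S[x, y], unname(oracle_neighborhood(g, m, x, y)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("local-path index counts 2- and 3-paths with epsilon weighting", {
  eps <- 0.01
  expect_equal(local_path_score(path3(), eps)$values["a", "c"], 1)
  # A^3 counts length-3 walks: a-b-a-b, a-b-c-b, a-d-a-b, a-d-c-b
  expect_equal(local_path_score(cycle4(), eps)$values["a", "b"], 4 * eps)
  # epsilon = 0 reduces to common neighbors off the diagonal
  set.seed(5)
  g <- random_er_graph(10, 0.3)
  S0 <- local_path_score(g, 0)$values
  CN <- neighborhood_score(g, "common_neighbors")$values
  off <- row(S0) != col(S0)
  expect_equal(S0[off], CN[off])
})

test_that("Katz resolvent matches closed form, series, and monotonicity", {
  g <- ugraph(list(c("a", "b")))
  expect_equal(katz_score(g, 0.1)$values["a", "b"], 0.1 / (1 - 0.01),
               tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:5) {
    gr <- random_er_graph(8, 0.4)
    rho <- max(abs(eigen(gr$adjacency, only.values = TRUE)$values))
    beta <- 0.5 / max(rho, 1)
    expect_equal(katz_score(gr, beta)$values, oracle_katz_series(gr, beta),
                 tolerance = 1e-8, ignore_attr = TRUE)
    S_lo <- katz_score(gr, beta / 2)$values
    expect_true(all(katz_score(gr, beta)$values - S_lo >= -1e-12))
    expect_error(katz_score(gr, 1 / max(rho, 1e-9) + 1), "diverges")
  }
})

test_that("geodesic score is reciprocal shortest-path distance", {
  g <- path3()
  expect_equal(geodesic_score(g)$values["a", "c"], 1 / 2)
  expect_equal(geodesic_score(g)$values["a", "b"], 1)
  two <- ugraph(list(c("a", "b")), nodes = c("a", "b", "z"))
  expect_equal(geodesic_score(two)$values["a", "z"], 0)
})

test_that("hitting times solve the first-step equations exactly", {
  H <- hitting_time(path3())$values
  expect_equal(unname(c(H["a", "b"], H["b", "c"], H["a", "c"])), c(1, 3, 4))
  # additivity through the middle of a path
  expect_equal(H["a", "c"], H["a", "b"] + H["b", "c"])
  e <- hitting_time(ugraph(list(c("a", "b"))))$values
  expect_equal(unname(c(e["a", "b"], e["b", "a"])), c(1, 1))
  # cross-component sentinel
  two <- ugraph(list(c("a", "b"), c("c", "d")))
  expect_equal(hitting_time(two)$values["a", "c"], Inf)
})

test_that("exact hitting times agree with a Monte-Carlo walk", {
  g <- ugraph(list(c("a", "b"), c("b", "c"), c("c", "d"), c("b", "d")))
  H <- hitting_time(g)$values
  set.seed(123)
  mc <- simulate_hitting(g, "a", "d", n_walks = 20000L)
  expect_lt(abs(H["a", "d"] - mc["mean"]), 3.5 * mc["se"])
})

test_that("unipartite RWR reaches its fixed point with probability columns", {
  g <- ugraph(list(c("a", "b")))
  p <- rwr_unipartite(g, c = 0.5)$values[, "a"]
  expect_equal(unname(p), c(2 / 3, 1 / 3), tolerance = 1e-8)
  set.seed(21)
  gr <- random_er_graph(12, 0.3)
  c0 <- 0.3
  P <- rwr_unipartite(gr, c = c0)$values
  expect_equal(unname(colSums(P)), rep(1, 12), tolerance = 1e-8)
  expect_true(all(P >= 0))
  # defining equation residual
  W <- gr$adjacency / pmax(rowSums(gr$adjacency), 1)
  W[rowSums(gr$adjacency) == 0, ] <- 0
  diag(W)[rowSums(gr$adjacency) == 0] <- 1
  for (s in 1:12) {
    e <- rep(0, 12); e[s] <- 1
    expect_lt(sum(abs(P[, s] - (1 - c0) * t(W) %*% P[, s] - c0 * e)), 1e-7)
  }
  # near-total restart keeps the walker home
  expect_gt(rwr_unipartite(g, c = 0.999)$values["a", "a"], 0.99)
  expect_error(rwr_unipartite(gr, c = 0.3, max_iter = 1L), "converge")
})

test_that("unipartite ranking excludes the diagonal and flags known edges", {
  g <- path3()
  tab <- rank_unipartite(g, neighborhood_score(g, "common_neighbors"))
  expect_equal(nrow(tab), 3L)   # 3 unordered pairs
  expect_setequal(tab$known_edge[tab$node_a == "a" & tab$node_b == "b"], TRUE)
  expect_equal(tab$score[1], 1)  # (a,c) shares b
  expect_false(tab$known_edge[1])
})
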