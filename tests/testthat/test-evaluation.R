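test_that("rank metrics reproduce hand-computed values and reject degeneracy", {
  m <- rank_metrics(c(1, 2), 10)
  expect_equal(unname(m["auc"]), 1.0)
  expect_equal(unname(m["ef"]), 5.0)
  expect_equal(unname(m["auac"]), 1 - (0.1 + 0.2) / 2)
  worst <- rank_metrics(c(9, 10), 10)
  expect_equal(unname(worst["auc"]), 0.0)
  # near-perfect early recognition saturates BEDROC
  good <- rank_metrics(1:5, 1000, alpha = 20)
  expect_lt(abs(good["bedroc"] - 1), 1e-3)
  expect_error(rank_metrics(integer(0), 10), "undefined")
  expect_error(rank_metrics(1:10, 10), "undefined")
  expect_error(rank_metrics(c(2, 1), 10), "increasing")
})

test_that("rank metrics agree with curve-walking and pairwise-count oracles", {
  set.seed(12)
  for (rep in 1:60) {
    N <- sample(20:200, 1)
    n <- sample(1:(min(N - 1, 30)), 1)
    ranks <- sort(sample(N, n))
    alpha <- sample(c(5, 20, 50), 1)
    chi <- sample(c(0.05, 0.1, 0.25), 1)
    got <- rank_metrics(ranks, N, alpha = alpha, chi = chi)
    expect_equal(unname(got["auc"]), oracle_auc_pairs(ranks, N),
                 tolerance = 1e-12)
    oc <- oracle_curve_metrics(ranks, N, alpha, chi)
    expect_equal(unname(got["auac"]), unname(oc["auac"]), tolerance = 1e-12)
    expect_equal(unname(got["auctop"]), unname(oc["auctop"]),
                 tolerance = 1e-12)
    expect_equal(unname(got["ef"]), unname(oc["ef"]), tolerance = 1e-12)
    expect_equal(unname(got["bedroc"]), unname(oc["bedroc"]),
                 tolerance = 1e-9)
  }
})

test_that("link removal hides floor(fraction*m) edges and partitions the edge set", {
  set.seed(2)
  net <- random_bipartite(11, 12, 0.34, min_edges = 44)
  # trim to exactly 44 interactions for the benchmark-scale arithmetic
  A <- net$adjacency
  ones <- which(A > 0)
  A[ones[-seq_len(44)]] <- 0
  net <- bipartite_network(A)
  sp <- remove_links(net, 0.2, seed = 5)
  expect_equal(nrow(sp$hidden), 8L)   # floor(0.2 * 44)
  expect_equal(n_edges(sp$training), 36L)
  # partition contract
  hid_idx <- cbind(match(sp$hidden$target, net$target_labels),
                   match(sp$hidden$drug, net$drug_labels))
  expect_true(all(net$adjacency[hid_idx] == 1))
  expect_true(all(sp$training$adjacency[hid_idx] == 0))
  expect_equal(sp$training$adjacency + replace(net$adjacency * 0, hid_idx, 1),
               net$adjacency)
  # determinism
  sp2 <- remove_links(net, 0.2, seed = 5)
  expect_identical(sp$training$adjacency, sp2$training$adjacency)
  # degree-weighted mode runs and still partitions
  spd <- remove_links(net, 0.2, weighting = "degree", seed = 5)
  expect_equal(nrow(spd$hidden), 8L)
  # degenerate removals are refused
  tiny <- toy_net()
  expect_error(remove_links(tiny, 0.2), "larger fraction")
  expect_error(remove_links(tiny, 1.0), "fraction")
})

test_that("benchmark reports per-repetition metrics, reproducibly", {
  st <- gen_study(n_drugs = 15, n_targets = 12, n_modules = 3,
                  p_in = 0.6, p_out = 0.05, seed = 3)
  r1 <- benchmark(st$net, st$drug_sim, st$target_sim, algo = "nbi",
                  fraction = 0.2, reps = 3, seed = 11)
  r2 <- benchmark(st$net, st$drug_sim, st$target_sim, algo = "nbi",
                  fraction = 0.2, reps = 3, seed = 11)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$per_rep), 3L)
  expect_equal(unname(r1$mean["auc"]), mean(r1$per_rep$auc))
  expect_true(all(r1$per_rep$auc >= 0 & r1$per_rep$auc <= 1))
  expect_true(all(r1$per_rep$bedroc >= 0 & r1$per_rep$bedroc <= 1))
  expect_true(all(r1$per_rep$ef >= 0))
})

test_that("an uninformative random scorer hovers at chance AUC", {
  set.seed(14)
  net <- random_bipartite(15, 15, 0.25, min_edges = 20)
  aucs <- sapply(1:10, function(r) {
    sp <- remove_links(net, 0.2, seed = r)
    rand <- netlinkpred:::score_matrix_b(
      matrix(runif(225), 15, 15,
             dimnames = dimnames(net$adjacency)), "random")
    ar <- netlinkpred:::active_ranks(sp$training, sp$hidden, rand)
    rank_metrics(ar$ranks, ar$N)["auc"]
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("checkerboard rewiring preserves both degree sequences", {
  set.seed(23)
  net <- random_bipartite(10, 12, 0.3, min_edges = 15)
  A <- net$adjacency
  Ap <- netlinkpred:::with_seed(9,
    netlinkpred:::checkerboard_sweep(A, 50L, max_attempts = 1e5))
  expect_identical(rowSums(Ap), rowSums(A))
  expect_identical(colSums(Ap), colSums(A))
  expect_false(identical(Ap, A))
  expect_true(all(Ap %in% c(0, 1)))
})

test_that("permutation test yields calibrated columns and sentinel p", {
  st <- gen_study(n_drugs = 10, n_targets = 8, n_modules = 2,
                  p_in = 0.6, p_out = 0.1, seed = 6)
  res <- permutation_test(st$net, st$drug_sim, st$target_sim, algo = "nbi",
                          n_perm = 30, seed = 2)
  tab <- res$table
  expect_equal(nrow(tab), 80L)
  expect_true(all(tab$p > 0 & tab$p < 1))
  expect_true(all(tab$q >= tab$p - 1e-12))
  sd0 <- tab$perm_sd == 0
  if (any(sd0)) expect_true(all(tab$p[sd0] == 0.5))
  chk <- tab$perm_sd > 0
  expect_equal(tab$z[chk],
               (tab$score[chk] - tab$perm_mean[chk]) / tab$perm_sd[chk],
               tolerance = 1e-12)
  # p_keep filters
  res5 <- permutation_test(st$net, st$drug_sim, st$target_sim, algo = "nbi",
                           n_perm = 30, seed = 2, p_keep = 0.5)
  expect_true(all(res5$table$p <= 0.5))
  # fully constrained networks cannot be rewired
  cb <- bipartite_network(matrix(1, 3, 3,
    dimnames = list(sprintf("t%d", 1:3), sprintf("d%d", 1:3))))
  expect_error(
    permutation_test(cb, algo = "nbi", n_perm = 20, seed = 1),
    "checkerboard")
})
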