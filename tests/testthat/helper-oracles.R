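# Independent oracles and fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths: explicit set
# operations, exhaustive enumeration, curve walking, simulation.

# --- fixture builders -------------------------------------------------

labelled <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  m
}

ugraph <- function(edges, nodes = NULL, weights = NULL) {
  # edges: list of c(a, b); builds a unipartite_graph
  nodes <- if (is.null(nodes)) sort(unique(unlist(edges))) else nodes
  A <- labelled(matrix(0, length(nodes), length(nodes)), nodes)
  for (i in seq_along(edges)) {
    w <- if (is.null(weights)) 1 else weights[i]
    A[edges[[i]][1], edges[[i]][2]] <- w
    A[edges[[i]][2], edges[[i]][1]] <- w
  }
  unipartite_graph(A)
}

toy_net <- function() {
  # edges d1-t1, d1-t2, d2-t2
  A <- matrix(c(1, 1, 0, 1), 2, 2,
              dimnames = list(c("t1", "t2"), c("d1", "d2")))
  bipartite_network(A)
}

path3 <- function() ugraph(list(c("a", "b"), c("b", "c")))

cycle4 <- function() ugraph(list(c("a", "b"), c("b", "c"),
                                 c("c", "d"), c("d", "a")))

random_er_graph <- function(n, p) {
  labels <- sprintf("v%02d", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  up <- which(upper.tri(A))
  A[up] <- stats::rbinom(length(up), 1L, p)
  A <- A + t(A)
  unipartite_graph(A)
}

random_weighted_graph <- function(n, p) {
  g <- random_er_graph(n, p)
  A <- g$adjacency
  up <- which(upper.tri(A) & A > 0)
  # multiples of 1/4: binary-exact weights, so equal path lengths compare
  # exactly and tie-ordering is well defined
  A[up] <- sample(seq(0.5, 3, by = 0.25), length(up), replace = TRUE)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  unipartite_graph(A, weighted = TRUE)
}

random_bipartite <- function(nt, nd, p, min_edges = 1L) {
  repeat {
    A <- matrix(stats::rbinom(nt * nd, 1L, p), nt, nd,
                dimnames = list(sprintf("t%02d", seq_len(nt)),
                                sprintf("d%02d", seq_len(nd))))
    if (sum(A) >= min_edges) return(bipartite_network(A))
  }
}

# --- neighborhood oracle: explicit neighbor sets ----------------------

oracle_neighborhood <- function(g, method, x, y) {
  A <- (g$adjacency > 0) * 1
  gx <- which(A[x, ] > 0)
  gy <- which(A[y, ] > 0)
  C <- intersect(gx, gy)
  kx <- length(gx); ky <- length(gy)
  deg <- rowSums(A)
  ratio <- function(num, den) if (den == 0) 0 else num / den
  switch(method,
    common_neighbors = length(C),
    jaccard = ratio(length(C), length(union(gx, gy))),
    cosine = ratio(length(C), sqrt(kx * ky)),
    hpi = ratio(length(C), min(kx, ky)),
    hdi = ratio(length(C), max(kx, ky)),
    adamic_adar = sum(vapply(C, function(z)
      if (deg[z] >= 2) 1 / log(deg[z]) else 0, 0)),
    pref_attach = kx * ky,
    resource_alloc = sum(vapply(C, function(z)
      if (deg[z] > 0) 1 / deg[z] else 0, 0)),
    lhn = ratio(length(C), kx * ky))
}

# --- Katz truncated-series oracle -------------------------------------

oracle_katz_series <- function(g, beta, L = 30L) {
  A <- (g$adjacency > 0) * 1
  S <- matrix(0, nrow(A), ncol(A))
  P <- diag(nrow(A))
  for (l in seq_len(L)) {
    P <- P %*% A
    S <- S + beta^l * P
  }
  S
}

# --- exhaustive loopless-path enumeration (DFS) -----------------------

enumerate_paths <- function(g, source, sink) {
  W <- if (g$weighted) g$adjacency else (g$adjacency > 0) * 1
  labels <- g$labels
  out <- list()
  walk <- function(path, len) {
    cur <- path[length(path)]
    if (cur == sink) {
      out[[length(out) + 1L]] <<- list(nodes = path, length = len)
      return()
    }
    for (v in labels[W[cur, ] > 0])
      if (!v %in% path) walk(c(path, v), len + W[cur, v])
  }
  walk(source, 0)
  # sort by (length, lexicographic node sequence)
  keys <- vapply(out, function(p) paste(p$nodes, collapse = "|"), "")
  lens <- vapply(out, `[[`, 0, "length")
  out[order(lens, keys)]
}

# --- rank-metric oracles ----------------------------------------------

# Mann-Whitney pairwise concordance count
oracle_auc_pairs <- function(ranks, N) {
  act <- rep(FALSE, N); act[ranks] <- TRUE
  conc <- 0
  for (i in which(act)) conc <- conc + sum(!act[-seq_len(i)])
  conc / (sum(act) * sum(!act))
}

# walk the accumulation / ROC curves explicitly
oracle_curve_metrics <- function(ranks, N, alpha, chi) {
  n <- length(ranks)
  act <- rep(FALSE, N); act[ranks] <- TRUE
  # AUAC: area under the accumulation (position vs recall) curve,
  # left-endpoint rectangle rule
  recall_at <- cumsum(act) / n
  auac <- mean(c(0, recall_at[-N]))
  n_top <- ceiling(chi * N)
  # pessimistic truncated list: top rows, then leftover inactives,
  # then missed actives
  mod_order <- c(act[seq_len(n_top)],
                 rep(FALSE, sum(!act) - sum(!act[seq_len(n_top)])),
                 rep(TRUE, n - sum(act[seq_len(n_top)])))
  conc <- 0
  for (i in which(mod_order)) conc <- conc + sum(!mod_order[-seq_len(i)])
  auctop <- conc / (n * (N - n))
  ef <- (sum(act[seq_len(n_top)]) / n_top) / (n / N)
  # BEDROC via explicit min-max rescaling of RIE (independent route from
  # the closed-form scaling used by the implementation)
  rie <- function(r) sum(exp(-alpha * r / N)) /
    ((n / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  Ra <- n / N
  rie_min_c <- (1 - exp(alpha * Ra)) / (Ra * (1 - exp(alpha)))
  rie_max_c <- (1 - exp(-alpha * Ra)) / (Ra * (1 - exp(-alpha)))
  bedroc <- (rie(ranks) - rie_min_c) / (rie_max_c - rie_min_c)
  c(auac = auac, auctop = auctop, ef = ef, bedroc = bedroc)
}

# --- Barber modularity brute force ------------------------------------

oracle_barber <- function(net, part) {
  A <- net$adjacency
  m <- sum(A)
  kt <- rowSums(A); kd <- colSums(A)
  q <- 0
  for (l in seq_len(nrow(A)))
    for (i in seq_len(ncol(A)))
      if (part$target_module[net$target_labels[l]] ==
          part$drug_module[net$drug_labels[i]])
        q <- q + A[l, i] - kt[l] * kd[i] / m
  unname(q / m)
}

# --- random-walk simulation oracle for hitting times ------------------

simulate_hitting <- function(g, x, y, n_walks = 20000L, cap = 10000L) {
  A <- (g$adjacency > 0) * 1
  nbrs <- lapply(seq_len(nrow(A)), function(i) which(A[i, ] > 0))
  xi <- match(x, g$labels); yi <- match(y, g$labels)
  steps <- integer(n_walks)
  for (w in seq_len(n_walks)) {
    cur <- xi; s <- 0L
    while (cur != yi && s < cap) {
      nb <- nbrs[[cur]]
      cur <- nb[sample.int(length(nb), 1L)]
      s <- s + 1L
    }
    steps[w] <- s
  }
  c(mean = mean(steps), se = stats::sd(steps) / sqrt(n_walks))
}
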