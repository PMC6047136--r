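# Top-K loopless shortest paths: hand-written Dijkstra with a
# lexicographic tie-break (determinism the tests rely on) and Yen's
# spur-node construction on top of it.

path_result <- function(nodes, length) {
  structure(list(nodes = nodes, length = length,
                 found = length(nodes) > 0L),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$found) cat("No path\n")
  else cat(sprintf("Path (length %g): %s\n", x$length,
                   paste(x$nodes, collapse = " -> ")))
  invisible(x)
}

# TRUE if path a is lexicographically smaller than b (node sequences)
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Dijkstra from source restricted to `allowed` nodes, with `blocked`
# edges (2-column label matrix) removed. Among equal-length shortest
# paths the lexicographically smallest node sequence wins; with strictly
# positive weights, predecessors finalize before their successors, so a
# per-node best-path comparison suffices.
dijkstra_lex <- function(adj, labels, source, sink, weighted,
                         allowed = NULL, blocked = NULL) {
  n <- length(labels)
  src <- match(source, labels)
  snk <- match(sink, labels)
  W <- if (weighted) adj else (adj > 0) * 1
  if (any(W < 0)) stop_format("negative edge weights are not allowed")
  if (!is.null(allowed)) {
    drop <- !(labels %in% allowed)
    W[drop, ] <- 0
    W[, drop] <- 0
  }
  if (!is.null(blocked) && nrow(blocked) > 0L) {
    W[blocked] <- 0
    W[blocked[, 2:1, drop = FALSE]] <- 0
  }
  dist <- rep(Inf, n)
  paths <- vector("list", n)
  dist[src] <- 0
  paths[[src]] <- labels[src]
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0L) break
    u <- cand[which.min(dist[cand])]
    if (u == snk) break
    done[u] <- TRUE
    for (v in which(W[u, ] > 0)) {
      if (done[v]) next
      nd <- dist[u] + W[u, v]
      np <- c(paths[[u]], labels[v])
      if (nd < dist[v] || (nd == dist[v] && lex_less(np, paths[[v]]))) {
        dist[v] <- nd
        paths[[v]] <- np
      }
    }
  }
  if (!is.finite(dist[snk])) return(path_result(character(0), Inf))
  path_result(paths[[snk]], dist[snk])
}

#' Shortest path between two nodes
#'
#' Dijkstra's algorithm on non-negative edge weights (hop counts when the
#' graph is unweighted). Among equal-length shortest paths the
#' lexicographically smallest node sequence is returned, making results
#' deterministic. An unreachable sink yields a no-path result
#' (`found = FALSE`, length `Inf`) rather than an error.
#'
#' @param g a [unipartite_graph()].
#' @param source,sink node labels in `g`.
#' @return A `path_result` with fields `nodes`, `length`, `found`.
#' @export
shortest_path <- function(g, source, sink) {
  check_endpoints(g, source, sink)
  if (source == sink) return(path_result(source, 0))
  dijkstra_lex(g$adjacency, g$labels, source, sink, g$weighted)
}

check_endpoints <- function(g, source, sink) {
  for (v in c(source, sink))
    if (!v %in% g$labels)
      stop_format(sprintf("node '%s' is not in the graph", v))
}

#' Yen's K shortest loopless paths
#'
#' Enumerates the K loopless (simple) paths of smallest total length in
#' nondecreasing order, ties ordered lexicographically by node sequence.
#' Candidates are generated by deviating at each spur node of the previous
#' path with the root prefix's nodes and previously used continuation
#' edges masked; duplicates arising from different spur nodes are merged.
#' Fewer than K paths are returned when the graph has fewer.
#'
#' @param g a [unipartite_graph()].
#' @param source,sink node labels in `g`.
#' @param K number of paths requested (at least 1).
#' @return A list of `path_result` objects, possibly empty.
#' @export
yen_k_shortest <- function(g, source, sink, K = 1L) {
  if (K < 1L) stop_format("K must be at least 1")
  check_endpoints(g, source, sink)
  first <- shortest_path(g, source, sink)
  if (!first$found) return(list())
  found <- list(first)
  pool <- list()   # candidate paths, keyed for dedup
  pool_keys <- character(0)
  W <- if (g$weighted) g$adjacency else (g$adjacency > 0) * 1
  while (length(found) < K) {
    prev <- found[[length(found)]]$nodes
    for (s in seq_len(length(prev) - 1L)) {
      spur <- prev[s]
      root <- prev[seq_len(s)]
      # block continuation edges of known paths sharing this root
      blocked <- do.call(rbind, lapply(found, function(p) {
        pn <- p$nodes
        if (length(pn) > s && identical(pn[seq_len(s)], root))
          cbind(pn[s], pn[s + 1L])
        else NULL
      }))
      allowed <- setdiff(g$labels, root[-s])
      spur_path <- dijkstra_lex(g$adjacency, g$labels, spur, sink,
                                g$weighted, allowed = allowed,
                                blocked = blocked)
      if (!spur_path$found) next
      total <- c(root[-s], spur_path$nodes)
      key <- paste(total, collapse = "|")
      if (key %in% pool_keys) next
      # recompute the length canonically over the whole node sequence so
      # equal-length ties compare exactly across candidates
      pool <- c(pool, list(path_result(total, path_length(W, total))))
      pool_keys <- c(pool_keys, key)
    }
    if (length(pool) == 0L) break
    # pick the (length, lexicographic sequence) minimum candidate
    best <- 1L
    for (i in seq_along(pool)) {
      if (pool[[i]]$length < pool[[best]]$length ||
          (pool[[i]]$length == pool[[best]]$length &&
           lex_less(pool[[i]]$nodes, pool[[best]]$nodes)))
        best <- i
    }
    found <- c(found, pool[best])
    pool <- pool[-best]
    pool_keys <- pool_keys[-best]
  }
  found
}

path_length <- function(W, nodes) {
  if (length(nodes) < 2L) return(0)
  sum(W[cbind(nodes[-length(nodes)], nodes[-1L])])
}
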