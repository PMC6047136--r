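# Unipartite link-prediction scores: nine neighborhood indices and five
# path-based metrics. All scorers return a labelled square score matrix;
# the diagonal is reported but excluded by the rankers.

score_matrix_u <- function(values, method, params = list()) {
  structure(list(values = values, method = method, params = params),
            class = "score_matrix_u")
}

#' @export
print.score_matrix_u <- function(x, ...) {
  cat(sprintf("Unipartite score matrix (%s): %d x %d\n", x$method,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

binarized <- function(g) (g$adjacency > 0) * 1

#' Neighborhood-based link-prediction indices
#'
#' Scores every node pair from the overlap of their neighbor sets on the
#' binarized graph. With common-neighbor set \eqn{C = \Gamma(x) \cap
#' \Gamma(y)} and degrees \eqn{k_x, k_y}:
#' \describe{
#'   \item{common_neighbors}{\eqn{|C|}}
#'   \item{jaccard}{\eqn{|C| / |\Gamma(x) \cup \Gamma(y)|}}
#'   \item{cosine}{\eqn{|C| / \sqrt{k_x k_y}} (Salton index)}
#'   \item{hpi}{hub promoted, \eqn{|C| / \min(k_x, k_y)}}
#'   \item{hdi}{hub depressed, \eqn{|C| / \max(k_x, k_y)}}
#'   \item{adamic_adar}{\eqn{\sum_{z \in C} 1/\ln k_z}, skipping degree-1
#'     common neighbors whose log degree would be zero}
#'   \item{pref_attach}{preferential attachment, \eqn{k_x k_y}}
#'   \item{resource_alloc}{\eqn{\sum_{z \in C} 1/k_z}}
#'   \item{lhn}{Leicht-Holme-Newman, \eqn{|C| / (k_x k_y)}}
#' }
#' Ratio indices return 0 whenever their denominator is 0, so isolated
#' nodes score 0 rather than NaN.
#'
#' @param g a [unipartite_graph()]; weights are binarized.
#' @param method one of the nine index names above.
#' @return A `score_matrix_u` (symmetric).
#' @export
neighborhood_score <- function(g, method = c("common_neighbors", "jaccard",
                                             "cosine", "hpi", "hdi",
                                             "adamic_adar", "pref_attach",
                                             "resource_alloc", "lhn")) {
  method <- match.arg(method)
  A <- binarized(g)
  k <- colSums(A)
  CN <- A %*% A
  S <- switch(method,
    common_neighbors = CN,
    jaccard = safe_div(CN, outer(k, k, "+") - CN),
    cosine = safe_div(CN, sqrt(outer(k, k))),
    hpi = safe_div(CN, outer(k, k, pmin)),
    hdi = safe_div(CN, outer(k, k, pmax)),
    adamic_adar = {
      w <- ifelse(k >= 2, 1 / log(pmax(k, 2)), 0)
      A %*% (w * A)
    },
    pref_attach = outer(k, k),
    resource_alloc = {
      w <- ifelse(k > 0, 1 / pmax(k, 1), 0)
      A %*% (w * A)
    },
    lhn = safe_div(CN, outer(k, k)))
  dimnames(S) <- list(g$labels, g$labels)
  score_matrix_u(S, method)
}

safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- 0
  out
}

#' Local-path index
#'
#' Counts paths of length 2 and, down-weighted by `epsilon`, length 3:
#' \eqn{S = A^2 + \epsilon A^3} on the binarized adjacency. At
#' `epsilon = 0` it reduces to common neighbors off-diagonal.
#'
#' @param g a [unipartite_graph()].
#' @param epsilon weight of the length-3 term (default 0.01).
#' @return A `score_matrix_u`.
#' @export
local_path_score <- function(g, epsilon = 0.01) {
  if (epsilon < 0) stop_format("epsilon must be non-negative")
  A <- binarized(g)
  A2 <- A %*% A
  S <- A2 + epsilon * (A2 %*% A)
  dimnames(S) <- list(g$labels, g$labels)
  score_matrix_u(S, "local_path", list(epsilon = epsilon))
}

#' Katz index
#'
#' Counts all paths between node pairs, geometrically damped so shorter
#' paths weigh more: \eqn{S = \sum_{l \ge 1} \beta^l A^l =
#' (I - \beta A)^{-1} - I}. Requires \eqn{\beta < 1/\rho(A)} (spectral
#' radius) for convergence.
#'
#' @param g a [unipartite_graph()]; weights are binarized.
#' @param beta damping factor.
#' @return A `score_matrix_u`.
#' @export
katz_score <- function(g, beta = 0.01) {
  A <- binarized(g)
  rho <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  if (rho > 0 && beta >= 1 / rho)
    stop_format(sprintf(
      "katz series diverges: beta = %g must be below 1/rho(A) = %g",
      beta, 1 / rho))
  if (beta < 0) stop_format("beta must be non-negative")
  n <- nrow(A)
  S <- solve(diag(n) - beta * A) - diag(n)
  dimnames(S) <- list(g$labels, g$labels)
  score_matrix_u(S, "katz", list(beta = beta))
}

#' Geodesic similarity
#'
#' Scores a pair by the reciprocal of its shortest-path distance
#' (edge weights used as lengths on weighted graphs); unreachable pairs
#' score 0, and the diagonal is set to 0.
#'
#' @param g a [unipartite_graph()].
#' @return A `score_matrix_u`.
#' @export
geodesic_score <- function(g) {
  ig <- as_igraph(g)
  d <- igraph::distances(ig, weights = if (g$weighted) NULL else NA)
  S <- 1 / d
  S[!is.finite(S)] <- 0
  diag(S) <- 0
  dimnames(S) <- list(g$labels, g$labels)
  score_matrix_u(S, "geodesic")
}

#' Random-walk hitting times
#'
#' \eqn{H_{x,y}} is the expected number of steps for a uniform random walk
#' started at `x` to first reach `y`. Solved exactly per connected
#' component from the linear system \eqn{H_{x,y} = 1 + \sum_{z \in
#' \Gamma(x)} H_{z,y}/k_x}, \eqn{H_{y,y} = 0}. Pairs in different
#' components (and rows of isolated nodes) carry the `Inf` sentinel. The
#' matrix is generally asymmetric; lower means closer, so rankers negate
#' it.
#'
#' @param g a [unipartite_graph()]; weights are binarized.
#' @return A `score_matrix_u` with entry `[x, y]` = H(x -> y).
#' @export
hitting_time <- function(g) {
  A <- binarized(g)
  n <- nrow(A)
  H <- matrix(Inf, n, n, dimnames = list(g$labels, g$labels))
  diag(H) <- 0
  comp <- igraph::components(as_igraph(g))$membership
  k <- rowSums(A)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) < 2L) next
    P <- A[idx, idx, drop = FALSE] / k[idx]
    for (j in seq_along(idx)) {
      keep <- setdiff(seq_along(idx), j)
      Q <- P[keep, keep, drop = FALSE]
      h <- solve(diag(length(keep)) - Q, rep(1, length(keep)))
      H[idx[keep], idx[j]] <- h
    }
  }
  score_matrix_u(H, "hitting_time")
}

#' Random walk with restart on a unipartite graph
#'
#' For each start node s the walker follows a uniformly (or
#' weight-proportionally) chosen edge with probability `1 - c` and
#' teleports back to s with probability `c`. Column s of the result is the
#' stationary distribution, the fixed point of
#' \eqn{p = (1-c) W^\top p + c\, e_s} with W the row-normalized adjacency.
#' Isolated nodes are given an implicit self-loop so every column remains a
#' probability vector.
#'
#' @param g a [unipartite_graph()].
#' @param c restart probability in (0, 1) (default 0.3).
#' @param tol L1 convergence tolerance (default 1e-9).
#' @param max_iter iteration cap (default 1e4).
#' @return A `score_matrix_u`; entry `[x, s]` is the stationary probability
#'   of x for the walk restarting at s.
#' @export
rwr_unipartite <- function(g, c = 0.3, tol = 1e-9, max_iter = 10000L) {
  if (c <= 0 || c >= 1) stop_format("restart probability c must be in (0,1)")
  W <- row_normalize(g$adjacency, self_loop_if_zero = TRUE)
  P <- rwr_fixed_point(t(W), c, tol, max_iter)
  dimnames(P) <- list(g$labels, g$labels)
  score_matrix_u(P, "rwr", list(c = c))
}

row_normalize <- function(M, self_loop_if_zero = FALSE) {
  rs <- rowSums(M)
  zero <- rs == 0
  if (any(zero) && self_loop_if_zero) {
    diag(M)[zero] <- 1
    rs[zero] <- 1
  }
  M / ifelse(rs == 0, 1, rs)
}

# iterate P <- (1-c) Wt P + c E for all start columns at once (E = I)
rwr_fixed_point <- function(Wt, c, tol, max_iter, E = NULL) {
  n <- nrow(Wt)
  if (is.null(E)) E <- diag(n)
  P <- E
  for (it in seq_len(max_iter)) {
    P_new <- (1 - c) * (Wt %*% P) + c * E
    delta <- max(colSums(abs(P_new - P)))
    P <- P_new
    if (delta < tol) return(P)
  }
  stop_noconv(sprintf(
    "random walk did not converge in %d iterations (residual %.3g)",
    max_iter, delta))
}

#' Rank unipartite predictions
#'
#' Flattens a unipartite score matrix into a ranked pair table, excluding
#' the diagonal and counting each unordered pair once. Hitting-time scores
#' are negated so that smaller expected times rank first.
#'
#' @param g the scored [unipartite_graph()].
#' @param scores a `score_matrix_u` aligned to `g`.
#' @param top number of rows to keep (default all).
#' @return A data.frame with columns `node_a`, `node_b`, `score`,
#'   `known_edge`, sorted by score descending with deterministic label
#'   tie-breaks.
#' @export
rank_unipartite <- function(g, scores, top = Inf) {
  S <- scores$values
  if (identical(scores$method, "hitting_time")) {
    S <- -(S + t(S)) / 2   # symmetrize commute-style, lower time = better
    S[!is.finite(S)] <- -Inf
  }
  n <- nrow(S)
  ut <- which(upper.tri(S), arr.ind = TRUE)
  df <- data.frame(node_a = g$labels[ut[, 1L]],
                   node_b = g$labels[ut[, 2L]],
                   score = S[ut],
                   known_edge = g$adjacency[ut] > 0,
                   stringsAsFactors = FALSE)
  ord <- order(-df$score, df$node_a, df$node_b)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, n = if (is.finite(top)) top else nrow(df))
}
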