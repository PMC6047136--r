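# Bipartite drug-target recommenders: HeatS, network-based inference (NBI),
# random walk with restart on the heterogeneous drug/target network, and
# their combination (netcombo).

score_matrix_b <- function(values, method, params = list()) {
  structure(list(values = values, method = method, params = params),
            class = "score_matrix_b")
}

#' @export
print.score_matrix_b <- function(x, ...) {
  cat(sprintf("Bipartite score matrix (%s): %d targets x %d drugs\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# align a similarity matrix to the given labels, erroring with the
# symmetric difference when they do not match as sets
align_similarity <- function(sim, labels, what) {
  if (is.null(sim)) return(NULL)
  missing_l <- setdiff(labels, sim$labels)
  extra_l <- setdiff(sim$labels, labels)
  if (length(missing_l) > 0L || length(extra_l) > 0L)
    stop_format(sprintf(
      "%s similarity labels do not match the network (missing: %s; extra: %s)",
      what,
      if (length(missing_l)) paste(utils::head(missing_l, 5L), collapse = ", ")
      else "none",
      if (length(extra_l)) paste(utils::head(extra_l, 5L), collapse = ", ")
      else "none"))
  sim$values[labels, labels, drop = FALSE]
}

#' Network-based inference (mass diffusion) scores
#'
#' Two-phase resource transfer on the bipartite graph. For each drug j the
#' initial resource is its interaction profile over targets,
#' \eqn{r = A[, j]}. Phase 1 spreads target resource to drugs, each target
#' splitting its resource equally among its \eqn{k(t_l)} drugs:
#' \eqn{r_d(i) = \sum_l A[l,i]\, r(l)/k(t_l)}. Phase 2 returns it to
#' targets, each drug splitting equally among its \eqn{k(d_i)} targets:
#' \eqn{F[l,j] = \sum_i A[l,i]\, r_d(i)/k(d_i)}. In matrix form
#' \eqn{F = A D_d^{-1} A^\top D_t^{-1} A}. The diffusion conserves each
#' drug column's total resource.
#'
#' When similarity matrices are supplied the topology score is blended with
#' neighbor evidence as \eqn{F' = \hat S_t F \hat S_d^\top} with the hats
#' denoting row normalization; identity similarities reproduce the
#' topology-only score.
#'
#' @param net a [bipartite_network()].
#' @param drug_sim,target_sim optional [similarity_matrix()] objects whose
#'   labels match the network's drugs/targets (any order).
#' @return A `score_matrix_b` (targets x drugs).
#' @export
nbi_score <- function(net, drug_sim = NULL, target_sim = NULL) {
  A <- net$adjacency
  if (n_edges(net) < 1L) stop_format("network has no interactions")
  kd <- colSums(A)
  kt <- rowSums(A)
  if (any(kd == 0))
    warning(sprintf("%d drug(s) with no interactions score zero",
                    sum(kd == 0)), call. = FALSE)
  inv <- function(v) ifelse(v > 0, 1 / pmax(v, 1e-300), 0)
  # F = A Dd^-1 A^T Dt^-1 A  (phase 1 then phase 2, all drugs at once)
  F <- A %*% (inv(kd) * t(A)) %*% (inv(kt) * A)
  F <- blend_similarity(F, drug_sim, target_sim, net)
  dimnames(F) <- dimnames(A)
  score_matrix_b(F, "nbi")
}

blend_similarity <- function(F, drug_sim, target_sim, net) {
  Sd <- align_similarity(drug_sim, net$drug_labels, "drug")
  St <- align_similarity(target_sim, net$target_labels, "target")
  if (!is.null(St)) F <- row_normalize(St) %*% F
  if (!is.null(Sd)) F <- F %*% t(row_normalize(Sd))
  F
}

#' HeatS (heat conduction) scores
#'
#' The averaging analogue of [nbi_score()]: instead of the sender splitting
#' its resource, each receiver averages what its neighbors hold. Phase 1:
#' \eqn{r_d(i) = (1/k(d_i)) \sum_l A[l,i]\, r(l)}; phase 2:
#' \eqn{F[l,j] = (1/k(t_l)) \sum_i A[l,i]\, r_d(i)}. Uses only the
#' bipartite matrix.
#'
#' @param net a [bipartite_network()].
#' @return A `score_matrix_b` (targets x drugs).
#' @export
heats_score <- function(net) {
  A <- net$adjacency
  if (n_edges(net) < 1L) stop_format("network has no interactions")
  kd <- colSums(A)
  kt <- rowSums(A)
  if (any(kd == 0))
    warning(sprintf("%d drug(s) with no interactions score zero",
                    sum(kd == 0)), call. = FALSE)
  inv <- function(v) ifelse(v > 0, 1 / pmax(v, 1e-300), 0)
  # F = Dt^-1 A Dd^-1 A^T A  (receiver-degree averaging)
  F <- inv(kt) * (A %*% (inv(kd) * (t(A) %*% A)))
  dimnames(F) <- dimnames(A)
  score_matrix_b(F, "heats")
}

#' Random walk with restart on the heterogeneous network
#'
#' Builds a single walk space of all drugs and targets. Within-layer moves
#' follow the row-normalized similarity matrices with weight `1 - lam`;
#' cross-layer jumps follow the row-normalized bipartite adjacency with
#' weight `lam`. A node with no bipartite links cannot jump, so its
#' within-layer weight is 1. For each drug j a walker restarts at j with
#' probability `c`; the target block of its stationary distribution is
#' column j of the score matrix.
#'
#' @param net a [bipartite_network()].
#' @param drug_sim,target_sim required [similarity_matrix()] objects.
#' @param c restart probability in (0, 1) (default 0.7).
#' @param lam cross-network jump probability in (0, 1) (default 0.5).
#' @param tol L1 convergence tolerance (default 1e-9).
#' @param max_iter iteration cap (default 1e4).
#' @return A `score_matrix_b` (targets x drugs). Attribute `stationary`
#'   holds the full (drugs+targets) stationary matrix for diagnostics.
#' @export
rwr_hetero_score <- function(net, drug_sim, target_sim, c = 0.7, lam = 0.5,
                             tol = 1e-9, max_iter = 10000L) {
  if (missing(drug_sim) || missing(target_sim) ||
      is.null(drug_sim) || is.null(target_sim))
    stop_format("heterogeneous RWR requires both similarity matrices")
  if (c <= 0 || c >= 1) stop_format("restart probability c must be in (0,1)")
  if (lam <= 0 || lam >= 1) stop_format("jump probability lam must be in (0,1)")
  A <- net$adjacency
  nd <- ncol(A); nt <- nrow(A)
  Sd <- align_similarity(drug_sim, net$drug_labels, "drug")
  St <- align_similarity(target_sim, net$target_labels, "target")
  kd <- colSums(A); kt <- rowSums(A)

  M <- matrix(0, nd + nt, nd + nt)
  di <- seq_len(nd); ti <- nd + seq_len(nt)
  wd <- ifelse(kd > 0, 1 - lam, 1)   # linkless drugs stay within-layer
  wt <- ifelse(kt > 0, 1 - lam, 1)
  M[di, di] <- wd * row_normalize_uniform_fallback(Sd, "drug")
  M[ti, ti] <- wt * row_normalize_uniform_fallback(St, "target")
  M[di, ti] <- lam * row_normalize(t(A))   # drug -> its targets
  M[ti, di] <- lam * row_normalize(A)      # target -> its drugs
  E <- rbind(diag(nd), matrix(0, nt, nd))
  P <- rwr_fixed_point(t(M), c, tol, max_iter, E = E)
  F <- P[ti, , drop = FALSE]
  dimnames(F) <- dimnames(A)
  out <- score_matrix_b(F, "rwr", list(c = c, lam = lam))
  attr(out, "stationary") <- P
  out
}

row_normalize_uniform_fallback <- function(S, what) {
  rs <- rowSums(S)
  if (any(rs == 0)) {
    warning(sprintf("%d all-zero %s similarity row(s); using uniform fallback",
                    sum(rs == 0), what), call. = FALSE)
    S[rs == 0, ] <- 1
  }
  row_normalize(S)
}

#' Netcombo: averaged NBI and heterogeneous-RWR scores
#'
#' Runs both children, min-max scales each score matrix to \[0, 1\] over
#' the unknown (non-interacting) pairs so the two incomparable scales
#' align, and averages entrywise.
#'
#' @inheritParams rwr_hetero_score
#' @param ... further parameters passed to [rwr_hetero_score()].
#' @return A `score_matrix_b` (targets x drugs) with entries in \[0, 1\].
#' @export
netcombo_score <- function(net, drug_sim, target_sim, ...) {
  F1 <- nbi_score(net, drug_sim, target_sim)$values
  F2 <- rwr_hetero_score(net, drug_sim, target_sim, ...)$values
  unknown <- net$adjacency == 0
  F <- (minmax_scale(F1, unknown) + minmax_scale(F2, unknown)) / 2
  dimnames(F) <- dimnames(net$adjacency)
  score_matrix_b(F, "netcombo")
}

minmax_scale <- function(F, mask) {
  v <- F[mask]
  rng <- range(v)
  if (diff(rng) == 0) return(F * 0)
  pmin(pmax((F - rng[1L]) / diff(rng), 0), 1)
}

#' Degree-product baseline scores
#'
#' Null recommender scoring pair (t, d) by \eqn{k(t_l)\, k(d_i)}: predicts
#' purely from node popularity, with no diffusion. Used as the floor any
#' informative recommender must beat in benchmarks.
#'
#' @param net a [bipartite_network()].
#' @return A `score_matrix_b` (targets x drugs).
#' @export
degree_product_score <- function(net) {
  A <- net$adjacency
  F <- outer(rowSums(A), colSums(A))
  dimnames(F) <- dimnames(A)
  score_matrix_b(F, "degree")
}

#' Rank bipartite predictions
#'
#' Flattens a score matrix into the prediction table: one row per
#' (drug, target) pair, sorted by score descending with deterministic
#' (drug, target) label tie-breaks; known interactions are labelled
#' `"true"`, the rest `"predicted"`.
#'
#' @param net the scored [bipartite_network()].
#' @param scores a `score_matrix_b` aligned to `net`.
#' @param top number of rows to keep (default all).
#' @return A data.frame with columns `drug`, `target`, `score`, `outcome`.
#' @export
rank_predictions <- function(net, scores, top = Inf) {
  F <- scores$values
  if (!identical(dim(F), dim(net$adjacency)))
    stop_format("score matrix shape does not match the network")
  df <- data.frame(
    drug = rep(net$drug_labels, each = n_targets(net)),
    target = rep(net$target_labels, times = n_drugs(net)),
    score = as.vector(F),
    outcome = ifelse(as.vector(net$adjacency) > 0, "true", "predicted"),
    stringsAsFactors = FALSE)
  ord <- order(-df$score, df$drug, df$target)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, n = if (is.finite(top)) top else nrow(df))
}
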