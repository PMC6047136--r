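# Bipartite community detection: label propagation seeding, BRIM
# refinement, and Barber bipartite modularity.

#' Construct a module partition
#'
#' @param target_module named integer vector, module id per target label.
#' @param drug_module named integer vector, module id per drug label.
#' @param modularity Barber modularity of the partition (optional; filled
#'   by the detection functions).
#' @return An object of class `module_partition`. Module ids are compacted
#'   to the contiguous range 1..K.
#' @export
module_partition <- function(target_module, drug_module, modularity = NA_real_) {
  all_ids <- c(target_module, drug_module)
  if (anyNA(all_ids)) stop_format("every node needs a module id")
  relab <- match(all_ids, sort(unique(all_ids)))
  nt <- length(target_module)
  structure(list(
    target_module = stats::setNames(relab[seq_len(nt)], names(target_module)),
    drug_module = stats::setNames(relab[-seq_len(nt)], names(drug_module)),
    modularity = modularity),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules over %d targets + %d drugs, Q_B = %.4f\n",
              length(unique(c(x$target_module, x$drug_module))),
              length(x$target_module), length(x$drug_module), x$modularity))
  invisible(x)
}

# null-adjusted bipartite matrix B = A - k_t k_d / m
barber_B <- function(net) {
  A <- net$adjacency
  m <- sum(A)
  A - outer(rowSums(A), colSums(A)) / m
}

#' Barber bipartite modularity
#'
#' \eqn{Q_B = (1/m) \sum_{l,i} (A[l,i] - k(t_l) k(d_i)/m)\,
#' \delta(c_{t_l}, c_{d_i})}: the within-module edge mass in excess of the
#' degree-product null model, summed over target-drug pairs sharing a
#' module.
#'
#' @param net a [bipartite_network()].
#' @param part a [module_partition()] covering all nodes of `net`.
#' @return Q_B, a real in \[-1, 1\].
#' @export
barber_modularity <- function(net, part) {
  ct <- part$target_module[net$target_labels]
  cd <- part$drug_module[net$drug_labels]
  if (anyNA(ct) || anyNA(cd))
    stop_format("partition does not cover every network node")
  m <- n_edges(net)
  if (m < 1L) stop_format("network has no interactions")
  delta <- outer(ct, cd, "==")
  sum(barber_B(net) * delta) / m
}

#' Bipartite label propagation
#'
#' Every node starts in its own module; nodes are then swept in seeded
#' random order, each adopting the most frequent module among its
#' bipartite neighbors (ties broken uniformly at random under the seed).
#' Sweeps stop when a full pass changes no label or Barber modularity
#' stops increasing. Isolated nodes keep their own label.
#'
#' @param net a [bipartite_network()].
#' @param seed integer random seed (determinism contract: same seed, same
#'   partition).
#' @return A [module_partition()] with its Q_B.
#' @export
label_propagation <- function(net, seed = 1L) {
  A <- net$adjacency
  nt <- nrow(A); nd <- ncol(A)
  n <- nt + nd
  # neighbor index lists over the joint node ordering [targets, drugs]
  nbr <- c(lapply(seq_len(nt), function(l) nt + which(A[l, ] > 0)),
           lapply(seq_len(nd), function(i) which(A[, i] > 0)))
  lab <- seq_len(n)
  as_part <- function(lab) module_partition(
    stats::setNames(lab[seq_len(nt)], net$target_labels),
    stats::setNames(lab[nt + seq_len(nd)], net$drug_labels))
  best_q <- -Inf
  part <- as_part(lab)
  with_seed(seed, {
    for (sweep in 1:100) {
      changed <- FALSE
      for (v in sample(n)) {
        nv <- nbr[[v]]
        if (length(nv) == 0L) next
        tab <- table(lab[nv])
        winners <- as.integer(names(tab)[tab == max(tab)])
        new_lab <- if (length(winners) == 1L) winners else
          winners[sample.int(length(winners), 1L)]
        if (new_lab != lab[v]) {
          lab[v] <- new_lab
          changed <- TRUE
        }
      }
      cur <- as_part(lab)
      q <- barber_modularity(net, cur)
      # stop on label stability, or when an exchange sweep lowered Q_B;
      # Q_B-neutral relabeling sweeps keep going (bounded by the cap)
      stop_now <- !changed || q < best_q - 1e-12
      if (q > best_q) {
        best_q <- q
        part <- cur
      } else if (!changed && q >= best_q - 1e-12) {
        part <- cur
      }
      if (stop_now) break
    }
  })
  part$modularity <- if (is.finite(best_q)) best_q
                     else barber_modularity(net, part)
  part
}

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' BRIM refinement of a bipartite partition
#'
#' Alternating hill climb on Barber modularity: holding target assignments
#' fixed, each drug moves to the module maximizing its Q_B contribution
#' (ties to the lowest module id); then the converse; repeated until the
#' improvement drops below 1e-12. Q_B never decreases, so the returned
#' partition is at least as good as the input. Empty modules are compacted.
#'
#' @param net a [bipartite_network()].
#' @param part starting [module_partition()].
#' @return A refined [module_partition()] with its Q_B.
#' @export
brim_refine <- function(net, part) {
  B <- barber_B(net)
  m <- n_edges(net)
  ct <- part$target_module[net$target_labels]
  cd <- part$drug_module[net$drug_labels]
  K <- max(ct, cd)
  q_old <- barber_modularity(net, part)
  repeat {
    Tm <- indicator(ct, K)                 # n_t x K
    contrib_d <- t(B) %*% Tm               # n_d x K
    cd <- max.col(contrib_d, ties.method = "first")
    Dm <- indicator(cd, K)                 # n_d x K
    contrib_t <- B %*% Dm                  # n_t x K
    ct <- max.col(contrib_t, ties.method = "first")
    q_new <- sum(indicator(ct, K) * (B %*% indicator(cd, K))) / m
    if (q_new <= q_old + 1e-12) break
    q_old <- q_new
  }
  out <- module_partition(
    stats::setNames(ct, net$target_labels),
    stats::setNames(cd, net$drug_labels))
  out$modularity <- barber_modularity(net, out)
  out
}

indicator <- function(assign, K) {
  M <- matrix(0, length(assign), K)
  M[cbind(seq_along(assign), assign)] <- 1
  M
}

#' LP-BRIM bipartite community detection
#'
#' The full pipeline: label propagation seeds a partition, BRIM refines
#' it, and the best of `restarts` independent runs (sub-seeded from
#' `seed`) is returned.
#'
#' @param net a [bipartite_network()].
#' @param seed integer random seed.
#' @param restarts number of independent restarts (default 5).
#' @return The highest-Q_B [module_partition()] found.
#' @export
lpbrim <- function(net, seed = 1L, restarts = 5L) {
  if (restarts < 1L) stop_format("restarts must be at least 1")
  best <- NULL
  for (r in seq_len(restarts)) {
    part <- label_propagation(net, seed = seed + (r - 1L))
    part <- brim_refine(net, part)
    if (is.null(best) || part$modularity > best$modularity) best <- part
  }
  best
}

#' Normalized mutual information between two partitions
#'
#' Agreement between module assignments, normalized by the arithmetic mean
#' of the two entropies (2 I / (H1 + H2)); 1 means identical partitions up
#' to relabeling. Used to assess recovery of planted modules.
#'
#' @param a,b integer/character label vectors of equal length.
#' @return NMI in \[0, 1\]; defined as 1 when both partitions are single
#'   modules.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop_format("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  H1 <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  H2 <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (H1 + H2 == 0) return(1)
  2 * I / (H1 + H2)
}
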