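# Seeded generators: bipartite networks with planted module structure and
# similarity matrices correlated with interaction profiles. These stand in
# for curated drug-target benchmark sets so every algorithm can be
# exercised offline.

#' Generate a bipartite network with planted modules
#'
#' Drugs and targets are split near-evenly into `n_modules` blocks; a
#' target-drug edge is drawn with probability `p_in` when the two nodes
#' share a block and `p_out` otherwise. Any node left without an edge is
#' repaired with one forced within-block interaction, so no empty rows or
#' columns remain. Deterministic per seed.
#'
#' @param n_drugs,n_targets node counts.
#' @param n_modules number of planted modules (at most
#'   `min(n_drugs, n_targets)`).
#' @param p_in,p_out within/between-block edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed integer random seed.
#' @return List with `net` (a [bipartite_network()]), `drug_module` and
#'   `target_module` (named integer vectors: the planted ground truth).
#' @export
gen_bipartite <- function(n_drugs = 50L, n_targets = 40L, n_modules = 4L,
                          p_in = 0.5, p_out = 0.02, seed = 1L) {
  if (p_out < 0 || p_in > 1 || p_out >= p_in)
    stop_format("need 0 <= p_out < p_in <= 1")
  if (n_modules < 1L || n_modules > min(n_drugs, n_targets))
    stop_format("n_modules must be in 1..min(n_drugs, n_targets)")
  dl <- sprintf("d%03d", seq_len(n_drugs))
  tl <- sprintf("t%03d", seq_len(n_targets))
  dmod <- stats::setNames(near_even_split(n_drugs, n_modules), dl)
  tmod <- stats::setNames(near_even_split(n_targets, n_modules), tl)
  A <- with_seed(seed, {
    P <- matrix(p_out, n_targets, n_drugs)
    P[outer(tmod, dmod, "==")] <- p_in
    A <- matrix(stats::rbinom(n_targets * n_drugs, 1L, as.vector(P)),
                n_targets, n_drugs)
    # repair: any empty row/column gets one forced within-block edge
    for (l in which(rowSums(A) == 0)) {
      mates <- which(dmod == tmod[l])
      A[l, mates[sample.int(length(mates), 1L)]] <- 1L
    }
    for (i in which(colSums(A) == 0)) {
      mates <- which(tmod == dmod[i])
      A[mates[sample.int(length(mates), 1L)], i] <- 1L
    }
    A
  })
  dimnames(A) <- list(tl, dl)
  list(net = bipartite_network(A), drug_module = dmod, target_module = tmod)
}

near_even_split <- function(n, k) sort(rep_len(seq_len(k), n))

#' Generate a similarity matrix correlated with interaction profiles
#'
#' The signal part is the Jaccard similarity of interaction profiles
#' (columns of the adjacency for drugs, rows for targets) — mimicking how
#' chemical or sequence similarity tracks shared targets. The noise part
#' is symmetric uniform noise. The result is
#' `sim_signal * signal + (1 - sim_signal) * noise`, diagonal forced to 1
#' and values clipped to \[0, 1\].
#'
#' @param net a [bipartite_network()].
#' @param side `"drugs"` or `"targets"`.
#' @param sim_signal signal weight in \[0, 1\].
#' @param seed integer random seed.
#' @return A [similarity_matrix()].
#' @export
gen_similarity <- function(net, side = c("drugs", "targets"),
                           sim_signal = 0.8, seed = 1L) {
  side <- match.arg(side)
  if (sim_signal < 0 || sim_signal > 1)
    stop_format("sim_signal must be in [0, 1]")
  P <- if (side == "drugs") t(net$adjacency) else net$adjacency
  inter <- tcrossprod(P)
  sz <- rowSums(P)
  uni <- outer(sz, sz, "+") - inter
  signal <- safe_div(inter, uni)
  n <- nrow(signal)
  noise <- with_seed(seed, {
    U <- matrix(stats::runif(n * n), n, n)
    (U + t(U)) / 2
  })
  S <- sim_signal * signal + (1 - sim_signal) * noise
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  dimnames(S) <- dimnames(signal)
  similarity_matrix(S)
}

#' Generate the full synthetic study set
#'
#' Convenience wrapper producing a planted-module network plus matched
#' drug and target similarity matrices (sub-seeded from `seed`).
#'
#' @inheritParams gen_bipartite
#' @param sim_signal signal weight for both similarity matrices.
#' @return List with `net`, `drug_sim`, `target_sim`, `drug_module`,
#'   `target_module`.
#' @export
gen_study <- function(n_drugs = 50L, n_targets = 40L, n_modules = 4L,
                      p_in = 0.5, p_out = 0.02, sim_signal = 0.8,
                      seed = 1L) {
  g <- gen_bipartite(n_drugs, n_targets, n_modules, p_in, p_out, seed)
  list(net = g$net,
       drug_sim = gen_similarity(g$net, "drugs", sim_signal, seed + 1L),
       target_sim = gen_similarity(g$net, "targets", sim_signal, seed + 2L),
       drug_module = g$drug_module,
       target_module = g$target_module)
}
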