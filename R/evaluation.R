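# Validation procedures: the link-removal benchmark scored with early
# recognition metrics (AUAC, AUC, truncated AUC, BEDROC, enrichment
# factor), and degree-preserving permutation significance testing.

#' Early-recognition metrics from active ranks
#'
#' Given the 1-based ranks of the `n` actives (here: hidden true links)
#' within a ranked list of `N` scored pairs, computes:
#' \describe{
#'   \item{auc}{\eqn{1 - (\sum r_i - n(n+1)/2) / (n(N-n))}, the
#'     Mann-Whitney concordance probability.}
#'   \item{auac}{\eqn{1 - (1/n) \sum r_i / N}, area under the
#'     accumulation curve.}
#'   \item{auctop}{AUC of the list truncated at the top
#'     \eqn{\lceil \chi N \rceil} rows; actives below the cutoff count as
#'     missed (zero concordance) while the denominator stays
#'     \eqn{n(N-n)}, so a method is rewarded only for actives it places in
#'     the early window.}
#'   \item{bedroc}{Boltzmann-enhanced discrimination of ROC with
#'     exponential early-recognition weight `alpha`:
#'     \eqn{RIE = \sum_i e^{-\alpha r_i/N} \big/ \left[(n/N)
#'     (1-e^{-\alpha})/(e^{\alpha/N}-1)\right]} rescaled to \[0, 1\].}
#'   \item{ef}{enrichment factor at fraction `chi`: the actives rate in
#'     the top \eqn{\lceil \chi N \rceil} rows over the overall rate
#'     \eqn{n/N}.}
#' }
#'
#' @param ranks strictly increasing integer ranks of the actives, within
#'   1..N.
#' @param N total number of scored pairs.
#' @param alpha BEDROC early-recognition parameter (default 20).
#' @param chi top fraction for `auctop` and `ef` (default 0.1).
#' @return Named numeric vector `auac`, `auc`, `auctop`, `bedroc`, `ef`.
#' @export
rank_metrics <- function(ranks, N, alpha = 20, chi = 0.1) {
  ranks <- as.numeric(ranks)
  n <- length(ranks)
  if (n == 0L) stop_format("no actives: metrics are undefined")
  if (n >= N) stop_format("no inactives: metrics are undefined")
  if (is.unsorted(ranks, strictly = TRUE) || ranks[1L] < 1 || ranks[n] > N)
    stop_format("ranks must be strictly increasing within 1..N")
  if (alpha <= 0) stop_format("alpha must be positive")
  if (chi <= 0 || chi >= 1) stop_format("chi must be in (0,1)")

  auc <- 1 - (sum(ranks) - n * (n + 1) / 2) / (n * (N - n))
  auac <- 1 - mean(ranks / N)

  n_top <- ceiling(chi * N)
  in_top <- ranks <= n_top
  # concordant inactives for active i: (N-n) minus inactives ranked above it
  conc <- (N - n) - (ranks - seq_len(n))
  auctop <- sum(conc[in_top]) / (n * (N - n))

  ef <- (sum(in_top) / n_top) / (n / N)

  Ra <- n / N
  rie <- sum(exp(-alpha * ranks / N)) /
    (Ra * N * (1 - exp(-alpha)) / (N * (exp(alpha / N) - 1)))
  bedroc <- rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))

  c(auac = auac, auc = auc, auctop = auctop, bedroc = bedroc, ef = ef)
}

#' Hide a random fraction of interactions
#'
#' Removes \eqn{\lfloor fraction \cdot m \rfloor} edges from the network,
#' either uniformly at random or with probability proportional to the
#' degree product \eqn{k(d_i) k(t_l)} of the endpoints (removal biased
#' toward frequently interacting nodes). The training network keeps all
#' labels and its shape; training and hidden edges partition the original
#' edge set.
#'
#' @param net a [bipartite_network()].
#' @param fraction fraction of edges to hide, in (0, 1).
#' @param weighting `"uniform"` or `"degree"`.
#' @param seed integer random seed.
#' @return List with `training` (a [bipartite_network()]) and `hidden`
#'   (data.frame of `target`, `drug` labels).
#' @export
remove_links <- function(net, fraction, weighting = c("uniform", "degree"),
                         seed = 1L) {
  weighting <- match.arg(weighting)
  if (fraction <= 0 || fraction >= 1)
    stop_format("fraction must be in (0,1)")
  A <- net$adjacency
  m <- n_edges(net)
  n_rm <- floor(fraction * m)
  if (n_rm < 1L)
    stop_format(sprintf(
      "fraction %g of %d edges removes none; use a larger fraction",
      fraction, m))
  if (n_rm >= m)
    stop_format("removal would leave the network without edges")
  edges <- which(A > 0, arr.ind = TRUE)
  prob <- if (weighting == "degree")
    rowSums(A)[edges[, 1L]] * colSums(A)[edges[, 2L]] else NULL
  pick <- with_seed(seed,
                    sample.int(m, n_rm, replace = FALSE, prob = prob))
  hid <- edges[pick, , drop = FALSE]
  A2 <- A
  A2[hid] <- 0
  list(training = bipartite_network(A2),
       hidden = data.frame(target = net$target_labels[hid[, 1L]],
                           drug = net$drug_labels[hid[, 2L]],
                           stringsAsFactors = FALSE))
}

score_with_algo <- function(net, algo, drug_sim, target_sim, ...) {
  switch(algo,
    heats = heats_score(net),
    nbi = nbi_score(net, drug_sim, target_sim),
    rwr = rwr_hetero_score(net, drug_sim, target_sim, ...),
    netcombo = netcombo_score(net, drug_sim, target_sim, ...),
    degree = degree_product_score(net),
    stop_format(sprintf("unknown algorithm '%s'", algo)))
}

# ranks of the hidden (active) pairs among all non-training pairs,
# scores descending, deterministic (target, drug) label tie-break
active_ranks <- function(training, hidden, scores) {
  A <- training$adjacency
  cand <- which(A == 0)
  s <- scores$values[cand]
  rowi <- (cand - 1L) %% nrow(A) + 1L
  coli <- (cand - 1L) %/% nrow(A) + 1L
  ord <- order(-s, training$target_labels[rowi], training$drug_labels[coli])
  key_sorted <- cand[ord]
  hid_idx <- cbind(match(hidden$target, training$target_labels),
                   match(hidden$drug, training$drug_labels))
  hid_lin <- (hid_idx[, 2L] - 1L) * nrow(A) + hid_idx[, 1L]
  list(ranks = sort(match(hid_lin, key_sorted)), N = length(cand))
}

#' Link-removal benchmark
#'
#' The repeated random-removal protocol: in each repetition a fraction of
#' the true interactions is hidden, the chosen recommender is trained on
#' the reduced network, all non-training pairs are ranked, and the hidden
#' interactions are treated as the actives of [rank_metrics()]. Reports
#' per-repetition metrics and their mean; fully reproducible from `seed`.
#'
#' @param net a [bipartite_network()].
#' @param drug_sim,target_sim optional [similarity_matrix()] objects
#'   (required by `rwr` and `netcombo`; used by `nbi` when given).
#' @param algo one of `"heats"`, `"nbi"`, `"rwr"`, `"netcombo"`, or the
#'   `"degree"` null baseline.
#' @param fraction fraction of edges hidden per repetition (default 0.2).
#' @param reps number of repetitions (default 50).
#' @param seed integer random seed; repetition r uses `seed + r - 1`.
#' @param alpha,chi metric parameters, see [rank_metrics()].
#' @param weighting edge-removal mode, see [remove_links()].
#' @param ... further parameters for the scorer (e.g. `c`, `lam`).
#' @return An `eval_report`: list with `per_rep` (data.frame), `mean`
#'   (named vector) and `config`.
#' @export
benchmark <- function(net, drug_sim = NULL, target_sim = NULL,
                      algo = c("heats", "nbi", "rwr", "netcombo", "degree"),
                      fraction = 0.2, reps = 50L, seed = 1L,
                      alpha = 20, chi = 0.1,
                      weighting = c("uniform", "degree"), ...) {
  algo <- match.arg(algo)
  weighting <- match.arg(weighting)
  per <- vector("list", reps)
  for (r in seq_len(reps)) {
    split <- remove_links(net, fraction, weighting, seed = seed + r - 1L)
    # removal routinely leaves isolated drugs in the training net; the
    # scorer's zero-column warning is expected here, not actionable
    sc <- suppressWarnings(
      score_with_algo(split$training, algo, drug_sim, target_sim, ...))
    ar <- active_ranks(split$training, split$hidden, sc)
    per[[r]] <- rank_metrics(ar$ranks, ar$N, alpha = alpha, chi = chi)
  }
  per_rep <- as.data.frame(do.call(rbind, per))
  per_rep$rep <- seq_len(reps)
  structure(list(
    per_rep = per_rep[, c("rep", "auac", "auc", "auctop", "bedroc", "ef")],
    mean = colMeans(per_rep[, c("auac", "auc", "auctop", "bedroc", "ef")]),
    config = list(algo = algo, fraction = fraction, reps = reps,
                  seed = seed, alpha = alpha, chi = chi,
                  weighting = weighting)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Link-removal benchmark (%s, %.0f%% hidden, %d reps):\n",
              x$config$algo, 100 * x$config$fraction, x$config$reps))
  print(round(x$mean, 4))
  invisible(x)
}

# one checkerboard swap attempt on the edge list; preserves both degree
# sequences. Returns the updated matrix or NULL if the draw was unswappable.
checkerboard_sweep <- function(A, n_swaps, max_attempts) {
  edges <- which(A > 0, arr.ind = TRUE)
  m <- nrow(edges)
  done <- 0L
  attempts <- 0L
  while (done < n_swaps) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop_format(paste("network admits no checkerboard swaps:",
                        "degree-preserving null unavailable"))
    pick <- sample.int(m, 2L)
    r1 <- edges[pick[1L], 1L]; c1 <- edges[pick[1L], 2L]
    r2 <- edges[pick[2L], 1L]; c2 <- edges[pick[2L], 2L]
    if (r1 == r2 || c1 == c2) next
    if (A[r1, c2] > 0 || A[r2, c1] > 0) next
    A[r1, c1] <- 0; A[r2, c2] <- 0
    A[r1, c2] <- 1; A[r2, c1] <- 1
    edges[pick[1L], ] <- c(r1, c2)
    edges[pick[2L], ] <- c(r2, c1)
    done <- done + 1L
  }
  A
}

#' Permutation significance test for predicted interactions
#'
#' Scores the intact network, then rescoring `n_perm` degree-preserving
#' rewirings of the bipartite adjacency (checkerboard swaps: burn-in of
#' `10 m` swaps, `m` swaps between consecutive samples) builds a per-pair
#' null. The null for each pair is conditioned on the pair's observed
#' edge status: a non-edge pair is compared only against permutations in
#' which it is again a non-edge (and an edge pair against permutations
#' where it is an edge), since the direct adjacency contribution
#' otherwise dominates the comparison and biases every p-value. Each pair
#' gets \eqn{z = (observed - mean)/sd} and an upper-tail standard-normal
#' p (high score = significant); pairs with zero or inestimable null
#' spread get the sentinel p = 0.5. Benjamini-Hochberg q-values are
#' added, and rows are filtered to `p <= p_keep`. Similarity matrices, if
#' any, are left intact; only the adjacency is permuted.
#'
#' @param net a [bipartite_network()].
#' @param drug_sim,target_sim optional [similarity_matrix()] objects.
#' @param algo `"nbi"` or `"rwr"`.
#' @param n_perm number of permutations (at least 20).
#' @param seed integer random seed.
#' @param p_keep keep rows with p at or below this value (default 1).
#' @param ... further scorer parameters.
#' @return A `permutation_result`: list with `table` (data.frame of drug,
#'   target, score, perm_mean, perm_sd, z, p, q, outcome), `n_perm`,
#'   `seed`.
#' @export
permutation_test <- function(net, drug_sim = NULL, target_sim = NULL,
                             algo = c("nbi", "rwr"), n_perm = 100L,
                             seed = 1L, p_keep = 1, ...) {
  algo <- match.arg(algo)
  if (n_perm < 20L) stop_format("n_perm must be at least 20")
  if (p_keep <= 0 || p_keep > 1) stop_format("p_keep must be in (0,1]")
  obs <- score_with_algo(net, algo, drug_sim, target_sim, ...)$values
  A <- net$adjacency
  m <- n_edges(net)
  rs <- rowSums(A); cs <- colSums(A)
  status <- A > 0
  sum1 <- matrix(0, nrow(A), ncol(A))
  sum2 <- matrix(0, nrow(A), ncol(A))
  cnt <- matrix(0, nrow(A), ncol(A))
  with_seed(seed, {
    Ap <- checkerboard_sweep(A, 10L * m, max_attempts = 2000L * m)  # burn-in
    for (p in seq_len(n_perm)) {
      Ap <- checkerboard_sweep(Ap, m, max_attempts = 2000L * m)
      stopifnot(identical(rowSums(Ap), rs), identical(colSums(Ap), cs))
      netp <- bipartite_network(Ap)
      sp <- suppressWarnings(
        score_with_algo(netp, algo, drug_sim, target_sim, ...)$values)
      match_stat <- (Ap > 0) == status   # same edge status as observed
      sum1 <- sum1 + sp * match_stat
      sum2 <- sum2 + sp^2 * match_stat
      cnt <- cnt + match_stat
    }
  })
  est <- cnt >= 2
  mu <- ifelse(est, sum1 / pmax(cnt, 1), NA_real_)
  sd <- ifelse(est,
               sqrt(pmax(sum2 / pmax(cnt, 1) - mu^2, 0) *
                    cnt / pmax(cnt - 1, 1)),
               0)
  z <- ifelse(est & sd > 0, (obs - mu) / sd, 0)
  pval <- ifelse(est & sd > 0, stats::pnorm(z, lower.tail = FALSE), 0.5)
  mu[!est] <- 0
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1 - 1e-16)
  tab <- data.frame(
    drug = rep(net$drug_labels, each = nrow(A)),
    target = rep(net$target_labels, times = ncol(A)),
    score = as.vector(obs),
    perm_mean = as.vector(mu),
    perm_sd = as.vector(sd),
    z = as.vector(z),
    p = as.vector(pval),
    outcome = ifelse(as.vector(A) > 0, "true", "predicted"),
    stringsAsFactors = FALSE)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[tab$p <= p_keep, , drop = FALSE]
  tab <- tab[order(tab$p, tab$drug, tab$target), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, n_perm = n_perm, seed = seed, algo = algo),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %d permutations): %d pairs kept\n",
              x$algo, x$n_perm, nrow(x$table)))
  invisible(x)
}
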