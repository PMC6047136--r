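---
title: "Methods: network models, algorithms and design choices in netlinkpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network models, algorithms and design choices in netlinkpred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlinkpred)
```

# The problem

A drug–target interaction network is a bipartite graph: targets (proteins)
in rows, drugs in columns, with a binary adjacency matrix $A$
($n_t \times n_d$, $m$ edges). Experimentally confirmed interactions are
sparse and incomplete, and unobserved pairs are a mixture of true negatives
and undiscovered interactions. netlinkpred ranks the unobserved pairs by
plausibility using only the network topology and, optionally, drug–drug
chemical similarity $S_d$ and target–target sequence similarity $S_t$
supplied as precomputed matrices. The same machinery applies to unipartite
protein–protein interaction graphs, for which the package provides a family
of neighborhood and path-based link predictors plus top-$K$ loopless path
search.

# Bipartite recommenders

**NBI (network-based inference / mass diffusion).** For drug $j$, the
initial resource is its target profile $r = A_{\cdot j}$. Resource flows
targets→drugs, each target splitting equally among its $k(t_l)$ drugs, then
drugs→targets, each drug splitting among its $k(d_i)$ targets:
$$F = A\, D_d^{-1} A^\top D_t^{-1} A.$$
The diffusion conserves each drug column's total resource — this is tested
as an invariant. The sender-splitting rule means popular targets dilute
their evidence, which is what distinguishes NBI from raw co-occurrence
counting.

*Similarity blending.* How the original method combined the similarity
matrices with the diffusion is not specified beyond "uses" them; this
package post-/pre-multiplies the topology score with row-normalized
similarities, $F' = \hat S_t\, F\, \hat S_d^\top$, which averages each
pair's diffusion score over its similarity neighborhoods. Identity
similarities reproduce topology-only NBI exactly, so the blended variant
degrades gracefully. This is a documented design choice, not the only
defensible one.

**HeatS.** The heat-conduction analogue: receivers average incoming
resource instead of senders splitting it,
$F = D_t^{-1} A\, D_d^{-1} A^\top A$. It uses only the bipartite matrix.

**Heterogeneous RWR.** Drugs and targets form one walk space. Within-layer
moves follow row-normalized $S_d$ or $S_t$ with weight $1-\lambda$;
cross-layer jumps follow the row-normalized adjacency with weight
$\lambda$; a node with no bipartite links keeps weight 1 within its layer.
For each drug the walker restarts at that drug with probability $c$; the
target block of the stationary distribution scores its candidate targets.
Defaults $c = 0.7$, $\lambda = 0.5$ follow the heterogeneous-RWR
literature; the stationary vector is found by iterating
$p \leftarrow (1-c) M^\top p + c\,e_s$ to an $L_1$ tolerance of $10^{-9}$
(cap $10^4$ iterations; failure raises a distinct non-convergence
condition). Restarting at a point mass on the drug (rather than uniformly
on its known targets) is a deliberate simplification.

**netcombo.** NBI and heterogeneous-RWR scores live on incomparable
scales, so each matrix is min–max scaled to $[0,1]$ over the unknown pairs
before entrywise averaging.

**Degree baseline.** `degree_product_score()` ranks pair $(t_l, d_i)$ by
$k(t_l) k(d_i)$. It is the popularity-only null any informative
recommender must beat, and `benchmark()` accepts it as `algo = "degree"`.

# Unipartite link prediction

Nine neighborhood indices (common neighbors, Jaccard, cosine/Salton, hub
promoted, hub depressed, Adamic–Adar, preferential attachment, resource
allocation, Leicht–Holme–Newman) are computed from the binarized
adjacency via matrix products; each is verified against a brute-force
implementation that materializes the neighbor sets. Conventions: ratio
indices define $0/0 = 0$ so isolated nodes score 0 rather than NaN, and
Adamic–Adar skips degree-1 common neighbors whose $\ln k$ would vanish
(relevant only on the diagonal for simple graphs). Note that preferential
attachment, being degree-only, is the one index that does not vanish
across disconnected components.

Path-based scores: the local-path index $S = A^2 + \varepsilon A^3$
(default $\varepsilon = 0.01$, the value conventional in the literature;
$A^3$ counts walks, so adjacent nodes on a 4-cycle score $4\varepsilon$,
not the two simple paths); the Katz resolvent
$S = (I - \beta A)^{-1} - I$ with an explicit spectral-radius guard
($\beta \ge 1/\rho(A)$ is refused, reporting the bound); geodesic
similarity $1/d(x,y)$ with 0 for unreachable pairs; exact hitting times
$H_{x,y}$ solved per connected component from the first-step linear
system (reported raw — lower is closer — and negated by the ranker); and
unipartite RWR with restart $c = 0.3$ (isolated nodes receive an implicit
self-loop so every stationary column remains a probability vector).

# Community detection

Barber's bipartite modularity
$$Q_B = \frac{1}{m} \sum_{l,i} \left(A_{li} - \frac{k(t_l)k(d_i)}{m}\right)
\delta(c_{t_l}, c_{d_i})$$
scores a joint partition of targets and drugs. LP-BRIM first runs
label propagation — every node starts in its own module and, in a seeded
random sweep order, adopts the most frequent label among its bipartite
neighbors, ties broken uniformly at random under the seed — and then BRIM
refinement, which alternates moving every drug to its $Q_B$-maximizing
module given the targets and vice versa until the improvement falls below
$10^{-12}$. Refinement is a hill climb: $Q_B$ never decreases, an
invariant the tests assert.

Two points the underlying algorithm leaves open are fixed here: the sweep
order is a fresh seeded shuffle per iteration, and label propagation stops
on label stability or when a sweep *lowers* $Q_B$ (neutral relabeling
sweeps may continue, bounded by a 100-sweep cap). Stopping on any
non-increase can freeze pre-consensus labels on perfectly modular graphs.
`lpbrim()` takes the best of 5 restarts by default, sub-seeded from the
run seed; empty modules are compacted. Recovery quality against a known
partition is measured by normalized mutual information with
arithmetic-mean normalization, $2I/(H_1+H_2)$.

# Top-K loopless paths

`shortest_path()` is Dijkstra on non-negative weights with a deterministic
tie-break: among equal-length shortest paths, the lexicographically
smallest node sequence wins (with strictly positive weights, predecessors
finalize first, so a per-node best-path comparison is sound).
`yen_k_shortest()` builds on it with the spur-node construction: for each
prefix of the last accepted path it masks the prefix nodes and the
continuation edges of all known paths sharing that prefix, collects
deviation candidates (deduplicated across spur nodes), and repeatedly
accepts the (length, lexicographic sequence)-minimal candidate. Candidate
lengths are recomputed over the whole node sequence so equal-length ties
compare consistently. The result provably matches exhaustive enumeration
of all loopless paths sorted by (length, node sequence), which is how the
tests check it. Unweighted graphs use unit weights on the same code path.

# Evaluation protocols

**Link-removal benchmark.** Each repetition hides
$\lfloor \text{fraction} \cdot m \rfloor$ interactions (default 20%),
retrains the chosen scorer on the reduced network, ranks all non-training
pairs, and treats the hidden edges as actives. Removal is uniform by
default; a degree-weighted mode (probability $\propto k(d_i)k(t_l)$)
reflects removal biased toward frequently interacting nodes. Ranks feed
five early-recognition metrics:

- AUC $= 1 - \left(\sum r_i - n(n+1)/2\right)/(n(N-n))$ — Mann–Whitney
  concordance;
- AUAC $= 1 - \frac{1}{n}\sum r_i/N$ — area under the accumulation curve;
- AUCTOP — AUC of the list truncated at the top
  $\lceil \chi N \rceil$ rows. The literature does not fix how actives
  below the cutoff enter; here they count as missed (zero concordance)
  while the denominator stays $n(N-n)$, so the statistic rewards only
  early placements and is bounded by the fraction of actives that can fit
  in the window;
- BEDROC with exponential weight $\alpha$ (default 20), via the RIE
  closed-form rescaling; verified against an independent min–max rescaling
  route;
- EF at fraction $\chi$ (default 0.1): the actives rate in the top window
  over the overall rate.

**Permutation test.** Observed scores come from the intact network; the
null rescores degree-preserving rewirings of the adjacency (checkerboard
swaps — $2\times 2$ submatrix flips that exactly preserve both degree
sequences — with a burn-in of $10m$ swaps and $m$ swaps between samples).
The per-pair null is conditioned on the pair's observed edge status:
a non-edge pair is compared only against permutations in which it remains
a non-edge. Without that conditioning the null mixes in rewirings that
place an edge at the position, whose direct adjacency contribution
dominates the score, and every predicted pair looks spuriously
unremarkable. With it, p-values on structureless networks are uniform (a
Kolmogorov–Smirnov check in the test suite and acceptance script).
Significance is upper-tail standard normal on $z = (s - \mu)/\sigma$;
pairs with zero or inestimable null spread get the sentinel $p = 0.5$.
Raw p-values are reported alongside Benjamini–Hochberg q-values; only the
adjacency is permuted, similarities are left intact. Networks that admit
no checkerboard swap (e.g. complete bipartite) are refused.

# Synthetic study generator

`gen_bipartite()` plants module structure: drugs and targets are split
near-evenly into blocks, with edge probabilities $p_{in}$ within and
$p_{out}$ across blocks, and any empty row or column repaired with one
forced within-block edge. `gen_similarity()` mixes the Jaccard similarity
of interaction profiles (the signal — mimicking how chemical or sequence
similarity tracks shared targets) with symmetric uniform noise:
$S = w \cdot \text{Jaccard} + (1-w) \cdot \text{noise}$, diagonal forced
to 1. The default study — 50 drugs, 40 targets, 4 modules, $p_{in} = 0.5$,
$p_{out} = 0.02$, signal weight 0.8 — is sized so that every algorithm has
learnable structure at interactive runtimes; the copy in
`inst/extdata/` was written by this generator at seed 1.

What the generator does *not* emulate: real degree distributions are far
more skewed, chemical similarity is not a noisy Jaccard of target
profiles, and real benchmark sets have hub drugs and promiscuous targets.
Passing tests on these fixtures demonstrate algorithmic correctness and
sane relative behavior (diffusion and walk methods beat the degree
baseline; the combination tracks its children), not expected performance
on curated interaction databases.

# Problem sizes and numerical choices

The test suite verifies oracle equivalence on 200 random graphs (up to 30
nodes) for the neighborhood indices, 500 random rank configurations for
the metrics, and 300 random graphs (up to 12 nodes) for Yen's algorithm
against exhaustive enumeration; benchmarks in the statistical checks use
the 50×40 study at 10 repetitions and permutation calibration uses 200
permutations. Convergence tolerances are $10^{-9}$ ($L_1$) for all
random-walk fixed points; BRIM stops below $10^{-12}$ improvement;
similarity matrices tolerate asymmetry up to $10^{-6}$ (symmetrized) and
are written with 12 significant digits. All randomized procedures are
reproducible from integer seeds, and every ordering exposed to users has
a deterministic label tie-break.

# Known limitations

- The similarity-blending scheme for NBI is one defensible reading of an
  underspecified description; results with strongly informative
  similarities will depend on it.
- Hitting times and Katz use dense linear solves: fine for projection
  graphs and curated PPI subnetworks, not for genome-scale interactomes.
- The permutation null preserves degrees exactly but samples via MCMC;
  consecutive samples are mildly correlated, which slightly widens the
  effective error of the null moments at small `n_perm`.
- p-values rely on a normal approximation of the per-pair null; for very
  sparse networks or tiny `n_perm` the discrete null makes them coarse.
- No matrix-factorization or kernel recommenders are included; the scope
  is network diffusion, random walks, and their evaluation.
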