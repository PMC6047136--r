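# Data model and I/O: bipartite networks, similarity matrices, unipartite
# graphs, one-mode projection and network properties.

#' Construct a bipartite drug-target network
#'
#' The central prediction substrate: a binary adjacency matrix with target
#' proteins in rows and drugs in columns.
#'
#' @param adjacency numeric matrix with entries in \{0, 1\}; rownames are
#'   target labels, colnames are drug labels (both required and unique).
#' @return An object of class `bipartite_network` with fields `adjacency`,
#'   `target_labels`, `drug_labels`.
#' @examples
#' A <- matrix(c(1, 1, 0, 1), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("d1", "d2")))
#' net <- bipartite_network(A)
#' n_edges(net)
#' @export
bipartite_network <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) < 1L || ncol(adjacency) < 1L)
    stop_format("adjacency must be a non-empty matrix")
  bad <- which(matrix(!(adjacency %in% c(0, 1)), nrow(adjacency)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_format(sprintf(
      "non-binary entry %s at row %s, column %s",
      format(adjacency[bad[1L, , drop = FALSE]]),
      rowname_or_index(adjacency, bad[1L, 1L], 1L),
      rowname_or_index(adjacency, bad[1L, 2L], 2L)))
  if (is.null(rownames(adjacency)) || is.null(colnames(adjacency)))
    stop_format("adjacency must carry target rownames and drug colnames")
  check_unique_labels(rownames(adjacency), "target")
  check_unique_labels(colnames(adjacency), "drug")
  storage.mode(adjacency) <- "double"
  structure(
    list(adjacency = adjacency,
         target_labels = rownames(adjacency),
         drug_labels = colnames(adjacency)),
    class = "bipartite_network")
}

rowname_or_index <- function(m, i, axis) {
  nm <- dimnames(m)[[axis]]
  if (is.null(nm)) as.character(i) else sprintf("'%s'", nm[i])
}

check_unique_labels <- function(labels, what) {
  if (anyDuplicated(labels))
    stop_format(sprintf("duplicate %s label '%s'", what,
                        labels[duplicated(labels)][1L]))
  if (any(!nzchar(labels)))
    stop_format(sprintf("empty %s label", what))
  invisible(labels)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("Bipartite network: %d targets x %d drugs, %d interactions\n",
              n_targets(x), n_drugs(x), n_edges(x)))
  invisible(x)
}

#' Counts of a bipartite network
#' @param net a `bipartite_network`.
#' @return Integer count.
#' @export
n_targets <- function(net) nrow(net$adjacency)

#' @rdname n_targets
#' @export
n_drugs <- function(net) ncol(net$adjacency)

#' @rdname n_targets
#' @export
n_edges <- function(net) as.integer(sum(net$adjacency))

#' Construct a drug-drug or target-target similarity matrix
#'
#' Side information for the bipartite recommenders: chemical similarity
#' between drugs or sequence similarity between targets, precomputed
#' externally. Must be square and symmetric with unit diagonal and
#' off-diagonal values in \[0, 1\].
#'
#' @param values square numeric matrix with matching row/col labels.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values) {
  if (!is.matrix(values) || nrow(values) != ncol(values) || nrow(values) < 1L)
    stop_format("similarity matrix must be square and non-empty")
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values)
  if (is.null(colnames(values)))
    colnames(values) <- rownames(values)
  if (is.null(rownames(values)))
    stop_format("similarity matrix must carry labels")
  if (!identical(rownames(values), colnames(values)))
    stop_format("similarity matrix row and column labels differ")
  check_unique_labels(rownames(values), "similarity")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-6)
    stop_format(sprintf("similarity matrix asymmetry %.3g exceeds 1e-6", asym))
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > 1e-9)
    stop_format("similarity matrix diagonal must equal 1")
  off <- values[row(values) != col(values)]
  if (any(off < 0 | off > 1))
    stop_format("off-diagonal similarity values must lie in [0, 1]")
  structure(list(values = values, labels = rownames(values)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Similarity matrix: %d x %d\n", length(x$labels),
              length(x$labels)))
  invisible(x)
}

#' Construct an undirected unipartite graph
#'
#' Used for one-mode projections of bipartite networks and for
#' protein-protein interaction graphs. Edge weights are non-negative reals;
#' 0 means no edge; the diagonal must be zero (no self-loops).
#'
#' @param adjacency square symmetric numeric matrix with labels.
#' @param weighted logical; if `NULL`, detected from the entries (any value
#'   other than 0/1 makes the graph weighted).
#' @return An object of class `unipartite_graph` with fields `adjacency`,
#'   `labels`, `weighted`.
#' @export
unipartite_graph <- function(adjacency, weighted = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency) ||
      nrow(adjacency) < 1L)
    stop_format("unipartite adjacency must be square and non-empty")
  if (is.null(rownames(adjacency))) rownames(adjacency) <- colnames(adjacency)
  if (is.null(colnames(adjacency))) colnames(adjacency) <- rownames(adjacency)
  if (is.null(rownames(adjacency)))
    stop_format("unipartite adjacency must carry labels")
  check_unique_labels(rownames(adjacency), "node")
  if (max(abs(adjacency - t(adjacency))) > 1e-9)
    stop_format("unipartite adjacency must be symmetric (undirected graph)")
  adjacency <- (adjacency + t(adjacency)) / 2
  if (any(adjacency < 0))
    stop_format("edge weights must be non-negative")
  if (any(diag(adjacency) != 0))
    stop_format("self-loops are not allowed (diagonal must be zero)")
  if (is.null(weighted))
    weighted <- !all(adjacency %in% c(0, 1))
  storage.mode(adjacency) <- "double"
  structure(list(adjacency = adjacency, labels = rownames(adjacency),
                 weighted = isTRUE(weighted)),
            class = "unipartite_graph")
}

#' @export
print.unipartite_graph <- function(x, ...) {
  cat(sprintf("Unipartite graph: %d nodes, %d edges%s\n",
              length(x$labels), sum(x$adjacency > 0) / 2,
              if (x$weighted) " (weighted)" else ""))
  invisible(x)
}

# internal: igraph view of a unipartite_graph
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(
    g$adjacency, mode = "undirected",
    weighted = if (g$weighted) TRUE else NULL, diag = FALSE)
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first))
    stop_format(sprintf("empty file: %s", path))
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else ","
}

read_labelled_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      row.names = 1L, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e)
      stop_format(sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop_format(sprintf("empty matrix in %s", path))
  as.matrix(df)
}

#' Read a bipartite adjacency matrix from a delimited file
#'
#' Expects a header row of drug labels and a first column of target labels;
#' body entries must be 0 or 1. The delimiter is auto-detected from the
#' header line (tab vs comma) unless given explicitly.
#'
#' @param path path to a CSV/TSV file.
#' @param delimiter single character, or `NULL` to auto-detect.
#' @return A [bipartite_network()].
#' @export
read_bipartite_matrix <- function(path, delimiter = NULL) {
  m <- read_labelled_matrix(path, delimiter)
  if (!is.numeric(m))
    stop_format(sprintf("non-numeric entries in %s", path))
  bipartite_network(m)
}

#' Write a bipartite network to a delimited file
#'
#' Round-trips bit-exactly through [read_bipartite_matrix()].
#'
#' @param net a `bipartite_network`.
#' @param path output path.
#' @param delimiter field delimiter (default comma).
#' @export
write_bipartite_matrix <- function(net, path, delimiter = ",") {
  write_labelled_matrix(net$adjacency, path, delimiter,
                        fmt = function(v) format(v, trim = TRUE,
                                                 scientific = FALSE))
}

write_labelled_matrix <- function(m, path, delimiter = ",",
                                  fmt = function(v) sprintf("%.12g", v)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = delimiter), con)
  body <- apply(m, 1L, function(r) paste(fmt(r), collapse = delimiter))
  writeLines(paste(rownames(m), body, sep = delimiter), con)
  invisible(path)
}

#' Read a similarity matrix from a delimited file
#'
#' Small asymmetries (at most 1e-6, e.g. from limited print precision) are
#' symmetrized as (S + t(S))/2; anything larger is an error.
#'
#' @inheritParams read_bipartite_matrix
#' @return A [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, delimiter = NULL) {
  similarity_matrix(read_labelled_matrix(path, delimiter))
}

#' Write a similarity matrix to a delimited file
#'
#' Values are printed with 12 significant digits, so a read/write cycle is
#' stable to that precision.
#'
#' @param sim a `similarity_matrix`.
#' @inheritParams write_bipartite_matrix
#' @export
write_similarity_matrix <- function(sim, path, delimiter = ",") {
  write_labelled_matrix(sim$values, path, delimiter)
}

#' Read a unipartite graph from an adjacency matrix or edge-list file
#'
#' Edge lists are 2- or 3-column delimited files
#' (`source<TAB>target[<TAB>weight]`, no header); adjacency files follow the
#' labelled-matrix layout of [read_bipartite_matrix()]. With
#' `format = "auto"`, files whose rows have at most 3 fields and whose first
#' data row is non-numeric in both leading fields are treated as edge lists.
#'
#' @param path input path.
#' @param format one of `"auto"`, `"adjacency"`, `"edgelist"`.
#' @param delimiter single character, or `NULL` to auto-detect.
#' @return A [unipartite_graph()].
#' @export
read_unipartite_graph <- function(path,
                                  format = c("auto", "adjacency", "edgelist"),
                                  delimiter = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  if (format == "auto") {
    first <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1L]]
    format <- if (length(first) <= 3L) "edgelist" else "adjacency"
  }
  if (format == "adjacency")
    return(unipartite_graph(read_labelled_matrix(path, delimiter)))
  df <- utils::read.table(path, header = FALSE, sep = delimiter,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L)
    stop_format("edge list needs at least source and target columns")
  w <- if (ncol(df) >= 3L) as.numeric(df[[3L]]) else rep(1, nrow(df))
  if (anyNA(w)) stop_format("non-numeric edge weight in edge list")
  labels <- sort(unique(c(as.character(df[[1L]]), as.character(df[[2L]]))))
  adj <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  for (k in seq_len(nrow(df))) {
    a <- as.character(df[[1L]][k]); b <- as.character(df[[2L]][k])
    if (a == b) stop_format(sprintf("self-loop on node '%s' in edge list", a))
    adj[a, b] <- w[k]; adj[b, a] <- w[k]
  }
  unipartite_graph(adj, weighted = !all(w == 1))
}

#' One-mode projection of a bipartite network
#'
#' Two drugs are connected if they share at least one target (and
#' symmetrically for targets sharing a drug). The projection is unweighted
#' and undirected with no self-loops.
#'
#' @param net a `bipartite_network`.
#' @param side which node set to project onto: `"drugs"` or `"targets"`.
#' @return A [unipartite_graph()] on the chosen node set.
#' @export
project <- function(net, side = c("drugs", "targets")) {
  side <- match.arg(side)
  A <- net$adjacency
  co <- if (side == "drugs") crossprod(A) else tcrossprod(A)
  adj <- (co > 0) * 1
  diag(adj) <- 0
  unipartite_graph(adj, weighted = FALSE)
}

#' Bipartite network properties
#'
#' Node counts, interaction count, density, per-node degree, and node
#' betweenness computed on the two one-mode projections (unnormalized,
#' unweighted shortest-path betweenness).
#'
#' @param net a `bipartite_network`.
#' @return A list of class `property_report` with fields `n_drugs`,
#'   `n_targets`, `n_interactions`, `density`, `degree_drugs`,
#'   `degree_targets`, `betweenness_drugs`, `betweenness_targets`.
#' @export
bipartite_properties <- function(net) {
  A <- net$adjacency
  deg_d <- colSums(A)
  deg_t <- rowSums(A)
  btw <- function(side) {
    g <- as_igraph(project(net, side))
    igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  }
  structure(list(
    n_drugs = n_drugs(net),
    n_targets = n_targets(net),
    n_interactions = n_edges(net),
    density = sum(A) / (nrow(A) * ncol(A)),
    degree_drugs = deg_d,
    degree_targets = deg_t,
    betweenness_drugs = btw("drugs"),
    betweenness_targets = btw("targets")),
    class = "property_report")
}

#' @export
print.property_report <- function(x, ...) {
  cat(sprintf(paste0("Bipartite properties: %d drugs, %d targets, ",
                     "%d interactions, density %.4f\n"),
              x$n_drugs, x$n_targets, x$n_interactions, x$density))
  invisible(x)
}

#' Induced subgraph on a list of nodes
#'
#' Keeps the listed nodes and every edge among them, preserving weights.
#' Labels absent from the graph are reported with a warning and skipped
#' (protein lists pasted from external sources routinely contain strays);
#' an empty intersection is an error.
#'
#' @param g a `unipartite_graph`.
#' @param nodes character vector of node labels.
#' @return A [unipartite_graph()] restricted to the known labels, in graph
#'   order.
#' @export
induced_subgraph <- function(g, nodes) {
  nodes <- unique(as.character(nodes))
  unknown <- setdiff(nodes, g$labels)
  if (length(unknown) > 0L)
    warning(sprintf("skipping %d unknown label(s): %s", length(unknown),
                    paste(utils::head(unknown, 5L), collapse = ", ")),
            call. = FALSE)
  keep <- intersect(g$labels, nodes)
  if (length(keep) == 0L)
    stop_format("none of the requested nodes are present in the graph")
  unipartite_graph(g$adjacency[keep, keep, drop = FALSE],
                   weighted = g$weighted)
}

# condition helpers: input/format problems vs numerical non-convergence,
# so the CLI can map them to distinct exit codes.
stop_format <- function(msg) {
  stop(structure(class = c("nlp_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

stop_noconv <- function(msg) {
  stop(structure(class = c("nlp_convergence_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
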