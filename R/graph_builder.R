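# Conversion of connectivity matrices into the complete, undirected, weighted
# graphs the two graph branches consume. Node features are initialised to 1 so
# that everything a branch learns is attributable to edge weights alone.

#' Construct a brain graph
#'
#' A complete undirected weighted graph without self-loops. Edges enumerate all
#' unordered node pairs in column-major upper-triangle order; zero-weight edges
#' are retained (no sparsification).
#'
#' @param weights square symmetric numeric matrix of edge weights (diagonal
#'   ignored); signed for FNC, nonnegative for SC.
#' @param node_names node labels.
#' @param kind `"FNC"` or `"SC"`.
#' @return object of class `brain_graph` with fields `n_nodes`,
#'   `node_features` (all 1), `edges` (m x 2 integer matrix), `edge_weights`,
#'   `adjacency` (weights with zero diagonal), `node_names`, `kind`.
#' @export
brain_graph <- function(weights, node_names = NULL, kind = c("FNC", "SC")) {
  kind <- match.arg(kind)
  check_square_symmetric(weights, what = "weight matrix")
  n <- nrow(weights)
  if (kind == "SC" && min(weights[row(weights) != col(weights)]) < 0)
    stopf("SC graph weights must be nonnegative")
  if (is.null(node_names)) node_names <- rownames(weights) %||% sprintf("n%02d", seq_len(n))
  A <- weights
  diag(A) <- 0
  ut <- which(upper.tri(A), arr.ind = TRUE)
  structure(list(n_nodes = n,
                 node_features = rep(1, n),
                 edges = ut,
                 edge_weights = A[upper.tri(A)],
                 adjacency = A,
                 node_names = node_names,
                 kind = kind),
            class = "brain_graph")
}

#' Pearson FNC matrix from node time courses
#'
#' @param timecourses `n_timepoints x n_nodes` matrix (columns are node time
#'   series; at least 3 timepoints, no constant series).
#' @param node_names optional node labels.
#' @return a [connectivity_matrix()] of kind FNC with unit diagonal.
#' @export
compute_fnc <- function(timecourses, node_names = NULL) {
  tc <- as.matrix(timecourses)
  if (nrow(tc) < 3) stopf("need at least 3 timepoints, got %d", nrow(tc))
  sds <- apply(tc, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(tc) %||% as.character(seq_len(ncol(tc)))
    stopf("constant time series at node(s): %s", paste(nm[sds == 0], collapse = ", "))
  }
  R <- stats::cor(tc)
  diag(R) <- 1
  connectivity_matrix(R, kind = "FNC",
                      node_names = node_names %||% colnames(tc))
}

#' Build the functional graph from an FNC matrix
#'
#' Edge weights are the FNC correlation values, keeping both positive and
#' negative correlations; the diagonal is discarded and node features are 1.
#' @param m a [connectivity_matrix()] of kind FNC.
#' @export
fnc_to_graph <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (m$kind != "FNC") stopf("expected an FNC matrix, got %s", m$kind)
  brain_graph(m$values, m$node_names, kind = "FNC")
}

#' Build the structural graph from an SC matrix
#'
#' Edge weights are streamline counts; pairs with zero streamlines stay in the
#' graph as weight-0 edges and node features are 1.
#' @param m a [connectivity_matrix()] of kind SC.
#' @export
sc_to_graph <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (m$kind != "SC") stopf("expected an SC matrix, got %s", m$kind)
  brain_graph(m$values, m$node_names, kind = "SC")
}

#' Recover the connectivity matrix underlying a brain graph
#'
#' For FNC graphs the diagonal is restored to 1 (self-correlation); for SC it
#' stays 0. Round trip matrix -> graph -> matrix is the identity.
#' @param g a [brain_graph()].
#' @export
graph_to_matrix <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  vals <- g$adjacency
  if (g$kind == "FNC") diag(vals) <- 1
  connectivity_matrix(vals, kind = g$kind, node_names = g$node_names)
}

#' Write a brain graph as an edge-list TSV (node_i, node_j, weight)
#' @param g a [brain_graph()].
#' @param path output path.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "brain_graph"))
  df <- data.frame(node_i = g$node_names[g$edges[, 1]],
                   node_j = g$node_names[g$edges[, 2]],
                   weight = g$edge_weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("brain_graph (%s): %d nodes, %d edges (complete), unit node features\n",
              x$kind, x$n_nodes, nrow(x$edges)))
  invisible(x)
}
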