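# Stage 2: Spearman collinearity network over screening candidates and
# AUC-ranked pruning to a non-collinear biomarker set.

#' Build the Spearman collinearity network over candidate features
#'
#' Computes all pairwise Spearman correlations between candidate features on
#' the supplied (training) samples and draws an edge wherever
#' `|rho| > rho_threshold`.  Nodes carry the candidates' screening AUCs.
#'
#' @param matrix An [expression_matrix()] restricted to training samples; must
#'   contain every candidate feature.
#' @param candidates Data frame with columns `feature_id`, `auc` (as produced
#'   by [screen_features()]).
#' @param rho_threshold Absolute-correlation threshold, exclusive
#'   (default 0.5).
#' @return Object of class `collinearity_network`: list with `nodes`
#'   (data.frame feature_id, auc), `edges` (data.frame from, to, rho) and
#'   `rho_threshold`.
#' @export
build_network <- function(matrix, candidates, rho_threshold = 0.5) {
  stopifnot(inherits(matrix, "expression_matrix"))
  candidates <- as.data.frame(candidates)
  if (!all(c("feature_id", "auc") %in% names(candidates))) {
    stop2("`candidates` needs columns feature_id and auc")
  }
  if (!nrow(candidates)) stop2("no candidate features")
  ids <- as.character(candidates$feature_id)
  missing <- setdiff(ids, matrix$feature_ids)
  if (length(missing)) stop2("candidate '", missing[1], "' not in matrix")
  sub <- matrix$values[ids, , drop = FALSE]
  const <- which(apply(sub, 1L, function(r) max(r) == min(r)))
  if (length(const)) stop2("feature '", ids[const[1]], "' is constant")

  edges <- data.frame(from = character(0), to = character(0),
                      rho = numeric(0), stringsAsFactors = FALSE)
  if (length(ids) > 1L) {
    ranks <- t(apply(sub, 1L, rank))
    rho <- stats::cor(t(ranks)) # Pearson on midranks = Spearman
    idx <- which(upper.tri(rho) & abs(rho) > rho_threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                          rho = rho[idx], stringsAsFactors = FALSE)
    }
  }
  nodes <- data.frame(feature_id = ids, auc = as.numeric(candidates$auc),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, rho_threshold = rho_threshold),
            class = "collinearity_network")
}

#' Construct a collinearity network directly
#'
#' Mostly useful for tests and for loading externally computed networks;
#' [build_network()] is the normal route.
#'
#' @param nodes Data frame with columns `feature_id`, `auc` (may be empty).
#' @param edges Data frame with columns `from`, `to`, `rho` (may be empty).
#' @param rho_threshold The threshold the edges satisfy.
#' @return A `collinearity_network`.
#' @export
collinearity_network <- function(nodes, edges = NULL, rho_threshold = 0.5) {
  nodes <- as.data.frame(nodes)
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        rho = numeric(0), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop2("self-edge in network")
    unknown <- setdiff(c(edges$from, edges$to), nodes$feature_id)
    if (length(unknown)) stop2("edge references unknown node: ", unknown[1])
    if (any(abs(edges$rho) <= rho_threshold)) {
      stop2("edge with |rho| <= threshold")
    }
  }
  structure(list(nodes = nodes, edges = edges, rho_threshold = rho_threshold),
            class = "collinearity_network")
}

#' @export
print.collinearity_network <- function(x, ...) {
  cat("collinearity_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (|rho| >", x$rho_threshold, ")\n")
  invisible(x)
}

#' Prune a collinearity network by descending AUC
#'
#' Visits nodes in descending-AUC order (ties broken lexicographically by
#' feature ID) and retains a node iff it has no edge *in the original
#' network* to an already-retained node.  This generalizes the pairwise rule
#' "of two collinear features, keep the one with the larger AUC" to chains
#' and cliques; a node whose only collinear partner was itself dropped is
#' retained.
#'
#' @param network A `collinearity_network`.
#' @return Character vector of retained feature IDs in descending-AUC order.
#' @export
prune_network <- function(network) {
  stopifnot(inherits(network, "collinearity_network"))
  nodes <- network$nodes
  if (!nrow(nodes)) return(character(0))
  ord <- order(-nodes$auc, nodes$feature_id)
  adj <- split(c(network$edges$to, network$edges$from),
               c(network$edges$from, network$edges$to))
  retained <- character(0)
  for (id in nodes$feature_id[ord]) {
    if (!length(intersect(adj[[id]], retained))) {
      retained <- c(retained, id)
    }
  }
  retained
}

#' Export a collinearity network as SIF plus node attributes
#'
#' Writes a Cytoscape-loadable SIF file (`node1 co node2` per edge; isolated
#' nodes as bare lines) and a node-attribute TSV (`feature_id`, `auc`).
#'
#' @param network A `collinearity_network`.
#' @param sif_path Output SIF path.
#' @param node_attr_path Output TSV path (default: `sif_path` with a
#'   `.nodes.tsv` suffix).
#' @return `sif_path`, invisibly.
#' @export
export_network <- function(network, sif_path,
                           node_attr_path = paste0(sif_path, ".nodes.tsv")) {
  stopifnot(inherits(network, "collinearity_network"))
  linked <- unique(c(network$edges$from, network$edges$to))
  isolated <- setdiff(network$nodes$feature_id, linked)
  lines <- c(if (nrow(network$edges))
               paste(network$edges$from, "co", network$edges$to),
             isolated)
  con <- tryCatch(file(sif_path, "w"),
                  error = function(e) stop2("cannot write ", sif_path))
  writeLines(lines, con)
  close(con)
  write_tsv_table(network$nodes, node_attr_path)
  invisible(sif_path)
}
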