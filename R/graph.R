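# Internal node/type key separator for the hashed adjacency indices. Node ids
# and type labels come from TSV columns so they can never contain a tab.
.SEP <- "\t"

.key <- function(a, b) paste(a, b, sep = .SEP)

#' Construct a typed heterogeneous network
#'
#' Builds a schema-validated undirected network from a node table and an edge
#' table. Edges are stored undirected; duplicate rows (in either direction)
#' collapse to one edge; self-loops are dropped with a warning, since the
#' traversal model gives them no meaning. Parallel edges of the same type
#' between the same pair collapse, but the same pair may be joined by several
#' edges of different types.
#'
#' @param nodes Data frame with columns \code{id} and \code{class}.
#' @param edges Data frame with columns \code{source}, \code{type},
#'   \code{target} and optionally \code{weight}.
#' @param schema A [slap_schema]; every node class and edge type must be
#'   declared in it, and each edge's endpoint classes must match the classes
#'   its type declares.
#' @param max_weight Optional named numeric vector mapping edge-type labels to
#'   a weight cutoff: edges of that type are kept only if their \code{weight}
#'   is strictly smaller than the cutoff (e.g. a binding-affinity cutoff in
#'   micromolar for \code{bind} edges). Types not named are kept unfiltered.
#'   Default \code{NULL}: no filtering.
#' @return An object of class \code{semantic_graph}.
#' @export
semantic_graph <- function(nodes, edges, schema, max_weight = NULL) {
  stopifnot(inherits(schema, "slap_schema"))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "class") %in% names(nodes))) {
    stop("node table needs columns 'id' and 'class'", call. = FALSE)
  }
  if (!all(c("source", "type", "target") %in% names(edges))) {
    stop("edge table needs columns 'source', 'type' and 'target'",
         call. = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  nodes$class <- as.character(nodes$class)
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    stop("duplicate node ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(nodes$class), schema$node_classes)
  if (length(bad_class)) {
    stop("node class(es) not in schema: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  node_class <- stats::setNames(nodes$class, nodes$id)

  src <- as.character(edges$source)
  trg <- as.character(edges$target)
  typ <- as.character(edges$type)

  if (!is.null(max_weight)) {
    if (!("weight" %in% names(edges))) {
      stop("max_weight given but edge table has no 'weight' column",
           call. = FALSE)
    }
    w <- as.numeric(edges$weight)
    keep <- rep(TRUE, length(src))
    for (ty in names(max_weight)) {
      sel <- typ == ty
      keep[sel] <- !is.na(w[sel]) & w[sel] < max_weight[[ty]]
    }
    src <- src[keep]; trg <- trg[keep]; typ <- typ[keep]
  }

  self <- src == trg
  if (any(self)) {
    warning(sum(self), " self-loop edge(s) dropped")
    src <- src[!self]; trg <- trg[!self]; typ <- typ[!self]
  }

  missing_ids <- setdiff(unique(c(src, trg)), nodes$id)
  if (length(missing_ids)) {
    stop("edge(s) reference node id(s) absent from the node table: ",
         paste(utils::head(missing_ids, 10), collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(typ), names(schema$edge_types))
  if (length(bad_type)) {
    stop("edge type(s) not in schema: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }

  # canonical undirected representation: endpoints in lexicographic order
  a <- pmin(src, trg)
  b <- pmax(src, trg)
  canon <- paste(a, typ, b, sep = .SEP)
  keep <- !duplicated(canon)
  a <- a[keep]; b <- b[keep]; typ <- typ[keep]

  # endpoint classes must match the schema's declaration for the type
  for (ty in unique(typ)) {
    sel <- typ == ty
    decl <- sort(schema$edge_types[[ty]])
    got <- cbind(node_class[a[sel]], node_class[b[sel]])
    ok <- (pmin(got[, 1], got[, 2]) == decl[1]) &
      (pmax(got[, 1], got[, 2]) == decl[2])
    if (!all(ok)) {
      i <- which(sel)[which(!ok)[1]]
      stop("edge ", a[i], " -", ty, "- ", b[i], " joins classes (",
           node_class[a[i]], ", ", node_class[b[i]],
           ") but type '", ty, "' declares (",
           paste(schema$edge_types[[ty]], collapse = ", "), ")",
           call. = FALSE)
    }
  }

  ord <- order(a, typ, b)
  edges_df <- data.frame(source = a[ord], type = typ[ord], target = b[ord],
                         stringsAsFactors = FALSE)

  g <- structure(list(nodes = node_class[order(names(node_class))],
                      edges = edges_df,
                      schema = schema),
                 class = "semantic_graph")
  g$index <- .build_index(g)
  g
}

# Derives the hashed adjacency indices from the canonical edge table:
#   adj      node -> all distinct neighbors
#   typed    node \t type -> neighbors via that type
#   etypes   u \t v -> types joining u and v (both orders)
.build_index <- function(g) {
  adj <- new.env(hash = TRUE, parent = emptyenv())
  typed <- new.env(hash = TRUE, parent = emptyenv())
  etypes <- new.env(hash = TRUE, parent = emptyenv())
  e <- g$edges
  both_u <- c(e$source, e$target)
  both_v <- c(e$target, e$source)
  both_t <- c(e$type, e$type)
  # per-node neighbor lists
  sp <- split(both_v, both_u)
  for (n in names(sp)) assign(n, sort(unique(sp[[n]])), envir = adj)
  spt <- split(both_v, .key(both_u, both_t))
  for (k in names(spt)) assign(k, sort(unique(spt[[k]])), envir = typed)
  spe <- split(both_t, .key(both_u, both_v))
  for (k in names(spe)) assign(k, sort(unique(spe[[k]])), envir = etypes)
  list(adj = adj, typed = typed, etypes = etypes)
}

.neighbors <- function(g, node) {
  nb <- g$index$adj[[node]]
  if (is.null(nb)) character(0) else nb
}

.typed_neighbors <- function(g, node, type) {
  nb <- g$index$typed[[.key(node, type)]]
  if (is.null(nb)) character(0) else nb
}

.edge_types_between <- function(g, u, v) {
  ty <- g$index$etypes[[.key(u, v)]]
  if (is.null(ty)) character(0) else ty
}

#' Does the graph contain a node?
#' @param graph A [semantic_graph].
#' @param node Node id.
#' @return Logical scalar.
#' @export
has_node <- function(graph, node) {
  !is.na(match(node, names(graph$nodes)))
}

#' Class label of nodes
#' @param graph A [semantic_graph].
#' @param nodes Character vector of node ids.
#' @return Character vector of class labels.
#' @export
node_class <- function(graph, nodes) {
  cls <- graph$nodes[nodes]
  if (anyNA(cls)) {
    stop("unknown node(s): ",
         paste(nodes[is.na(cls)], collapse = ", "), call. = FALSE)
  }
  unname(cls)
}

#' Number of distinct neighbors via one edge type
#'
#' The per-type degree underlying the traversal model: stepping away from a
#' node along an edge of a given type is assigned probability
#' 1 / type_degree(node, type), i.e. an equal chance of reaching each of the
#' node's neighbors within that edge type.
#'
#' @param graph A [semantic_graph].
#' @param node Node id; must exist in the graph.
#' @param edge_type Edge-type label. A type with no incident edge at the node
#'   (including a type absent from the schema) gives degree 0.
#' @return Non-negative integer count of distinct neighbors.
#' @export
type_degree <- function(graph, node, edge_type) {
  if (!has_node(graph, node)) stop("unknown node: ", node, call. = FALSE)
  length(.typed_neighbors(graph, node, edge_type))
}

#' Read a typed network from TSV tables
#'
#' @param node_path TSV with header columns \code{id}, \code{class}.
#' @param edge_path TSV with header columns \code{source}, \code{type},
#'   \code{target} and optionally \code{weight}. Row direction is ignored; the
#'   graph is undirected.
#' @param schema A [slap_schema].
#' @param max_weight Optional per-type weight cutoff, see [semantic_graph()].
#' @return A \code{semantic_graph}. The load report (node counts per class,
#'   edge counts per type) is available through [summary.semantic_graph()].
#' @export
read_graph <- function(node_path, edge_path, schema, max_weight = NULL) {
  for (p in c(node_path, edge_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  nodes <- utils::read.delim(node_path, colClasses = "character",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  semantic_graph(nodes, edges, schema, max_weight = max_weight)
}

#' Write a typed network to TSV tables
#'
#' Inverse of [read_graph()]: writes the node and canonical undirected edge
#' tables. Reading them back yields a graph with the identical edge set.
#'
#' @param graph A [semantic_graph].
#' @param node_path,edge_path Output TSV paths.
#' @return Invisibly, \code{graph}.
#' @export
write_graph_tables <- function(graph, node_path, edge_path) {
  nodes <- data.frame(id = names(graph$nodes), class = unname(graph$nodes),
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(graph)
}

#' Re-validate a graph's internal consistency
#'
#' Checks every structural invariant: declared endpoints and types, class
#' constraints, absence of self-loops, and that the adjacency index agrees
#' exactly with the edge table (re-derived from scratch).
#'
#' @param graph A [semantic_graph].
#' @return \code{TRUE} invisibly; otherwise an error describing the violation.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "semantic_graph"))
  rebuilt <- semantic_graph(
    data.frame(id = names(graph$nodes), class = unname(graph$nodes),
               stringsAsFactors = FALSE),
    graph$edges, graph$schema)
  if (!identical(rebuilt$edges, graph$edges)) {
    stop("edge table is not in canonical form", call. = FALSE)
  }
  idx <- .build_index(graph)
  for (n in names(graph$nodes)) {
    if (!identical(idx$adj[[n]], graph$index$adj[[n]])) {
      stop("adjacency index inconsistent at node ", n, call. = FALSE)
    }
  }
  for (k in ls(idx$typed)) {
    if (!identical(idx$typed[[k]], graph$index$typed[[k]])) {
      stop("typed adjacency index inconsistent", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.semantic_graph <- function(x, ...) {
  cat("semantic_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "undirected typed edges\n")
  invisible(x)
}

#' Load report for a typed network
#' @param object A [semantic_graph].
#' @param ... Unused.
#' @return A list with \code{n_nodes}, \code{n_edges}, \code{nodes_per_class}
#'   and \code{edges_per_type} tables.
#' @export
summary.semantic_graph <- function(object, ...) {
  out <- list(n_nodes = length(object$nodes),
              n_edges = nrow(object$edges),
              nodes_per_class = table(unname(object$nodes)),
              edges_per_type = table(object$edges$type))
  class(out) <- "summary.semantic_graph"
  out
}

#' @export
print.summary.semantic_graph <- function(x, ...) {
  cat("Nodes:", x$n_nodes, " Edges:", x$n_edges, "\n")
  cat("Per class:\n"); print(x$nodes_per_class)
  cat("Per edge type:\n"); print(x$edges_per_type)
  invisible(x)
}

#' Read a drug-target pair list from TSV
#'
#' @param path TSV with header columns \code{source}, \code{target} and
#'   optionally \code{label} (1 = positive, 0 = decoy). Pairs need not all be
#'   present in a graph; unmapped pairs are detected and reported at scoring
#'   time.
#' @return Data frame with columns \code{source}, \code{target}, \code{label}.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!all(c("source", "target") %in% names(df))) {
    stop("pair file needs columns 'source' and 'target'", call. = FALSE)
  }
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  if (is.null(df$label)) df$label <- NA_integer_ else {
    df$label <- as.integer(df$label)
    if (any(!df$label %in% c(0L, 1L), na.rm = TRUE)) {
      stop("pair labels must be 0 or 1", call. = FALSE)
    }
  }
  df[c("source", "target", "label")]
}

#' Write a drug-target pair list to TSV
#' @param pairs Data frame with columns \code{source}, \code{target} and
#'   optionally \code{label}.
#' @param path Output path.
#' @return Invisibly, \code{pairs}.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pairs)
}
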