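#' Construct a network schema
#'
#' A schema declares the node classes a heterogeneous network may contain and
#' the edge types that may connect them. Every edge type names the (unordered)
#' pair of node classes it is allowed to join, e.g. \code{bind} joining
#' \code{Compound} and \code{Target}. Graphs loaded with [read_graph()] are
#' validated against their schema.
#'
#' @param node_classes Character vector of unique, non-empty class labels.
#' @param edge_types Named list; each element is a character vector of length 2
#'   giving the two node classes the edge type may connect (the two may be
#'   equal, e.g. \code{PPI = c("Target", "Target")}). Names are the edge-type
#'   labels.
#' @return An object of class \code{slap_schema} with elements
#'   \code{node_classes} (character) and \code{edge_types} (named list of
#'   length-2 character vectors).
#' @examples
#' sc <- slap_schema(c("Compound", "Target"),
#'                   list(bind = c("Compound", "Target")))
#' sc
#' @seealso [read_schema()], [default_schema()]
#' @export
slap_schema <- function(node_classes, edge_types) {
  node_classes <- as.character(node_classes)
  if (length(node_classes) == 0L || anyNA(node_classes) ||
      any(!nzchar(node_classes))) {
    stop("node classes must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(node_classes)) {
    stop("duplicate node class labels: ",
         paste(unique(node_classes[duplicated(node_classes)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(edge_types) || is.null(names(edge_types)) ||
      any(!nzchar(names(edge_types)))) {
    stop("edge_types must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(edge_types))) {
    stop("duplicate edge type labels: ",
         paste(unique(names(edge_types)[duplicated(names(edge_types))]),
               collapse = ", "), call. = FALSE)
  }
  edge_types <- lapply(edge_types, as.character)
  for (ty in names(edge_types)) {
    cls <- edge_types[[ty]]
    if (length(cls) != 2L) {
      stop("edge type '", ty, "' must declare exactly two node classes",
           call. = FALSE)
    }
    missing_cls <- setdiff(cls, node_classes)
    if (length(missing_cls)) {
      stop("edge type '", ty, "' references undeclared node class(es): ",
           paste(missing_cls, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(node_classes = node_classes, edge_types = edge_types),
            class = "slap_schema")
}

#' Read a schema from a YAML file
#'
#' The file must contain a mapping with two keys: \code{node_classes}, a
#' sequence of class labels, and \code{edge_types}, a mapping from edge-type
#' label to the two node classes it connects. See
#' \code{system.file("extdata", "default_schema.yaml", package = "slapr")}
#' for the bundled default.
#'
#' @param path Path to a YAML schema file.
#' @return A validated [slap_schema] object.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  parsed <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse schema file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(parsed) || is.null(parsed$node_classes) ||
      is.null(parsed$edge_types)) {
    stop("schema file must define 'node_classes' and 'edge_types'",
         call. = FALSE)
  }
  slap_schema(unlist(parsed$node_classes), parsed$edge_types)
}

#' Default heterogeneous-network schema
#'
#' The bundled schema of 10 node classes and 12 edge types covering the
#' entities commonly used to relate drugs and targets: compound-target binding
#' and expression links, target annotation links (GO terms, pathways, tissues,
#' gene families, protein-protein interaction), and compound annotation links
#' (substructures, side effects, chemical ontology terms, disease
#' indications). It is a starting point, not a fixed vocabulary: pass your own
#' YAML file to [read_schema()] to change it.
#'
#' @return A [slap_schema] object.
#' @export
default_schema <- function() {
  read_schema(system.file("extdata", "default_schema.yaml",
                          package = "slapr", mustWork = TRUE))
}

#' @export
print.slap_schema <- function(x, ...) {
  cat("Network schema:", length(x$node_classes), "node classes,",
      length(x$edge_types), "edge types\n")
  cat("  classes:", paste(x$node_classes, collapse = ", "), "\n")
  for (ty in names(x$edge_types)) {
    cat(sprintf("  %s: (%s, %s)\n", ty, x$edge_types[[ty]][1],
                x$edge_types[[ty]][2]))
  }
  invisible(x)
}
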