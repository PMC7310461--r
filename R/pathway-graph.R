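#' Construct a pathway graph
#'
#' A `pathway_graph` holds the directed gene-gene structure of a signaling
#' pathway. Nodes are canonical gene symbols; directed edges point from a
#' parent (upstream regulator) to a child and carry an optional relation
#' label (`"activation"`, `"inhibition"`, or `"unknown"`). Relation labels
#' are retained for export but are not used during parameter estimation:
#' the sign of a relationship is estimated from data, not assumed from
#' curation. Once made acyclic (see [break_cycles()]) the graph serves as
#' the fixed structure of a linear-Gaussian Bayesian network in which each
#' gene is regressed on its parents.
#'
#' @param pathway_id single string identifying the pathway (e.g.
#'   `"hsa:05322"`).
#' @param nodes character vector of gene identifiers. Genes appearing only
#'   in `edges` are added automatically.
#' @param edges `data.frame` with columns `parent`, `child` and optionally
#'   `relation`. Duplicate (parent, child) pairs are collapsed to one edge
#'   and self-loops are dropped (both recorded in `removed_edges`).
#' @param aliases optional named list mapping a gene id to alternate
#'   symbols or platform probe ids.
#' @param removed_edges `data.frame` of edges deleted during construction
#'   or cycle breaking, with columns `parent`, `child`, `reason`.
#' @param skipped_entries `data.frame` describing source entries that could
#'   not be resolved to gene symbols (populated by [parse_kgml()]).
#'
#' @return An object of class `pathway_graph`: a list with elements
#'   `pathway_id`, `nodes` (sorted character vector), `edges`,
#'   `aliases`, `removed_edges`, `skipped_entries`.
#' @seealso [parse_kgml()], [parse_sif()], [break_cycles()], [parents_of()]
#' @export
#' @examples
#' g <- pathway_graph("toy", edges = data.frame(parent = "A", child = "B"))
#' parents_of(g, "B")
pathway_graph <- function(pathway_id, nodes = character(), edges = NULL,
                          aliases = list(), removed_edges = NULL,
                          skipped_entries = NULL) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            nzchar(pathway_id))
  if (is.null(edges)) {
    edges <- data.frame(parent = character(), child = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(edges)))
    stop("`edges` must have columns 'parent' and 'child'")
  if (is.null(edges$relation)) edges$relation <- rep("unknown", nrow(edges))
  edges <- edges[, c("parent", "child", "relation")]
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  edges$relation <- as.character(edges$relation)

  removed <- removed_edges
  if (is.null(removed))
    removed <- data.frame(parent = character(), child = character(),
                          reason = character(), stringsAsFactors = FALSE)

  # self-loops cannot appear in a DAG-structured regression
  loop <- edges$parent == edges$child
  if (any(loop)) {
    removed <- rbind(removed, data.frame(parent = edges$parent[loop],
                                         child = edges$child[loop],
                                         reason = "self-loop"))
    edges <- edges[!loop, , drop = FALSE]
  }
  dup <- duplicated(edges[, c("parent", "child")])
  edges <- edges[!dup, , drop = FALSE]

  nodes <- sort(unique(c(as.character(nodes), edges$parent, edges$child)))
  if (any(!nzchar(nodes))) stop("gene ids must be non-empty strings")

  rownames(edges) <- NULL
  if (is.null(skipped_entries))
    skipped_entries <- data.frame(entry_id = character(), type = character(),
                                  reason = character(), stringsAsFactors = FALSE)
  structure(list(pathway_id = pathway_id, nodes = nodes, edges = edges,
                 aliases = aliases, removed_edges = removed,
                 skipped_entries = skipped_entries),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s': %d genes, %d edges",
              x$pathway_id, length(x$nodes), nrow(x$edges)))
  if (nrow(x$removed_edges) > 0)
    cat(sprintf(" (%d removed)", nrow(x$removed_edges)))
  cat("\n")
  invisible(x)
}

#' Parents of a gene, in deterministic order
#'
#' Returns the lexicographically sorted parent set of `gene_id`, i.e. the
#' regressors of that gene's node model. Root genes return an empty vector.
#'
#' @param g a [pathway_graph()].
#' @param gene_id gene to query; must be a node of `g`.
#' @return Character vector of parent gene ids (possibly empty).
#' @export
parents_of <- function(g, gene_id) {
  stopifnot(inherits(g, "pathway_graph"))
  if (!gene_id %in% g$nodes)
    stop(sprintf("gene '%s' is not in pathway '%s'", gene_id, g$pathway_id))
  sort(g$edges$parent[g$edges$child == gene_id])
}

#' Topological order of an acyclic pathway graph
#'
#' Kahn's algorithm with lexicographic tie-breaking, so the order is unique
#' and stable across runs. Errors if the graph still contains a cycle.
#'
#' @param g a [pathway_graph()].
#' @return Character vector of all gene ids in topological order.
#' @export
topological_order <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  nodes <- g$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(g$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  edges <- g$edges
  while (length(avail) > 0) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    ch <- edges$child[edges$parent == v]
    indeg[ch] <- indeg[ch] - 1L
    newly <- ch[indeg[ch] == 0L]
    if (length(newly)) avail <- sort(c(avail, newly))
    indeg <- indeg[names(indeg) != v | indeg[names(indeg)] >= 0]
    indeg[v] <- NA_integer_
  }
  out <- out[!is.na(out)]
  if (length(out) != length(nodes))
    stop(sprintf("pathway '%s' contains a cycle; run break_cycles() first",
                 g$pathway_id))
  out
}

#' Test whether a pathway graph is acyclic
#'
#' @param g a [pathway_graph()].
#' @return `TRUE` if a topological order exists.
#' @export
is_acyclic <- function(g) {
  ok <- TRUE
  tryCatch(topological_order(g), error = function(e) ok <<- FALSE)
  ok
}

#' Remove cycle-closing edges to obtain a DAG
#'
#' Bayesian-network structure requires acyclicity, but curated signaling
#' pathways contain feedback loops. This deletes a deterministic set of
#' back-edges: a depth-first search is started from every node in
#' lexicographic gene-id order, children are visited in lexicographic
#' order, and any edge pointing to a vertex currently on the DFS stack is
#' deleted. Removed edges are appended to `removed_edges` with reason
#' `"cycle"` so the deletions are auditable.
#'
#' @param g a [pathway_graph()], possibly cyclic.
#' @return An acyclic `pathway_graph` with the same nodes;
#'   `removed_edges` records every deleted edge.
#' @export
break_cycles <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  nodes <- g$nodes
  # adjacency: children sorted so traversal order is fully determined
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    sort(g$edges$child[g$edges$parent == v]))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 white 1 grey 2 black
  drop_parent <- character(0)
  drop_child <- character(0)

  for (root in nodes) {
    if (state[root] != 0L) next
    # iterative DFS keeping a pointer into each node's child list
    stack_v <- root
    stack_i <- 1L
    state[root] <- 1L
    while (length(stack_v) > 0) {
      top <- length(stack_v)
      v <- stack_v[top]
      kids <- adj[[v]]
      i <- stack_i[top]
      if (i > length(kids)) {
        state[v] <- 2L
        stack_v <- stack_v[-top]
        stack_i <- stack_i[-top]
        next
      }
      stack_i[top] <- i + 1L
      w <- kids[i]
      if (state[w] == 1L) {           # back-edge: w is on the current stack
        drop_parent <- c(drop_parent, v)
        drop_child <- c(drop_child, w)
      } else if (state[w] == 0L) {
        state[w] <- 1L
        stack_v <- c(stack_v, w)
        stack_i <- c(stack_i, 1L)
      }
    }
  }

  if (length(drop_parent) == 0) return(g)
  key <- paste(g$edges$parent, g$edges$child, sep = "\r")
  dropkey <- paste(drop_parent, drop_child, sep = "\r")
  keep <- !(key %in% dropkey)
  removed <- rbind(g$removed_edges,
                   data.frame(parent = drop_parent, child = drop_child,
                              reason = "cycle", stringsAsFactors = FALSE))
  out <- pathway_graph(g$pathway_id, nodes = g$nodes,
                       edges = g$edges[keep, , drop = FALSE],
                       aliases = g$aliases, removed_edges = removed,
                       skipped_entries = g$skipped_entries)
  stopifnot(is_acyclic(out))
  out
}

#' Write the removed-edges report
#'
#' @param g a [pathway_graph()].
#' @param path output TSV path (columns parent, child, reason).
#' @return `path`, invisibly.
#' @export
write_removed_edges <- function(g, path) {
  utils::write.table(g$removed_edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
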