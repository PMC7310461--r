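#' Read a pathway from SIF text
#'
#' SIF (simple interaction format) is the three-column tab-separated
#' network format used by Cytoscape and most graph tools:
#' `parent<TAB>relation<TAB>child`, one edge per line. Duplicate
#' (parent, child) lines are collapsed to a single edge; the node set is
#' the union of all endpoints.
#'
#' @param sif either a path to a SIF file or a character vector of SIF
#'   lines.
#' @param pathway_id identifier stored on the resulting graph.
#' @return A [pathway_graph()] (possibly cyclic; see [break_cycles()]).
#' @export
parse_sif <- function(sif, pathway_id = "pathway") {
  lines <- if (length(sif) == 1L && file.exists(sif))
    readLines(sif) else unlist(strsplit(sif, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(pathway_graph(pathway_id))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop(sprintf("SIF line %d has %d fields, expected 3 (parent, relation, child)",
                 which(nf != 3L)[1L], nf[nf != 3L][1L]))
  m <- do.call(rbind, parts)
  pathway_graph(pathway_id,
                edges = data.frame(parent = m[, 1L], child = m[, 3L],
                                   relation = m[, 2L],
                                   stringsAsFactors = FALSE))
}

#' Write a pathway graph as SIF
#'
#' Edges are written in sorted (parent, child) order so that output is
#' deterministic; isolated nodes are not representable in SIF and are
#' omitted with a warning.
#'
#' @param g a [pathway_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  e <- g$edges[order(g$edges$parent, g$edges$child), , drop = FALSE]
  iso <- setdiff(g$nodes, c(e$parent, e$child))
  if (length(iso))
    warning(sprintf("%d isolated gene(s) cannot be represented in SIF: %s",
                    length(iso), paste(iso, collapse = ", ")))
  writeLines(paste(e$parent, e$relation, e$child, sep = "\t"), path)
  invisible(path)
}
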