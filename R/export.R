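#' Export final parameters onto the pathway as GraphML
#'
#' Writes the pathway topology with the merged results attached as
#' attributes, ready for Cytoscape/Gephi styling: every node carries
#' `mu_star` (for color) and `abs_mu_star` (for size), every edge carries
#' `mu_star`; parameters without a final value get 0 and
#' `significant = "no"`. The curated relation label is kept on edges.
#'
#' @param finals a [merge_contrasts()] result (may span pathways; only
#'   rows matching `g$pathway_id` are used).
#' @param g the [pathway_graph()] the parameters were estimated on.
#' @param path output GraphML path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(finals, g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  f <- finals[finals$pathway_id == g$pathway_id, , drop = FALSE]
  fn <- f[f$type == "node", , drop = FALSE]
  fe <- f[f$type == "edge", , drop = FALSE]

  node_score <- stats::setNames(rep(0, length(g$nodes)), g$nodes)
  node_score[fn$child] <- fn$mu_star
  e <- g$edges
  ekey <- paste(e$parent, e$child)
  escore <- stats::setNames(rep(0, nrow(e)), ekey)
  escore[paste(fe$parent, fe$child)] <- fe$mu_star

  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$parent, to = e$child, relation = e$relation,
               mu_star = unname(escore),
               significant = ifelse(ekey %in% paste(fe$parent, fe$child),
                                    "yes", "no"),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$nodes, mu_star = unname(node_score),
                          abs_mu_star = abs(unname(node_score)),
                          significant = ifelse(g$nodes %in% fn$child,
                                               "yes", "no"),
                          stringsAsFactors = FALSE))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write a final-parameters table as TSV
#'
#' @param finals a [merge_contrasts()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_final_parameters <- function(finals, path) {
  utils::write.table(as.data.frame(finals), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
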