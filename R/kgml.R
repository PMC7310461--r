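#' Parse a KGML pathway document
#'
#' Reads KEGG Markup Language (the XML format KEGG uses to distribute
#' pathway topologies) into a gene-level [pathway_graph()]:
#'
#' * `gene` entries are expanded to the individual gene symbols listed in
#'   their `graphics/@name` label (KEGG lists them comma-separated, the
#'   first being the canonical symbol for display);
#' * `group` (complex) entries are expanded so that every member gene
#'   inherits all edges of the group;
#' * relations that pass through entries carrying no genes (compounds,
#'   linked maps) are collapsed to direct gene-to-gene edges;
#' * relation subtypes `activation`/`expression` and
#'   `inhibition`/`repression` become the edge relation label, anything
#'   else `"unknown"`.
#'
#' Entries that resolve to no gene symbol are listed in the graph's
#' `skipped_entries` report rather than aborting the parse. Cycles are
#' preserved; call [break_cycles()] before network fitting.
#'
#' @param kgml path to a KGML file or a single string of KGML text.
#' @param pathway_id optional id; defaults to the document's
#'   `pathway/@name`.
#' @return A [pathway_graph()].
#' @export
parse_kgml <- function(kgml, pathway_id = NULL) {
  doc <- tryCatch({
    if (length(kgml) == 1L && !grepl("<", kgml, fixed = TRUE) &&
        file.exists(kgml)) xml2::read_xml(kgml) else xml2::read_xml(kgml)
  }, error = function(e)
    stop(sprintf("malformed KGML document: %s", conditionMessage(e)),
         call. = FALSE))
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing"))
    stop("malformed KGML document: missing <pathway> root element")
  if (is.null(pathway_id)) {
    pathway_id <- xml2::xml_attr(root, "name")
    if (is.na(pathway_id)) pathway_id <- "pathway"
  }

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  genes_of <- stats::setNames(vector("list", length(ids)), ids)
  skipped <- data.frame(entry_id = character(), type = character(),
                        reason = character(), stringsAsFactors = FALSE)

  label_genes <- function(entry) {
    gname <- xml2::xml_attr(xml2::xml_find_first(entry, "graphics"), "name")
    if (is.na(gname) || !nzchar(gname)) return(character(0))
    syms <- trimws(unlist(strsplit(gname, ",", fixed = TRUE)))
    syms <- sub("\\.\\.\\.$", "", syms)
    syms[nzchar(syms)]
  }

  for (k in seq_along(ids)) {
    if (identical(types[k], "gene")) {
      gs <- label_genes(entries[[k]])
      if (length(gs) == 0)
        skipped <- rbind(skipped, data.frame(
          entry_id = ids[k], type = types[k],
          reason = "no resolvable gene symbol", stringsAsFactors = FALSE))
      genes_of[[k]] <- unique(gs)
    } else {
      genes_of[[k]] <- character(0)
    }
  }
  # groups/complexes: members inherit the group's edges
  for (k in seq_along(ids)) {
    if (identical(types[k], "group")) {
      comp <- xml2::xml_attr(
        xml2::xml_find_all(entries[[k]], "component"), "id")
      genes_of[[k]] <- unique(unlist(genes_of[comp]))
      if (length(genes_of[[k]]) == 0)
        skipped <- rbind(skipped, data.frame(
          entry_id = ids[k], type = types[k],
          reason = "group with no gene members", stringsAsFactors = FALSE))
    }
  }

  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  e1 <- xml2::xml_attr(rels, "entry1")
  e2 <- xml2::xml_attr(rels, "entry2")
  lab <- vapply(rels, function(r) {
    sub <- xml2::xml_attr(xml2::xml_find_all(r, "subtype"), "name")
    if (any(sub %in% c("activation", "expression"))) "activation"
    else if (any(sub %in% c("inhibition", "repression"))) "inhibition"
    else "unknown"
  }, character(1))

  eedges <- data.frame(from = e1, to = e2, relation = lab,
                       stringsAsFactors = FALSE)
  eedges <- eedges[eedges$from %in% ids & eedges$to %in% ids, , drop = FALSE]

  # collapse relations routed through gene-less connector entries
  # (compounds, maps): predecessors connect directly to successors
  has_genes <- vapply(genes_of, length, integer(1)) > 0
  repeat {
    conn <- ids[!has_genes[ids]]
    conn <- conn[conn %in% c(eedges$from, eedges$to)]
    if (length(conn) == 0) break
    c1 <- conn[1L]
    ins <- eedges[eedges$to == c1 & eedges$from != c1, , drop = FALSE]
    outs <- eedges[eedges$from == c1 & eedges$to != c1, , drop = FALSE]
    spliced <- NULL
    if (nrow(ins) > 0 && nrow(outs) > 0)
      spliced <- expand.grid(i = seq_len(nrow(ins)), o = seq_len(nrow(outs)))
    eedges <- eedges[eedges$from != c1 & eedges$to != c1, , drop = FALSE]
    if (!is.null(spliced))
      eedges <- rbind(eedges, data.frame(
        from = ins$from[spliced$i], to = outs$to[spliced$o],
        relation = "unknown", stringsAsFactors = FALSE))
    ids <- setdiff(ids, c1)
  }

  # expand entry pairs to all member-gene pairs
  gp <- character(0); gc <- character(0); gr <- character(0)
  for (k in seq_len(nrow(eedges))) {
    from_g <- genes_of[[eedges$from[k]]]
    to_g <- genes_of[[eedges$to[k]]]
    if (length(from_g) == 0 || length(to_g) == 0) next
    grid <- expand.grid(p = from_g, c = to_g, stringsAsFactors = FALSE)
    gp <- c(gp, grid$p); gc <- c(gc, grid$c)
    gr <- c(gr, rep(eedges$relation[k], nrow(grid)))
  }

  pathway_graph(pathway_id,
                nodes = unique(unlist(genes_of)),
                edges = data.frame(parent = gp, child = gc, relation = gr,
                                   stringsAsFactors = FALSE),
                skipped_entries = skipped)
}
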