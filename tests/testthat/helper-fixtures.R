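# shared fixture builders; everything is generated in code

param_key <- function(d) {
  paste(d$type, d$child, ifelse(is.na(d$parent), "", d$parent))
}

# minimal KGML document builder: entries is a list of
# list(id, type, genes (graphics label), components); relations a list of
# list(entry1, entry2, subtype)
make_kgml <- function(entries, relations = list()) {
  ent <- vapply(entries, function(e) {
    comp <- if (!is.null(e$components))
      paste(sprintf('<component id="%s"/>', e$components), collapse = "")
    else ""
    gfx <- if (!is.null(e$genes))
      sprintf('<graphics name="%s" type="rectangle"/>', e$genes) else ""
    sprintf('<entry id="%s" name="%s" type="%s">%s%s</entry>',
            e$id, if (is.null(e$name)) paste0("hsa:", e$id) else e$name,
            e$type, gfx, comp)
  }, character(1))
  rel <- vapply(relations, function(r) {
    sub <- if (!is.null(r$subtype))
      sprintf('<subtype name="%s" value="--"/>', r$subtype) else ""
    sprintf('<relation entry1="%s" entry2="%s" type="PPrel">%s</relation>',
            r$entry1, r$entry2, sub)
  }, character(1))
  paste0('<?xml version="1.0"?><pathway name="path:test" org="hsa" number="1">',
         paste(ent, collapse = ""), paste(rel, collapse = ""), "</pathway>")
}

# expression_dataset with explicit matrix values
make_dataset <- function(dataset_id, platform_id, mat, groups) {
  expression_dataset(
    dataset_id, platform_id, mat,
    data.frame(sample_id = colnames(mat), group = groups,
               stringsAsFactors = FALSE))
}

# merged_platform built directly (bypasses merge_platform validation),
# used to probe combat_adjust error paths
make_merged <- function(mat, groups, batches, platform_id = "P") {
  structure(list(platform_id = platform_id, matrix = mat,
                 sample_meta = data.frame(sample_id = colnames(mat),
                                          group = groups,
                                          dataset_id = batches,
                                          stringsAsFactors = FALSE),
                 lost_gene_report = data.frame()),
            class = "merged_platform")
}

# the perturbation layout used by the recovery experiments: five node and
# five edge parameters with disjoint child genes; the CD86 -> CD28 edge
# carries the strong (5-SE) effect, everything else 3 SE
recovery_ground_truth <- function(n_per_group = 80) {
  gt <- default_ground_truth()
  perturb_ground_truth(
    gt,
    nodes = c("C1QA", "C1S", "C2", "C5", "SYK"),
    edges = data.frame(parent = c("C1QB", "C1S", "C2", "C3", "CD86"),
                       child = c("C1R", "C4A", "C3", "FCGR1A", "CD28"),
                       stringsAsFactors = FALSE),
    effect = c(rep(3, 9), 5), n_per_group = n_per_group)
}
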