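#' Run the full differential-network analysis in memory
#'
#' Executes the whole workflow on a set of expression datasets: per
#' dataset quantile normalization, per platform intersection merge and
#' ComBat batch adjustment, per platform and group Bayesian-network
#' parameter estimation on the (acyclicized) pathway, case-vs-control
#' Welch contrasts under per-(pathway, platform) BH-FDR control, and the
#' subject-count-weighted mixture merge into standardized final
#' parameters.
#'
#' @param study either a [generate_study()] bundle or a named list of
#'   [expression_dataset()] objects (then `pathway` and `manifest` are
#'   required).
#' @param pathway a [pathway_graph()]; cycles are broken automatically.
#' @param manifest a [load_manifest()] result or a data.frame acceptable
#'   to it; defaults to the synthetic study's own layout.
#' @param alpha FDR threshold per platform (default 0.05).
#' @param adjust_batch run [combat_adjust()] on platforms with more than
#'   one dataset (default TRUE).
#' @param preserve_group passed to [combat_adjust()].
#' @param quantile_norm quantile-normalize each dataset first (default
#'   TRUE).
#' @return Object of class `pipeline_result`: `contrasts` (all
#'   platforms, row-bound), `per_platform` (list with `merged`,
#'   `qc_before`, `qc_after`, `fit_case`, `fit_control`, `contrasts`),
#'   `finals`, `ranking`, `counts`, `weights`, `pathway` (post cycle
#'   breaking), `alpha`, `log` (character vector of stage records).
#' @export
run_study <- function(study, pathway = NULL, manifest = NULL, alpha = 0.05,
                      adjust_batch = TRUE, preserve_group = TRUE,
                      quantile_norm = TRUE) {
  if (inherits(study, "synthetic_study")) {
    datasets <- study$datasets
    if (is.null(pathway)) pathway <- study$pathway
    if (is.null(manifest)) manifest <- study$manifest
  } else {
    datasets <- study
  }
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "expression_dataset")),
            inherits(pathway, "pathway_graph"))
  if (!inherits(manifest, "study_manifest")) manifest <- load_manifest(manifest)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  g <- break_cycles(pathway)
  if (nrow(g$removed_edges))
    note("pathway %s: removed %d cycle edge(s)", g$pathway_id,
         nrow(g$removed_edges))

  platforms <- split(datasets,
                     vapply(datasets, `[[`, character(1), "platform_id"))
  per_platform <- list()
  contrasts <- list()
  for (pl in sort(names(platforms))) {
    dl <- platforms[[pl]]
    if (quantile_norm) dl <- lapply(dl, quantile_normalize)
    merged <- merge_platform(dl)
    qc_before <- qc_summary(merged)
    note("platform %s: merged %d dataset(s), %d genes x %d samples",
         pl, length(dl), nrow(merged$matrix), ncol(merged$matrix))
    for (i in seq_len(nrow(merged$lost_gene_report)))
      note("platform %s: dataset %s lost %.1f%% of genes to the intersection",
           pl, merged$lost_gene_report$dataset_id[i],
           100 * merged$lost_gene_report$lost_fraction[i])
    qc_after <- NULL
    if (adjust_batch && length(dl) > 1L) {
      merged <- combat_adjust(merged, preserve_group = preserve_group)
      qc_after <- qc_summary(merged)
      note("platform %s: ComBat batch adjustment (group covariate: %s); PC1~batch R2 %.3f -> %.3f",
           pl, preserve_group, qc_before$pc1_batch_r2, qc_after$pc1_batch_r2)
    }
    fit_case <- fit_network(g, merged, "case")
    fit_control <- fit_network(g, merged, "control")
    for (fn in list(fit_case, fit_control)) {
      for (i in seq_len(nrow(fn$skipped)))
        note("platform %s (%s): skipped gene %s (%s)", pl, fn$group,
             fn$skipped$gene[i], fn$skipped$reason[i])
      dropped <- unlist(lapply(fn$node_models, `[[`, "dropped_parents"))
      if (length(dropped))
        note("platform %s (%s): dropped collinear parent(s): %s", pl,
             fn$group, paste(dropped, collapse = ", "))
    }
    ct <- contrast_networks(fit_case, fit_control, alpha = alpha)
    note("platform %s: %d testable parameters, %d significant at FDR < %g",
         pl, nrow(ct), sum(ct$significant), alpha)
    per_platform[[pl]] <- list(merged = merged, qc_before = qc_before,
                               qc_after = qc_after, fit_case = fit_case,
                               fit_control = fit_control, contrasts = ct)
    contrasts[[pl]] <- ct
  }
  all_ct <- rbind_rows(lapply(contrasts, as.data.frame))

  w <- manifest_weights(manifest)
  missing_pl <- setdiff(names(platforms), names(w$p))
  if (length(missing_pl))
    stop("platform(s) absent from manifest: ", paste(missing_pl, collapse = ", "))
  note("mixture weights: %s",
       paste(sprintf("%s=%.5f", names(w$p), w$p), collapse = ", "))
  finals <- merge_contrasts(all_ct, w)
  note("%d final parameter(s) significant on >= 1 platform", nrow(finals))
  structure(list(contrasts = all_ct, per_platform = per_platform,
                 finals = finals, ranking = rank_parameters(finals),
                 counts = significant_counts(all_ct, alpha),
                 weights = w, pathway = g, alpha = alpha, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d platform(s), %d testable parameters, %d final parameter(s)\n",
              length(x$per_platform), nrow(x$contrasts), nrow(x$finals)))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits `contrasts.tsv` (per-platform tests), `final_parameters.tsv`,
#' `significant_counts.tsv`, `extremes.tsv`, a GraphML per pathway with
#' node/edge `mu_star` attributes, `removed_edges.tsv`, `run_log.txt`
#' and `run_metadata.json` (weights, alpha, session counts).
#'
#' @param result a [run_study()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) utils::write.table(
    as.data.frame(d), file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wr(result$contrasts, "contrasts.tsv")
  wr(result$finals, "final_parameters.tsv")
  wr(result$counts, "significant_counts.tsv")
  wr(result$ranking$extremes, "extremes.tsv")
  wr(result$pathway$removed_edges, "removed_edges.tsv")
  export_graphml(result$finals, result$pathway,
                 file.path(out_dir, paste0(
                   gsub("[^A-Za-z0-9._-]", "_", result$pathway$pathway_id),
                   ".graphml")))
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(
    list(alpha = result$alpha,
         weights = as.list(result$weights$p),
         platform_n = as.list(result$weights$N),
         n_testable = nrow(result$contrasts),
         n_final = nrow(result$finals)),
    file.path(out_dir, "run_metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the pipeline from a configuration file
#'
#' File-based front end to [run_study()]. The YAML config names the
#' inputs and options:
#' ```yaml
#' pathway: pathway.sif        # or a KGML .xml file
#' data_dir: study/            # <dataset>_expression.tsv + sample_meta.tsv
#' manifest: manifest.yaml
#' alpha: 0.05
#' adjust_batch: true
#' preserve_group: true
#' ```
#' `sample_meta.tsv` must have columns `sample_id`, `group`,
#' `dataset_id`, `platform_id`. Relative paths are resolved against the
#' config file's directory. Real expression studies plug in here: export
#' each series as a gene-by-sample TSV (collapsing probes with
#' [collapse_probes()] first) and describe it in the metadata and
#' manifest.
#'
#' @param config path to a YAML config file or an equivalent list.
#' @param out_dir directory for [write_pipeline_outputs()]; `NULL` skips
#'   writing.
#' @return The [run_study()] result, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  for (f in c("pathway", "data_dir", "manifest"))
    if (is.null(config[[f]])) stop("config is missing '", f, "'")

  pw_path <- rel(config$pathway)
  pathway <- if (grepl("\\.(xml|kgml)$", pw_path, ignore.case = TRUE))
    parse_kgml(pw_path) else parse_sif(pw_path)

  meta <- utils::read.delim(file.path(rel(config$data_dir),
                                      "sample_meta.tsv"),
                            stringsAsFactors = FALSE)
  datasets <- list()
  for (id in unique(meta$dataset_id)) {
    sm <- meta[meta$dataset_id == id, , drop = FALSE]
    m <- read_expression_tsv(file.path(rel(config$data_dir),
                                       paste0(id, "_expression.tsv")))
    datasets[[id]] <- expression_dataset(
      id, sm$platform_id[1L], m[, sm$sample_id, drop = FALSE],
      sm[, c("sample_id", "group")])
  }
  manifest <- load_manifest(rel(config$manifest))
  res <- run_study(datasets, pathway = pathway, manifest = manifest,
                   alpha = if (is.null(config$alpha)) 0.05 else config$alpha,
                   adjust_batch = !isFALSE(config$adjust_batch),
                   preserve_group = !isFALSE(config$preserve_group))
  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, out_dir)
    return(invisible(res))
  }
  res
}
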