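#' Construct an expression dataset
#'
#' One study dataset (e.g. a GEO series): a genes-by-samples matrix of
#' log-scale intensities with per-sample group labels. Values are assumed
#' to be on a log2-like scale already; no re-logging is performed.
#'
#' @param dataset_id single string (e.g. a GEO accession).
#' @param platform_id single string naming the array platform.
#' @param matrix numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_meta `data.frame` with columns `sample_id` and `group`
#'   (`"case"` or `"control"`), one row per column of `matrix`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, platform_id, matrix, sample_meta) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L,
            is.character(platform_id), length(platform_id) == 1L,
            is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene ids in dataset ", dataset_id)
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample ids in dataset ", dataset_id)
  if (nrow(matrix) < 1L || ncol(matrix) < 2L)
    stop("dataset ", dataset_id, " needs >=1 gene and >=2 samples")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sample_meta)))
    stop("`sample_meta` must have columns sample_id and group")
  if (!setequal(sample_meta$sample_id, colnames(matrix)) ||
      anyDuplicated(sample_meta$sample_id))
    stop("sample_meta$sample_id must match matrix columns exactly")
  if (!all(sample_meta$group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  sample_meta <- sample_meta[match(colnames(matrix), sample_meta$sample_id),
                             c("sample_id", "group"), drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(dataset_id = dataset_id, platform_id = platform_id,
                 matrix = matrix, sample_meta = sample_meta),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s' (%s): %d genes x %d samples (%d case / %d control)\n",
              x$dataset_id, x$platform_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$sample_meta$group == "case"),
              sum(x$sample_meta$group == "control")))
  invisible(x)
}

#' Read an expression matrix TSV
#'
#' Expected layout: first column `gene_id`, remaining columns one per
#' sample, values log2 intensities.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1L] != "gene_id")
    stop("first column of ", path, " must be 'gene_id'")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix TSV
#'
#' @param matrix genes-by-samples numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  d <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene level
#'
#' Arrays measure several probes per gene; downstream modeling needs one
#' row per gene. For each gene the probe with the highest mean intensity
#' is kept (ties broken by probe id), a common summarization that favors
#' the best-hybridizing probe.
#'
#' @param matrix probes-by-samples matrix, rownames = probe ids.
#' @param probe_map `data.frame` with columns `probe_id`, `gene_id`.
#'   Probes absent from the map are dropped.
#' @return Gene-level matrix, plus attribute `"collapsed_probes"` naming
#'   the probe chosen for each gene.
#' @export
collapse_probes <- function(matrix, probe_map) {
  probe_map <- probe_map[probe_map$probe_id %in% rownames(matrix), , drop = FALSE]
  if (nrow(probe_map) == 0) stop("no probes in `probe_map` match the matrix")
  means <- rowMeans(matrix)[probe_map$probe_id]
  ord <- order(probe_map$gene_id, -means, probe_map$probe_id)
  pm <- probe_map[ord, , drop = FALSE]
  keep <- pm[!duplicated(pm$gene_id), , drop = FALSE]
  out <- matrix[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  attr(out, "collapsed_probes") <- stats::setNames(keep$probe_id, keep$gene_id)
  out
}
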