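#' Quantile-normalize one dataset
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of the sorted columns. Ties within a column
#' receive the mean of the reference values at the tied ranks. This is
#' the standard within-dataset normalization step before cross-platform
#' merging; it is delegated to `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param d an [expression_dataset()].
#' @return The dataset with its matrix quantile-normalized; labels and
#'   metadata unchanged.
#' @export
quantile_normalize <- function(d) {
  stopifnot(inherits(d, "expression_dataset"))
  bad <- which(!is.finite(d$matrix), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite expression values, e.g. gene %s sample %s",
                 rownames(d$matrix)[bad[1L, 1L]],
                 colnames(d$matrix)[bad[1L, 2L]]))
  m <- limma::normalizeQuantiles(d$matrix, ties = TRUE)
  dimnames(m) <- dimnames(d$matrix)
  d$matrix <- m
  d
}

#' Merge same-platform datasets into one matrix
#'
#' Implements the cross-platform-normalization merge: the gene set of the
#' merged matrix is the **intersection** of the member datasets' genes and
#' the columns are the concatenation of all member samples. Each member's
#' fraction of genes lost to the intersection is reported, and every
#' sample keeps its originating `dataset_id`, which becomes the batch
#' label for [combat_adjust()].
#'
#' @param datasets list of [expression_dataset()] objects sharing one
#'   `platform_id`.
#' @return An object of class `merged_platform`: list with `platform_id`,
#'   `matrix`, `sample_meta` (columns `sample_id`, `group`, `dataset_id`)
#'   and `lost_gene_report` (`dataset_id`, `n_genes`, `n_after`,
#'   `lost_fraction`).
#' @export
merge_platform <- function(datasets) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "expression_dataset")))
  platforms <- unique(vapply(datasets, `[[`, character(1), "platform_id"))
  if (length(platforms) != 1L)
    stop("datasets span multiple platforms: ", paste(platforms, collapse = ", "))
  gene_sets <- lapply(datasets, function(d) rownames(d$matrix))
  common <- sort(Reduce(intersect, gene_sets))
  if (length(common) == 0) stop("gene intersection across datasets is empty")

  mats <- lapply(datasets, function(d) d$matrix[common, , drop = FALSE])
  m <- do.call(cbind, mats)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids across datasets of platform ", platforms)
  meta <- do.call(rbind, lapply(datasets, function(d)
    data.frame(sample_id = d$sample_meta$sample_id,
               group = d$sample_meta$group,
               dataset_id = d$dataset_id, stringsAsFactors = FALSE)))
  rownames(meta) <- NULL
  lost <- data.frame(
    dataset_id = vapply(datasets, `[[`, character(1), "dataset_id"),
    n_genes = lengths(gene_sets),
    n_after = length(common),
    lost_fraction = 1 - length(common) / lengths(gene_sets),
    stringsAsFactors = FALSE)
  structure(list(platform_id = platforms, matrix = m, sample_meta = meta,
                 lost_gene_report = lost),
            class = "merged_platform")
}

#' @export
print.merged_platform <- function(x, ...) {
  cat(sprintf("merged_platform '%s': %d genes x %d samples, %d dataset(s)\n",
              x$platform_id, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$sample_meta$dataset_id))))
  invisible(x)
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Removes per-dataset location/scale batch effects from a merged
#' platform matrix with parametric ComBat (`sva::ComBat`): per-gene
#' standardization against a grand model, method-of-moments estimation of
#' normal / inverse-gamma priors for batch effects, iterative
#' empirical-Bayes shrinkage of the per-batch per-gene location and scale,
#' then subtraction/rescaling and back-transformation. The batch variable
#' is `dataset_id`.
#'
#' With `preserve_group = TRUE` (default) the case/control label enters
#' the grand model as a covariate, protecting genuine group differences
#' from being absorbed into batch means; set to `FALSE` to adjust blind
#' to group.
#'
#' Genes with zero overall variance carry no batch information and are
#' passed through unadjusted with a warning. A single-batch input has
#' nothing to adjust and is returned unchanged.
#'
#' @param m a [merge_platform()] result.
#' @param preserve_group logical; include the group covariate.
#' @return The `merged_platform` object with an adjusted matrix.
#' @export
combat_adjust <- function(m, preserve_group = TRUE) {
  stopifnot(inherits(m, "merged_platform"))
  batch <- factor(m$sample_meta$dataset_id)
  if (nlevels(batch) < 2L) {
    message("single batch: nothing to adjust")
    return(m)
  }
  sizes <- table(batch)
  if (any(sizes < 2L))
    stop("batch(es) with a single sample: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "),
         "; merge or exclude them before adjustment")
  v <- apply(m$matrix, 1L, stats::var)
  flat <- v <= 0 | !is.finite(v)
  if (any(flat))
    warning(sprintf("%d zero-variance gene(s) passed through unadjusted: %s",
                    sum(flat), paste(utils::head(rownames(m$matrix)[flat], 5L),
                                     collapse = ", ")))
  if (all(flat)) return(m)
  mod <- if (preserve_group)
    stats::model.matrix(~ factor(m$sample_meta$group)) else NULL
  dat <- m$matrix[!flat, , drop = FALSE]
  adj <- NULL
  utils::capture.output(suppressMessages(
    adj <- sva::ComBat(dat = dat, batch = batch, mod = mod,
                       par.prior = TRUE, prior.plots = FALSE)))
  out <- m$matrix
  out[!flat, ] <- adj
  m$matrix <- out
  m
}

#' Numeric quality-control summary of a merged platform
#'
#' The graphical checks usually made with boxplots and PCA plots, as
#' numbers: per-sample quartiles of expression, the top-two principal
#' component coordinates of the samples, the variance fractions they
#' explain, and the R-squared of PC1 regressed on the batch label. A
#' large `pc1_batch_r2` before adjustment that collapses after
#' [combat_adjust()] is the numeric signature of successful batch
#' removal.
#'
#' @param m a [merge_platform()] result.
#' @return List of class `platform_qc`: `sample_quartiles` (samples x 5),
#'   `pc_coords` (samples x 2), `pc_var_explained` (length 2),
#'   `pc1_batch_r2`, `degenerate` (TRUE when the matrix has no variance,
#'   in which case the PCA fields are NA).
#' @export
qc_summary <- function(m) {
  stopifnot(inherits(m, "merged_platform"))
  q <- t(apply(m$matrix, 2L, stats::quantile,
               probs = c(0, 0.25, 0.5, 0.75, 1)))
  total_var <- sum(apply(m$matrix, 1L, stats::var))
  if (!is.finite(total_var) || total_var <= 0) {
    return(structure(list(sample_quartiles = q,
                          pc_coords = NULL,
                          pc_var_explained = c(NA_real_, NA_real_),
                          pc1_batch_r2 = NA_real_, degenerate = TRUE),
                     class = "platform_qc"))
  }
  pc <- stats::prcomp(t(m$matrix), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  batch <- factor(m$sample_meta$dataset_id)
  r2 <- if (nlevels(batch) > 1L)
    summary(stats::lm(coords[, 1L] ~ batch))$r.squared else NA_real_
  structure(list(sample_quartiles = q, pc_coords = coords,
                 pc_var_explained = ve, pc1_batch_r2 = r2,
                 degenerate = FALSE),
            class = "platform_qc")
}

#' @export
print.platform_qc <- function(x, ...) {
  if (x$degenerate) {
    cat("platform_qc: degenerate (constant matrix)\n")
  } else {
    cat(sprintf("platform_qc: PC1 %.1f%%, PC2 %.1f%% of variance; PC1~batch R2 = %s\n",
                100 * x$pc_var_explained[1L],
                100 * ifelse(is.na(x$pc_var_explained[2L]), 0,
                             x$pc_var_explained[2L]),
                format(round(x$pc1_batch_r2, 3))))
  }
  invisible(x)
}
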