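#' Load and validate a study manifest
#'
#' The manifest declares the study layout — one row per dataset with its
#' platform and case/control sample counts — and is the source of the
#' platform subject counts \eqn{N_j} that weight the mixture merge. YAML
#' layout:
#' ```yaml
#' datasets:
#'   - {dataset_id: GSE17755, platform_id: Hitachisoft, n_case: 22, n_control: 55}
#' ```
#'
#' @param manifest path to a YAML file, a YAML string, or a `data.frame`
#'   with columns `dataset_id`, `platform_id`, `n_case`, `n_control`.
#' @return Object of class `study_manifest`: the `datasets` data.frame
#'   plus derived `platform_n` (named subjects per platform),
#'   `total_case`, `total_control`.
#' @export
load_manifest <- function(manifest) {
  if (is.data.frame(manifest)) {
    d <- manifest
  } else {
    y <- if (length(manifest) == 1L && file.exists(manifest))
      yaml::read_yaml(manifest) else yaml::yaml.load(manifest)
    if (is.null(y$datasets)) stop("manifest YAML must have a 'datasets' list")
    d <- do.call(rbind, lapply(y$datasets, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  req <- c("dataset_id", "platform_id", "n_case", "n_control")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("manifest is missing field(s): ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(d))) {
    if (any(is.na(d[i, req])))
      stop("manifest row ", i, " (", d$dataset_id[i], ") has missing values")
    if (d$n_case[i] <= 0 || d$n_control[i] <= 0)
      stop("manifest row ", i, " (", d$dataset_id[i],
           ") has non-positive sample counts")
  }
  if (anyDuplicated(d$dataset_id))
    stop("duplicate dataset_id in manifest: ",
         paste(d$dataset_id[duplicated(d$dataset_id)], collapse = ", "))
  d <- d[, req]
  n_subj <- d$n_case + d$n_control
  platform_n <- vapply(split(n_subj, d$platform_id), sum, numeric(1))
  structure(list(datasets = d,
                 platform_n = platform_n,
                 total_case = sum(d$n_case),
                 total_control = sum(d$n_control)),
            class = "study_manifest")
}

#' @export
print.study_manifest <- function(x, ...) {
  cat(sprintf("study_manifest: %d datasets, %d platforms, %d cases / %d controls\n",
              nrow(x$datasets), length(x$platform_n), x$total_case,
              x$total_control))
  print(x$platform_n)
  invisible(x)
}

#' Mixture weights implied by a manifest
#'
#' @param manifest a [load_manifest()] result.
#' @return A [platform_weights()] built from the per-platform subject
#'   counts.
#' @export
manifest_weights <- function(manifest) {
  stopifnot(inherits(manifest, "study_manifest"))
  platform_weights(manifest$platform_n)
}
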