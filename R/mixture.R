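#' Platform mixing weights from subject counts
#'
#' Each platform contributes to the merged final parameters in proportion
#' to the number of subjects (cases plus controls) it assayed:
#' \deqn{p_j = N_j / \sum_k N_k.}
#'
#' @param N named numeric vector of subjects per platform, all >= 1.
#' @return Object of class `platform_weights`: list with `N` and the
#'   normalized weights `p` (both named by platform).
#' @export
#' @examples
#' platform_weights(c(Affymetrix = 166, Illumina = 95, Hitachisoft = 94))
platform_weights <- function(N) {
  if (is.null(names(N)) || any(!nzchar(names(N))))
    stop("`N` must be named by platform id")
  if (anyDuplicated(names(N))) stop("duplicate platform ids in `N`")
  if (any(!is.finite(N) | N < 1)) stop("subject counts must be >= 1")
  structure(list(N = N, p = N / sum(N)), class = "platform_weights")
}

#' @export
print.platform_weights <- function(x, ...) {
  cat("platform_weights:\n")
  print(round(rbind(N = x$N, p = x$p), 5))
  invisible(x)
}

#' Merge one parameter's per-platform contrasts into a final parameter
#'
#' The per-platform significant differences \eqn{\beta^{*(j)}} are
#' combined as a mixture with weights \eqn{p_j}:
#' \deqn{\mu(\beta_f) = \sum_j p_j \mu(\beta^{*(j)}),}
#' \deqn{Var(\beta_f) = \sum_j p_j (var(\beta^{*(j)}) +
#'   \mu^2(\beta^{*(j)})) - \mu^2(\beta_f).}
#' A platform where the parameter was not significant (or not testable)
#' contributes a zero-mean, zero-variance component; a parameter
#' significant on no platform has no defined final value and is omitted
#' (`NULL` is returned). \eqn{\mu(\beta^{*(j)})} is the contrast point
#' estimate and \eqn{var(\beta^{*(j)})} its squared standard error.
#'
#' @param platform_stats `data.frame` with columns `platform_id`, `mu`,
#'   `var`, `significant`; platforms of `w` absent from it count as
#'   non-significant.
#' @param w a [platform_weights()] covering every platform.
#' @return List with `mu_f`, `var_f`, `mu_star`, `contributing_platforms`,
#'   `degenerate` (TRUE when `var_f` is zero so the standardized score is
#'   infinite), or `NULL` when no platform is significant.
#' @export
merge_parameter <- function(platform_stats, w) {
  stopifnot(inherits(w, "platform_weights"))
  ps <- as.data.frame(platform_stats, stringsAsFactors = FALSE)
  extra <- setdiff(ps$platform_id, names(w$p))
  if (length(extra))
    stop("platform(s) missing from weights: ", paste(extra, collapse = ", "))
  mu <- var <- stats::setNames(numeric(length(w$p)), names(w$p))
  sig <- ps$platform_id[ps$significant]
  if (length(sig) == 0) return(NULL)
  mu[ps$platform_id[ps$significant]] <- ps$mu[ps$significant]
  var[ps$platform_id[ps$significant]] <- ps$var[ps$significant]

  p <- w$p[names(mu)]
  mu_f <- sum(p * mu)
  var_f <- sum(p * (var + mu^2)) - mu_f^2
  # Jensen: the mixture second moment dominates the squared mixture mean
  stopifnot(var_f >= -1e-12)
  var_f <- max(var_f, 0)
  degenerate <- var_f == 0 && mu_f != 0
  mu_star <- if (var_f > 0) mu_f / sqrt(var_f)
  else if (mu_f == 0) 0 else sign(mu_f) * Inf
  list(mu_f = mu_f, var_f = var_f, mu_star = mu_star,
       contributing_platforms = sort(sig), degenerate = degenerate)
}

#' Standardized final-parameter score
#'
#' \eqn{\mu^*(\beta_f) = \mu(\beta_f) / \sqrt{Var(\beta_f)}}: the mixture
#' mean in units of its standard deviation, making parameters with very
#' different variances comparable on one scale.
#'
#' @param mu_f mixture mean.
#' @param var_f mixture variance; must be positive unless `mu_f` is 0.
#' @return The standardized score (0 when `mu_f` is 0).
#' @export
standardized_score <- function(mu_f, var_f) {
  if (mu_f == 0) return(0)
  if (var_f <= 0)
    stop("standardized score undefined: degenerate mixture with zero variance")
  mu_f / sqrt(var_f)
}

#' Sign class of a final parameter
#'
#' A positive score on a node parameter means the gene is upregulated in
#' cases, negative means downregulated; on an edge parameter the sign
#' marks an increased or decreased biological function of the
#' relationship. A zero score is reported as no net change.
#'
#' @param mu_star standardized score.
#' @param type `"node"` or `"edge"`.
#' @return One of `"upregulated"`, `"downregulated"`,
#'   `"increasing function"`, `"decreasing function"`, `"no net change"`.
#' @export
classify_sign <- function(mu_star, type) {
  stopifnot(type %in% c("node", "edge"))
  if (mu_star == 0) return("no net change")
  if (type == "node") {
    if (mu_star > 0) "upregulated" else "downregulated"
  } else {
    if (mu_star > 0) "increasing function" else "decreasing function"
  }
}

#' Merge all platforms' contrasts into final parameters
#'
#' Applies [merge_parameter()] to every parameter that is significant on
#' at least one platform, across the row-bound per-platform contrast
#' tables.
#'
#' @param contrasts a `data.frame` combining [contrast_networks()]
#'   results from all platforms (columns `pathway_id`, `platform_id`,
#'   `type`, `child`, `parent`, `beta_star`, `se_star`, `significant`).
#' @param w a [platform_weights()].
#' @return `data.frame` of class `final_parameters`: `pathway_id`,
#'   `type`, `child`, `parent`, `mu_f`, `var_f`, `mu_star`, `sign_class`,
#'   `platforms` (comma-separated contributing platforms),
#'   `n_platforms`, `degenerate`; sorted by key.
#' @export
merge_contrasts <- function(contrasts, w) {
  stopifnot(inherits(w, "platform_weights"))
  d <- as.data.frame(contrasts, stringsAsFactors = FALSE)
  key <- paste(d$pathway_id, d$type, d$child,
               ifelse(is.na(d$parent), "", d$parent), sep = "\r")
  out <- list()
  for (k in sort(unique(key[d$significant]))) {
    rows <- d[key == k, , drop = FALSE]
    merged <- merge_parameter(
      data.frame(platform_id = rows$platform_id, mu = rows$beta_star,
                 var = rows$se_star^2, significant = rows$significant,
                 stringsAsFactors = FALSE), w)
    if (is.null(merged)) next
    out[[k]] <- data.frame(
      pathway_id = rows$pathway_id[1L], type = rows$type[1L],
      child = rows$child[1L], parent = rows$parent[1L],
      mu_f = merged$mu_f, var_f = merged$var_f, mu_star = merged$mu_star,
      sign_class = classify_sign(merged$mu_star, rows$type[1L]),
      platforms = paste(merged$contributing_platforms, collapse = ","),
      n_platforms = length(merged$contributing_platforms),
      degenerate = merged$degenerate, stringsAsFactors = FALSE)
  }
  res <- rbind_rows(out)
  if (is.null(res))
    res <- data.frame(pathway_id = character(), type = character(),
                      child = character(), parent = character(),
                      mu_f = numeric(), var_f = numeric(),
                      mu_star = numeric(), sign_class = character(),
                      platforms = character(), n_platforms = integer(),
                      degenerate = logical(), stringsAsFactors = FALSE)
  class(res) <- c("final_parameters", "data.frame")
  res
}

#' Rank final parameters and summarize their extremes
#'
#' Nodes and edges are ranked separately by the standardized score
#' \eqn{\mu^*(\beta_f)}; ties are broken lexicographically by parameter
#' key so rankings are reproducible. Returns the top-k in each direction
#' (most upregulated / downregulated nodes, most increased / decreased
#' edges) together with a min/max summary per type.
#'
#' @param finals a [merge_contrasts()] result.
#' @param k how many parameters per direction (default 3).
#' @return List with `top`: list of four data.frames (`nodes_up`,
#'   `nodes_down`, `edges_up`, `edges_down`), and `extremes`: one row per
#'   (pathway, type) with `min` and `max` of `mu_star`.
#' @export
rank_parameters <- function(finals, k = 3L) {
  stopifnot(inherits(finals, "data.frame"))
  keyof <- function(d) paste(d$child, ifelse(is.na(d$parent), "", d$parent))
  take <- function(d, decreasing) {
    ord <- order(if (decreasing) -d$mu_star else d$mu_star, keyof(d))
    head(d[ord, , drop = FALSE], k)
  }
  nodes <- finals[finals$type == "node", , drop = FALSE]
  edges <- finals[finals$type == "edge", , drop = FALSE]
  top <- list(nodes_up = take(nodes, TRUE), nodes_down = take(nodes, FALSE),
              edges_up = take(edges, TRUE), edges_down = take(edges, FALSE))
  combos <- unique(finals[, c("pathway_id", "type")])
  combos <- combos[order(combos$pathway_id, combos$type), , drop = FALSE]
  if (nrow(combos)) {
    combos$min <- mapply(function(pw, ty)
      min(finals$mu_star[finals$pathway_id == pw & finals$type == ty]),
      combos$pathway_id, combos$type)
    combos$max <- mapply(function(pw, ty)
      max(finals$mu_star[finals$pathway_id == pw & finals$type == ty]),
      combos$pathway_id, combos$type)
  } else {
    combos$min <- numeric(0); combos$max <- numeric(0)
  }
  rownames(combos) <- NULL
  list(top = top, extremes = combos)
}
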