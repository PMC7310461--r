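#' Fit one gene's node model by ordinary least squares
#'
#' Each gene's expression is modeled as a linear regression on the
#' expression of its pathway parents:
#' \deqn{Y = \beta_0 + \beta_1 X_1 + \dots + \beta_{p-1} X_{p-1} + \varepsilon.}
#' The intercept \eqn{\beta_0} is the gene's *node parameter* (its
#' expression level in the group being fitted) and each parent
#' coefficient is an *edge parameter* quantifying the strength of the
#' parent-child relationship. The coefficient vector is asymptotically
#' \eqn{N(\hat\beta, \sigma^2 (X^T X)^{-1})}, and that covariance (with
#' \eqn{\sigma^2} estimated by RSS / (n - p)) is what downstream testing
#' uses.
#'
#' Parent columns are taken in lexicographic order. Collinear columns are
#' dropped deterministically — scanning in that order, a column that does
#' not increase the design rank is removed — so refits are reproducible;
#' dropped parents are reported in the result.
#'
#' @param y numeric response vector (the child gene's expression).
#' @param X numeric matrix of parent expression, one named column per
#'   parent; `NULL` or zero columns for a root gene.
#' @param child name of the child gene (bookkeeping only).
#' @return Object of class `fitted_node_model`: `child`, `parents` (kept,
#'   lexicographic), `dropped_parents`, `beta0`, `betas` (named per
#'   parent), `coefficients` (intercept first), `sigma2_hat`, `cov_beta`,
#'   `df_resid`, `n`.
#' @export
fit_node_regression <- function(y, X = NULL, child = "y") {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (!all(is.finite(y)) || (length(X) && !all(is.finite(X))))
    stop("non-finite values in regression inputs for gene ", child)
  if (nrow(X) != n) stop("length(y) and nrow(X) differ for gene ", child)

  if (ncol(X) > 0) X <- X[, order(colnames(X)), drop = FALSE]

  # deterministic collinearity handling: scan columns in lexicographic
  # order and keep only those that increase the design rank
  design <- matrix(1, nrow = n, ncol = 1L,
                   dimnames = list(NULL, "(Intercept)"))
  dropped <- character(0)
  for (j in seq_len(ncol(X))) {
    cand <- cbind(design, X[, j, drop = FALSE])
    if (qr(cand)$rank > qr(design)$rank) design <- cand
    else dropped <- c(dropped, colnames(X)[j])
  }
  p <- ncol(design)
  df_resid <- n - p
  if (df_resid < 1L)
    stop(sprintf("gene %s unestimable: n = %d samples for %d coefficients",
                 child, n, p))

  fit <- stats::lm.fit(design, y)
  coefs <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df_resid

  # (X'X)^{-1} from the QR factor, undoing any pivoting
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  xtx_inv_piv <- chol2inv(R)
  piv <- fit$qr$pivot
  xtx_inv <- matrix(0, p, p)
  xtx_inv[piv, piv] <- xtx_inv_piv
  dimnames(xtx_inv) <- list(colnames(design), colnames(design))
  cov_beta <- sigma2 * xtx_inv

  parents <- setdiff(colnames(design), "(Intercept)")
  structure(list(child = child, parents = parents,
                 dropped_parents = dropped,
                 beta0 = unname(coefs["(Intercept)"]),
                 betas = coefs[parents],
                 coefficients = coefs,
                 sigma2_hat = sigma2, cov_beta = cov_beta,
                 df_resid = df_resid, n = n),
            class = "fitted_node_model")
}

#' @export
print.fitted_node_model <- function(x, ...) {
  cat(sprintf("fitted_node_model %s ~ %s (n = %d, df = %d)\n", x$child,
              if (length(x$parents)) paste(x$parents, collapse = " + ")
              else "1", x$n, x$df_resid))
  invisible(x)
}

#' Train the pathway Bayesian network on one group
#'
#' Fits [fit_node_regression()] for every pathway gene present in the
#' expression matrix, using the samples of one group only. Genes are
#' visited in topological order (ties lexicographic). A pathway parent
#' absent from the matrix is excluded from that child's design and
#' recorded; a gene that is itself absent, or whose sample count leaves
#' no residual degrees of freedom, is skipped with a reason. This is why
#' different platforms generally yield parameter sets of different sizes:
#' estimability depends on each platform's gene coverage.
#'
#' @param g an acyclic [pathway_graph()].
#' @param m a [merge_platform()] result (after normalization/adjustment).
#' @param group `"case"` or `"control"`.
#' @return Object of class `fitted_network`: `pathway_id`, `platform_id`,
#'   `group`, `node_models` (named list), `skipped`
#'   (`data.frame(gene, reason)`), `missing_parents`
#'   (`data.frame(child, parent)`).
#' @export
fit_network <- function(g, m, group) {
  stopifnot(inherits(g, "pathway_graph"), inherits(m, "merged_platform"),
            group %in% c("case", "control"))
  keep <- m$sample_meta$group == group
  if (!any(keep))
    stop(sprintf("no '%s' samples on platform %s", group, m$platform_id))
  mat <- m$matrix[, keep, drop = FALSE]

  node_models <- list()
  skipped <- data.frame(gene = character(), reason = character(),
                        stringsAsFactors = FALSE)
  missing_parents <- data.frame(child = character(), parent = character(),
                                stringsAsFactors = FALSE)

  for (gene in topological_order(g)) {
    if (!gene %in% rownames(mat)) {
      skipped <- rbind(skipped, data.frame(gene = gene,
                                           reason = "missing gene"))
      next
    }
    pars <- parents_of(g, gene)
    absent <- setdiff(pars, rownames(mat))
    if (length(absent))
      missing_parents <- rbind(missing_parents,
                               data.frame(child = gene, parent = absent))
    pars <- setdiff(pars, absent)
    X <- if (length(pars)) t(mat[pars, , drop = FALSE]) else NULL
    fitted <- tryCatch(fit_node_regression(mat[gene, ], X, child = gene),
                       error = function(e) e)
    if (inherits(fitted, "error")) {
      skipped <- rbind(skipped, data.frame(gene = gene,
                                           reason = conditionMessage(fitted)))
      next
    }
    node_models[[gene]] <- fitted
  }
  structure(list(pathway_id = g$pathway_id, platform_id = m$platform_id,
                 group = group, node_models = node_models,
                 skipped = skipped, missing_parents = missing_parents),
            class = "fitted_network")
}

#' @export
print.fitted_network <- function(x, ...) {
  cat(sprintf("fitted_network %s / %s / %s: %d node models, %d skipped\n",
              x$pathway_id, x$platform_id, x$group, length(x$node_models),
              nrow(x$skipped)))
  invisible(x)
}

#' Flatten a fitted network into a parameter table
#'
#' One row per parameter: node parameters (intercepts, `parent = NA`) and
#' edge parameters (parent coefficients), with estimate, standard error
#' and residual degrees of freedom.
#'
#' @param fn a [fit_network()] result.
#' @return `data.frame` with columns `pathway_id`, `platform_id`, `group`,
#'   `type` (`"node"`/`"edge"`), `child`, `parent`, `estimate`, `se`,
#'   `df`.
#' @export
parameter_table <- function(fn) {
  stopifnot(inherits(fn, "fitted_network"))
  rows <- lapply(fn$node_models, function(nm) {
    se <- sqrt(diag(nm$cov_beta))
    data.frame(
      pathway_id = fn$pathway_id, platform_id = fn$platform_id,
      group = fn$group,
      type = c("node", rep("edge", length(nm$parents))),
      child = nm$child,
      parent = c(NA_character_, nm$parents),
      estimate = unname(c(nm$beta0, nm$betas)),
      se = unname(c(se["(Intercept)"], se[nm$parents])),
      df = nm$df_resid, stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(pathway_id = character(), platform_id = character(),
                      group = character(), type = character(),
                      child = character(), parent = character(),
                      estimate = numeric(), se = numeric(), df = integer(),
                      stringsAsFactors = FALSE)
  out
}
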