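#' Welch-type contrast of one parameter between groups
#'
#' Each group's network fit yields, for a given parameter, a point
#' estimate with a standard error and residual degrees of freedom. The
#' case-minus-control difference
#' \deqn{\beta^* = \hat\beta_{case} - \hat\beta_{control}}
#' has variance \eqn{se_{case}^2 + se_{control}^2} (the fits are on
#' independent samples), giving a Wald statistic referred to a
#' t distribution with Welch-Satterthwaite degrees of freedom. This is
#' the two-coefficient analogue of an independent two-sample t test.
#'
#' @param case,control lists (or one-row data.frames) with elements
#'   `estimate`, `se`, `df`.
#' @return List with `beta_star`, `se_star`, `t_stat`, `df`, `p_value`.
#' @export
contrast_parameter <- function(case, control) {
  for (side in list(case, control))
    if (!all(is.finite(c(side$estimate, side$se, side$df))))
      stop("contrast requires finite estimate, se and df in both groups")
  se_star <- sqrt(case$se^2 + control$se^2)
  if (se_star <= 0)
    stop("contrast undefined: both standard errors are zero")
  beta_star <- case$estimate - control$estimate
  t_stat <- beta_star / se_star
  df <- se_star^4 / (case$se^4 / case$df + control$se^4 / control$df)
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  list(beta_star = beta_star, se_star = se_star, t_stat = t_stat,
       df = df, p_value = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`p.adjust(method = "BH")`) with input
#' validation; adjusted values are monotone in p-rank and capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Vector of BH-adjusted values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Contrast all shared parameters of two fitted networks
#'
#' Tests every parameter estimable in **both** the case and the control
#' network of one platform; parameters present in only one group are
#' untestable and excluded from the FDR family. Node and edge parameters
#' are adjusted jointly within the (pathway, platform) family.
#'
#' @param case_fn,control_fn [fit_network()] results for the same pathway
#'   and platform, `group = "case"` and `"control"`.
#' @param alpha FDR significance threshold (default 0.05).
#' @return `data.frame` of class `parameter_contrasts` with columns
#'   `pathway_id`, `platform_id`, `type`, `child`, `parent`, `beta_star`,
#'   `se_star`, `t_stat`, `df`, `p_value`, `fdr`, `significant`; the
#'   untestable parameter keys are in `attr(, "untestable")`.
#' @export
contrast_networks <- function(case_fn, control_fn, alpha = 0.05) {
  stopifnot(inherits(case_fn, "fitted_network"),
            inherits(control_fn, "fitted_network"),
            case_fn$group == "case", control_fn$group == "control",
            case_fn$pathway_id == control_fn$pathway_id,
            case_fn$platform_id == control_fn$platform_id)
  tc <- parameter_table(case_fn)
  th <- parameter_table(control_fn)
  key <- function(d) paste(d$type, d$child, ifelse(is.na(d$parent), "", d$parent),
                           sep = "\r")
  kc <- key(tc); kh <- key(th)
  shared <- intersect(kc, kh)
  untestable <- setdiff(union(kc, kh), shared)
  tc <- tc[match(shared, kc), , drop = FALSE]
  th <- th[match(shared, kh), , drop = FALSE]

  res <- tc[, c("pathway_id", "platform_id", "type", "child", "parent")]
  n <- nrow(res)
  res$beta_star <- res$se_star <- res$t_stat <- res$df <- res$p_value <-
    rep(NA_real_, n)
  for (i in seq_len(n)) {
    ct <- contrast_parameter(
      list(estimate = tc$estimate[i], se = tc$se[i], df = tc$df[i]),
      list(estimate = th$estimate[i], se = th$se[i], df = th$df[i]))
    res$beta_star[i] <- ct$beta_star
    res$se_star[i] <- ct$se_star
    res$t_stat[i] <- ct$t_stat
    res$df[i] <- ct$df
    res$p_value[i] <- ct$p_value
  }
  res$fdr <- bh_fdr(res$p_value)
  res$significant <- res$fdr < alpha
  res <- res[order(res$type, res$child,
                   ifelse(is.na(res$parent), "", res$parent)), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "untestable") <- sort(gsub("\r", "|", untestable, fixed = TRUE))
  attr(res, "alpha") <- alpha
  class(res) <- c("parameter_contrasts", "data.frame")
  res
}

#' Filter contrasts to the significant set
#'
#' @param contrasts a [contrast_networks()] result (or any data.frame
#'   with an `fdr` column).
#' @param alpha FDR threshold.
#' @return The rows with `fdr < alpha`, with `significant` recomputed.
#' @export
significant_set <- function(contrasts, alpha = 0.05) {
  stopifnot("fdr" %in% names(contrasts))
  out <- contrasts[contrasts$fdr < alpha, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Count significant parameters by pathway, platform and type
#'
#' Produces the standard reporting layout: for each pathway and platform,
#' how many node and how many edge parameters pass the FDR threshold.
#'
#' @param contrasts one or more [contrast_networks()] results
#'   (row-bound).
#' @param alpha FDR threshold.
#' @return `data.frame` with columns `pathway_id`, `platform_id`,
#'   `nodes`, `edges`.
#' @export
significant_counts <- function(contrasts, alpha = 0.05) {
  sig <- significant_set(contrasts, alpha)
  combos <- unique(contrasts[, c("pathway_id", "platform_id")])
  combos <- combos[order(combos$pathway_id, combos$platform_id), , drop = FALSE]
  combos$nodes <- mapply(function(pw, pl)
    sum(sig$pathway_id == pw & sig$platform_id == pl & sig$type == "node"),
    combos$pathway_id, combos$platform_id)
  combos$edges <- mapply(function(pw, pl)
    sum(sig$pathway_id == pw & sig$platform_id == pl & sig$type == "edge"),
    combos$pathway_id, combos$platform_id)
  rownames(combos) <- NULL
  combos
}
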