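#' A small complement/costimulation pathway for simulation and examples
#'
#' A 12-gene acyclic network shaped like the classical complement cascade
#' plus a costimulation arm: C1q subunits trigger the C1r/C1s proteases,
#' which activate C2 and C4, converging on C3 and C5, with an Fc-receptor
#' / SYK / CD28 branch. It is the default structure for the synthetic
#' study generator; sizes (12 genes, 13 edges, in-degree up to 2) are
#' chosen so a full multi-platform study simulates and fits in seconds.
#'
#' @return A [pathway_graph()] with 12 genes and 13 edges.
#' @export
example_pathway <- function() {
  edges <- data.frame(
    parent = c("C1QA", "C1QB", "C1R", "C1S", "C1S", "C1QB", "C2", "C4A",
               "C3", "C3", "CD86", "FCGR1A", "CD28"),
    child  = c("C1R", "C1R", "C1S", "C2", "C4A", "C2", "C3", "C3",
               "C5", "FCGR1A", "CD28", "SYK", "SYK"),
    relation = "activation", stringsAsFactors = FALSE)
  pathway_graph("toy:complement", edges = edges)
}

#' Ground truth for a linear-Gaussian pathway simulation
#'
#' Fixes, per group, the generative parameters of the structural equation
#' model the network fit assumes: each root gene is
#' \eqn{N(\beta_0, \sigma^2)} and each child is
#' \eqn{\beta_0 + \sum_k \beta_k X_k + N(0, \sigma^2)} over its pathway
#' parents. Parameters whose case value differs from control form the
#' perturbed set, the recovery target for the whole pipeline.
#'
#' @param pathway an acyclic [pathway_graph()].
#' @param node_params `data.frame(gene, control, case)`, one row per
#'   pathway gene (intercepts).
#' @param edge_params `data.frame(parent, child, control, case)`, one row
#'   per pathway edge (coefficients).
#' @param noise_sd named numeric vector, residual standard deviation per
#'   gene; all > 0.
#' @return Object of class `ground_truth` with elements `pathway`,
#'   `node_params`, `edge_params`, `noise_sd`, `perturbed`
#'   (`data.frame(type, child, parent, control, case, direction)`).
#' @export
ground_truth <- function(pathway, node_params, edge_params, noise_sd) {
  stopifnot(inherits(pathway, "pathway_graph"))
  if (!is_acyclic(pathway)) stop("ground truth requires an acyclic pathway")
  node_params <- as.data.frame(node_params, stringsAsFactors = FALSE)
  edge_params <- as.data.frame(edge_params, stringsAsFactors = FALSE)
  if (!setequal(node_params$gene, pathway$nodes))
    stop("node_params must cover every pathway gene exactly once")
  ek <- paste(pathway$edges$parent, pathway$edges$child)
  if (!setequal(paste(edge_params$parent, edge_params$child), ek) ||
      anyDuplicated(paste(edge_params$parent, edge_params$child)))
    stop("edge_params must cover every pathway edge exactly once")
  if (!setequal(names(noise_sd), pathway$nodes) || any(noise_sd <= 0))
    stop("noise_sd must be positive and named for every gene")

  pn <- node_params[node_params$control != node_params$case, , drop = FALSE]
  pe <- edge_params[edge_params$control != edge_params$case, , drop = FALSE]
  perturbed <- rbind(
    if (nrow(pn)) data.frame(type = "node", child = pn$gene,
                             parent = NA_character_, control = pn$control,
                             case = pn$case,
                             direction = sign(pn$case - pn$control)),
    if (nrow(pe)) data.frame(type = "edge", child = pe$child,
                             parent = pe$parent, control = pe$control,
                             case = pe$case,
                             direction = sign(pe$case - pe$control)))
  if (is.null(perturbed))
    perturbed <- data.frame(type = character(), child = character(),
                            parent = character(), control = numeric(),
                            case = numeric(), direction = numeric())
  structure(list(pathway = pathway, node_params = node_params,
                 edge_params = edge_params, noise_sd = noise_sd,
                 perturbed = perturbed),
            class = "ground_truth")
}

#' Default ground truth on a pathway
#'
#' Deterministic, realistic-scale parameters for log2 microarray data.
#' Edge coefficients cycle through moderate positive and negative values
#' (+0.5, -0.4, +0.8, +0.6, -0.7 in sorted edge order) and every gene
#' has residual standard deviation 1. Intercepts are calibrated, in
#' topological order, so that every gene's marginal mean equals
#' `level` (default 8, the middle of a typical log2 intensity range):
#' expression values must stay interior to the array's dynamic range,
#' otherwise rank-based normalization pins a gene at the global
#' minimum/maximum and destroys its variance — something that does not
#' happen to real array genes. Case and control start identical; use
#' [perturb_ground_truth()] to inject group differences.
#'
#' Root genes (upstream regulators with no modeled parents) get residual
#' standard deviation `root_sd` (default 2): their spread absorbs all
#' unmodeled upstream biology, and in subject-level immune expression
#' data the drivers vary considerably more between subjects than the
#' residual noise of a downstream gene given its regulators.
#'
#' @param pathway an acyclic [pathway_graph()]; default
#'   [example_pathway()].
#' @param noise_sd residual standard deviation of non-root genes.
#' @param root_sd marginal standard deviation of root genes.
#' @param level target marginal mean log2 expression for every gene.
#' @return A [ground_truth()].
#' @export
default_ground_truth <- function(pathway = example_pathway(), noise_sd = 1,
                                 root_sd = 2, level = 8) {
  e <- pathway$edges[order(pathway$edges$parent, pathway$edges$child), ,
                     drop = FALSE]
  coefs <- rep(c(0.5, -0.4, 0.8, 0.6, -0.7), length.out = nrow(e))
  edge_params <- data.frame(parent = e$parent, child = e$child,
                            control = coefs, case = coefs,
                            stringsAsFactors = FALSE)
  # intercepts chosen so every marginal mean is `level`:
  # beta0 = level - sum_k beta_k * level
  node_params <- data.frame(gene = pathway$nodes, control = NA_real_,
                            stringsAsFactors = FALSE)
  for (gene in pathway$nodes) {
    b <- edge_params$control[edge_params$child == gene]
    node_params$control[node_params$gene == gene] <- level * (1 - sum(b))
  }
  node_params$case <- node_params$control
  is_root <- vapply(pathway$nodes, function(v)
    length(parents_of(pathway, v)) == 0L, logical(1))
  ground_truth(pathway, node_params, edge_params,
               stats::setNames(ifelse(is_root, root_sd, noise_sd),
                               pathway$nodes))
}

#' Analytic moments of the simulated expression distribution
#'
#' For the linear SEM \eqn{x = \beta_0 + B^T x + \varepsilon} the mean is
#' \eqn{(I - B^T)^{-1}\beta_0} and the covariance
#' \eqn{(I - B^T)^{-1} D (I - B^T)^{-T}} with
#' \eqn{D = diag(\sigma^2)}. Used to size injected effects and as an
#' independent check on the simulator.
#'
#' @param gt a [ground_truth()].
#' @param group `"case"` or `"control"`.
#' @return List with `mean` (named vector) and `cov` (matrix).
#' @export
sem_moments <- function(gt, group = "control") {
  stopifnot(inherits(gt, "ground_truth"), group %in% c("case", "control"))
  genes <- gt$pathway$nodes
  k <- length(genes)
  B <- matrix(0, k, k, dimnames = list(genes, genes))  # B[parent, child]
  ep <- gt$edge_params
  B[cbind(ep$parent, ep$child)] <- ep[[group]]
  b0 <- stats::setNames(gt$node_params[[group]], gt$node_params$gene)[genes]
  A <- solve(diag(k) - t(B))
  mu <- as.vector(A %*% b0)
  D <- diag(gt$noise_sd[genes]^2, k)
  S <- A %*% D %*% t(A)
  dimnames(S) <- list(genes, genes)
  list(mean = stats::setNames(mu, genes), cov = S)
}

#' Approximate contrast standard errors under the ground truth
#'
#' Asymptotic standard error of each case-minus-control parameter
#' contrast for a balanced design with `n_per_group` samples per group on
#' one platform, computed from the control-group SEM moments: for a child
#' with parent set \eqn{P}, \eqn{cov(\hat\beta) \approx \sigma^2 M^{-1}/n}
#' where \eqn{M} is the second-moment matrix of \eqn{(1, X_P)}, and the
#' contrast SE is \eqn{\sqrt 2} times the per-group SE. Used to express
#' injected effect sizes in contrast-SE units.
#'
#' @param gt a [ground_truth()].
#' @param n_per_group samples per group.
#' @return `data.frame(type, child, parent, se_group, se_contrast)`.
#' @export
contrast_se_approx <- function(gt, n_per_group) {
  mom <- sem_moments(gt, "control")
  out <- list()
  for (gene in gt$pathway$nodes) {
    pars <- parents_of(gt$pathway, gene)
    m <- mom$mean[pars]
    S <- mom$cov[pars, pars, drop = FALSE]
    M <- rbind(c(1, m), cbind(m, S + tcrossprod(m)))
    covb <- gt$noise_sd[gene]^2 * solve(M) / n_per_group
    se <- sqrt(diag(covb))
    out[[gene]] <- data.frame(
      type = c("node", rep("edge", length(pars))), child = gene,
      parent = c(NA_character_, pars), se_group = unname(se),
      se_contrast = unname(se) * sqrt(2), stringsAsFactors = FALSE)
  }
  rbind_rows(out)
}

#' Inject group differences into a ground truth
#'
#' Sets the case value of the chosen parameters to
#' `control + direction * effect * se_contrast`, where `se_contrast` is
#' the per-platform contrast standard error from [contrast_se_approx()],
#' so `effect` is interpreted in detection-relevant units (an effect of 3
#' is a 3-SE shift on one platform). Directions alternate +, -, +, ... in
#' the order given unless supplied.
#'
#' @param gt a [ground_truth()] (typically unperturbed).
#' @param nodes character vector of genes whose node parameter shifts.
#' @param edges `data.frame(parent, child)` of edges whose coefficient
#'   shifts.
#' @param effect effect size(s) in contrast-SE units, recycled over
#'   nodes then edges.
#' @param n_per_group per-group platform sample size the SE refers to.
#' @param direction optional +1/-1 vector, recycled likewise.
#' @return The modified [ground_truth()] with an updated perturbed set.
#' @export
perturb_ground_truth <- function(gt, nodes = character(),
                                 edges = NULL, effect = 3,
                                 n_per_group = 80, direction = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.null(edges))
    edges <- data.frame(parent = character(), child = character())
  n_tot <- length(nodes) + nrow(edges)
  if (n_tot == 0) return(gt)
  effect <- rep(effect, length.out = n_tot)
  if (is.null(direction)) direction <- rep(c(1, -1), length.out = n_tot)
  direction <- rep(direction, length.out = n_tot)
  ses <- contrast_se_approx(gt, n_per_group)

  np <- gt$node_params
  i <- 0L
  for (gene in nodes) {
    i <- i + 1L
    se <- ses$se_contrast[ses$type == "node" & ses$child == gene]
    if (length(se) != 1L) stop("unknown gene in `nodes`: ", gene)
    np$case[np$gene == gene] <-
      np$control[np$gene == gene] + direction[i] * effect[i] * se
  }
  ep <- gt$edge_params
  for (k in seq_len(nrow(edges))) {
    i <- i + 1L
    sel <- ses$type == "edge" & ses$child == edges$child[k] &
      ses$parent == edges$parent[k]
    if (sum(sel, na.rm = TRUE) != 1L)
      stop("unknown edge in `edges`: ", edges$parent[k], " -> ",
           edges$child[k])
    se <- ses$se_contrast[which(sel)]
    at <- ep$parent == edges$parent[k] & ep$child == edges$child[k]
    ep$case[at] <- ep$control[at] + direction[i] * effect[i] * se
  }
  ground_truth(gt$pathway, np, ep, gt$noise_sd)
}

#' Simulate expression from the pathway SEM
#'
#' Samples genes in topological order: roots from
#' \eqn{N(\beta_0, \sigma^2)}, children as their linear parent
#' combination plus Gaussian noise, using the group's parameters.
#'
#' @param gt a [ground_truth()].
#' @param group `"case"` or `"control"`.
#' @param n number of samples; must exceed the maximum in-degree + 1 or
#'   the resulting data could not identify the node regressions.
#' @param seed optional integer seed; `NULL` uses the current RNG
#'   stream.
#' @return Numeric genes-by-samples matrix (rownames = genes).
#' @export
simulate_sem <- function(gt, group, n, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"), group %in% c("case", "control"))
  ord <- topological_order(gt$pathway)  # errors on cyclic input
  max_indeg <- max(c(0L, vapply(gt$pathway$nodes, function(v)
    length(parents_of(gt$pathway, v)), integer(1))))
  if (n <= max_indeg + 1L)
    stop(sprintf("n = %d cannot identify regressions with in-degree %d; need n > %d",
                 n, max_indeg, max_indeg + 1L))
  if (!is.null(seed)) set.seed(seed)
  b0 <- stats::setNames(gt$node_params[[group]], gt$node_params$gene)
  ep <- gt$edge_params
  beta <- stats::setNames(ep[[group]], paste(ep$parent, ep$child))
  m <- matrix(NA_real_, nrow = length(ord), ncol = n,
              dimnames = list(ord, NULL))
  for (gene in ord) {
    pars <- parents_of(gt$pathway, gene)
    mean_part <- b0[gene]
    if (length(pars)) {
      w <- beta[paste(pars, gene)]
      mean_part <- mean_part + as.vector(w %*% m[pars, , drop = FALSE])
    }
    m[gene, ] <- mean_part + stats::rnorm(n, 0, gt$noise_sd[gene])
  }
  m[gt$pathway$nodes, , drop = FALSE]
}

#' Describe a multi-platform study layout
#'
#' Fixes the batch structure the generator will emulate: which datasets
#' exist, their platform, their per-group sample sizes, the magnitude of
#' per-dataset location/scale batch effects, and per-platform gene
#' dropout. Per-gene batch shifts are drawn as
#' \eqn{N(shift_d, batch\_shift\_sd^2)} and scales as
#' \eqn{exp(N(0, batch\_scale\_sd^2))} — the location/scale model class
#' that ComBat removes.
#'
#' @param datasets `data.frame(dataset_id, platform_id, n_case,
#'   n_control)`; sample sizes must be >= 2 per group.
#' @param batch_shift named numeric (by dataset_id), systematic additive
#'   shift per dataset; defaults to 0 for all.
#' @param batch_shift_sd standard deviation of per-gene shifts around the
#'   dataset shift (default 1, comparable to the residual noise).
#' @param batch_scale_sd log-scale standard deviation of per-gene
#'   multiplicative effects (default 0.1).
#' @param dropout named list, platform_id -> character vector of genes
#'   absent from that platform.
#' @param n_background number of off-pathway background genes added to
#'   every dataset (default 200). Quantile normalization and ComBat act
#'   on whole-array gene complements; rank-based normalization of a
#'   bare handful of pathway genes would destroy their covariance, so
#'   the simulator surrounds the pathway with independent genes whose
#'   baseline levels spread over `bg_level_range` (log2 units, residual
#'   sd `bg_sd`).
#' @param bg_level_range range of background baseline expression.
#' @param bg_sd residual standard deviation of background genes.
#' @param seed integer seed driving all randomness of the study.
#' @return Object of class `study_design`.
#' @export
study_design <- function(datasets, batch_shift = NULL, batch_shift_sd = 1,
                         batch_scale_sd = 0.1, dropout = list(),
                         n_background = 200L, bg_level_range = c(2, 14),
                         bg_sd = 1, seed = 1L) {
  datasets <- as.data.frame(datasets, stringsAsFactors = FALSE)
  stopifnot(all(c("dataset_id", "platform_id", "n_case", "n_control") %in%
                  names(datasets)))
  if (anyDuplicated(datasets$dataset_id)) stop("duplicate dataset_id")
  if (any(datasets$n_case < 2) || any(datasets$n_control < 2))
    stop("each dataset needs >= 2 samples per group")
  if (is.null(batch_shift))
    batch_shift <- stats::setNames(rep(0, nrow(datasets)),
                                   datasets$dataset_id)
  if (!all(datasets$dataset_id %in% names(batch_shift)))
    stop("batch_shift must name every dataset")
  structure(list(datasets = datasets, batch_shift = batch_shift,
                 batch_shift_sd = batch_shift_sd,
                 batch_scale_sd = batch_scale_sd,
                 dropout = dropout, n_background = as.integer(n_background),
                 bg_level_range = bg_level_range, bg_sd = bg_sd,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Default three-platform, six-dataset study design
#'
#' Mirrors the layout of a multi-platform case-control compendium: three
#' platforms, two datasets each, balanced groups of `n_per_group`
#' samples per platform (split evenly over its two datasets), moderate
#' per-dataset batch effects, and one gene dropped from platform `P2` to
#' exercise the lost-gene accounting.
#'
#' @param n_per_group per-platform samples per group (default 80).
#' @param seed study seed.
#' @param dropout named list of per-platform missing genes; default
#'   drops `"SYK"` from platform `P2`.
#' @return A [study_design()].
#' @export
default_study_design <- function(n_per_group = 80, seed = 1L,
                                 dropout = list(P2 = "SYK")) {
  half <- ceiling(n_per_group / 2)
  datasets <- data.frame(
    dataset_id = paste0("D", 1:6),
    platform_id = rep(c("P1", "P2", "P3"), each = 2),
    n_case = half, n_control = half, stringsAsFactors = FALSE)
  study_design(datasets,
               batch_shift = stats::setNames(rep(c(0, 1.5), 3),
                                             paste0("D", 1:6)),
               dropout = dropout, seed = seed)
}

#' Apply batch effects and gene dropout to simulated datasets
#'
#' Transforms each dataset's values gene-wise as
#' `x -> scale_g * x + shift_g` with the per-gene effects drawn from the
#' design's batch model, then removes each platform's dropout genes.
#' Dropping a pathway gene is allowed (it recreates the lost-gene
#' situation of real cross-platform merges) and is reported via a
#' message.
#'
#' @param blocks named list (by dataset_id) of [expression_dataset()]
#'   objects on the same gene set.
#' @param design a [study_design()] covering every dataset.
#' @return Named list of transformed [expression_dataset()] objects.
#' @export
apply_batch_and_dropout <- function(blocks, design) {
  stopifnot(inherits(design, "study_design"),
            all(names(blocks) %in% design$datasets$dataset_id))
  out <- list()
  for (id in names(blocks)) {
    d <- blocks[[id]]
    genes <- rownames(d$matrix)
    shift <- stats::rnorm(length(genes), design$batch_shift[id],
                          design$batch_shift_sd)
    scale <- exp(stats::rnorm(length(genes), 0, design$batch_scale_sd))
    d$matrix <- d$matrix * scale + shift
    drop_genes <- design$dropout[[d$platform_id]]
    if (length(drop_genes)) {
      present <- intersect(drop_genes, genes)
      if (length(present)) {
        message(sprintf("dropout: removing %s from %s (%s)",
                        paste(present, collapse = ", "), id, d$platform_id))
        d$matrix <- d$matrix[setdiff(genes, present), , drop = FALSE]
      }
    }
    out[[id]] <- d
  }
  out
}

#' Generate a complete synthetic multi-platform study
#'
#' Simulates every dataset of the design from the ground truth (cases
#' and controls from their respective SEM parameters), applies batch
#' effects and dropout, and returns the study bundle together with the
#' truth manifest used to score recovery. All randomness derives from
#' `design$seed`, so identical inputs give identical output (including
#' byte-identical files when `out_dir` is set).
#'
#' Sample ids follow the `<dataset>S.<i>` / `<dataset>H.<i>` convention
#' for cases and controls.
#'
#' @param gt a [ground_truth()].
#' @param design a [study_design()].
#' @param out_dir optional directory; when given, writes one expression
#'   TSV per dataset, `sample_meta.tsv`, `pathway.sif`, `truth.tsv` and
#'   `manifest.yaml`.
#' @return List of class `synthetic_study`: `datasets` (named list of
#'   [expression_dataset()]), `truth` (`data.frame` with one row per
#'   pathway parameter: key, group values, `perturbed`, `direction`),
#'   `manifest` (`data.frame(dataset_id, platform_id, n_case,
#'   n_control)`), `pathway`, `design`.
#' @export
generate_study <- function(gt, design, out_dir = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(design, "study_design"))
  set.seed(design$seed)
  nbg <- design$n_background
  bg_levels <- if (nbg > 0)
    stats::setNames(stats::runif(nbg, design$bg_level_range[1L],
                                 design$bg_level_range[2L]),
                    sprintf("BG%04d", seq_len(nbg))) else numeric(0)
  blocks <- list()
  for (k in seq_len(nrow(design$datasets))) {
    row <- design$datasets[k, ]
    case_m <- simulate_sem(gt, "case", row$n_case)
    ctrl_m <- simulate_sem(gt, "control", row$n_control)
    if (nbg > 0) {
      bg <- function(n) matrix(stats::rnorm(nbg * n, bg_levels, design$bg_sd),
                               nrow = nbg, dimnames = list(names(bg_levels),
                                                           NULL))
      case_m <- rbind(case_m, bg(row$n_case))
      ctrl_m <- rbind(ctrl_m, bg(row$n_control))
    }
    colnames(case_m) <- sprintf("%sS.%d", row$dataset_id,
                                seq_len(row$n_case))
    colnames(ctrl_m) <- sprintf("%sH.%d", row$dataset_id,
                                seq_len(row$n_control))
    m <- cbind(case_m, ctrl_m)
    meta <- data.frame(
      sample_id = colnames(m),
      group = rep(c("case", "control"), c(row$n_case, row$n_control)),
      stringsAsFactors = FALSE)
    blocks[[row$dataset_id]] <-
      expression_dataset(row$dataset_id, row$platform_id, m, meta)
  }
  datasets <- suppressMessages(apply_batch_and_dropout(blocks, design))

  np <- gt$node_params; ep <- gt$edge_params
  truth <- rbind(
    data.frame(pathway_id = gt$pathway$pathway_id, type = "node",
               child = np$gene, parent = NA_character_,
               control = np$control, case = np$case,
               stringsAsFactors = FALSE),
    data.frame(pathway_id = gt$pathway$pathway_id, type = "edge",
               child = ep$child, parent = ep$parent,
               control = ep$control, case = ep$case,
               stringsAsFactors = FALSE))
  truth$perturbed <- truth$case != truth$control
  truth$direction <- sign(truth$case - truth$control)
  truth <- truth[order(truth$type, truth$child,
                       ifelse(is.na(truth$parent), "", truth$parent)), ]
  rownames(truth) <- NULL

  study <- structure(list(datasets = datasets, truth = truth,
                          manifest = design$datasets,
                          pathway = gt$pathway, design = design),
                     class = "synthetic_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d datasets on %d platform(s), %d genes, %d perturbed parameter(s)\n",
              length(x$datasets),
              length(unique(x$manifest$platform_id)),
              length(x$pathway$nodes), sum(x$truth$perturbed)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' @param study a [generate_study()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta_all <- list()
  for (id in names(study$datasets)) {
    d <- study$datasets[[id]]
    write_expression_tsv(round(d$matrix, 6),
                         file.path(out_dir, paste0(id, "_expression.tsv")))
    meta_all[[id]] <- data.frame(sample_id = d$sample_meta$sample_id,
                                 group = d$sample_meta$group,
                                 dataset_id = id,
                                 platform_id = d$platform_id,
                                 stringsAsFactors = FALSE)
  }
  utils::write.table(rbind_rows(meta_all),
                     file.path(out_dir, "sample_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sif(study$pathway, file.path(out_dir, "pathway.sif"))
  utils::write.table(study$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(datasets = lapply(seq_len(nrow(study$manifest)),
                                          function(i) as.list(study$manifest[i, ]))),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
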