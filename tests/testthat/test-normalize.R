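test_that("quantile normalization forces a shared empirical distribution", {
  # columns that are permutations of one another already share their
  # distribution, so QN only reorders values back by gene
  set.seed(1)
  v <- rnorm(6, 8, 1)
  mat <- cbind(s1 = v, s2 = sample(v), s3 = sample(v))
  rownames(mat) <- paste0("g", 1:6)
  d <- make_dataset("d1", "P", mat, rep(c("case", "control"), 3)[1:3])
  out <- quantile_normalize(d)
  expect_equal(out$matrix, mat, tolerance = 1e-12)

  # identical columns are a fixed point
  m2 <- cbind(s1 = v, s2 = v)
  rownames(m2) <- paste0("g", 1:6)
  d2 <- make_dataset("d2", "P", m2, c("case", "control"))
  expect_equal(quantile_normalize(d2)$matrix, m2)
})

test_that("quantile normalization matches a sort-average-restore oracle", {
  set.seed(2)
  mat <- matrix(rnorm(12, 8, 2), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  d <- make_dataset("d", "P", mat, c("case", "case", "control"))
  out <- quantile_normalize(d)$matrix

  ref <- rowMeans(apply(mat, 2, sort))          # mean of sorted columns
  oracle <- apply(mat, 2, function(col) ref[rank(col)])
  dimnames(oracle) <- dimnames(mat)
  expect_equal(out, oracle, tolerance = 1e-10)

  # rank preservation within every column
  for (j in 1:3)
    expect_equal(cor(mat[, j], out[, j], method = "spearman"), 1)
})

test_that("quantile normalization rejects non-finite values", {
  mat <- matrix(c(1, NA, 3, 4), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  d <- make_dataset("d", "P", matrix(1:4 + 0.5, 2, 2,
                                     dimnames = dimnames(mat)),
                    c("case", "control"))
  d$matrix <- mat
  expect_error(quantile_normalize(d), "g2.*s1")
})

test_that("merge_platform intersects genes and reports losses", {
  m1 <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"),
                                               c("s1", "s2")))
  m2 <- matrix(rnorm(6), 3, 2, dimnames = list(c("B", "C", "D"),
                                               c("s3", "s4")))
  d1 <- make_dataset("d1", "P", m1, c("case", "control"))
  d2 <- make_dataset("d2", "P", m2, c("case", "control"))
  mg <- merge_platform(list(d1, d2))
  expect_equal(rownames(mg$matrix), c("B", "C"))
  expect_equal(ncol(mg$matrix), 4L)
  expect_equal(mg$lost_gene_report$lost_fraction, c(1, 1) / 3)

  # identical gene sets lose nothing
  d3 <- make_dataset("d3", "P", m1 + 1, c("case", "control"))
  colnames(d3$matrix) <- c("s5", "s6")
  d3$sample_meta$sample_id <- c("s5", "s6")
  mg2 <- merge_platform(list(d1, d3))
  expect_equal(mg2$lost_gene_report$lost_fraction, c(0, 0))

  # single dataset is an identity merge
  mg3 <- merge_platform(list(d1))
  expect_equal(mg3$matrix, m1[sort(rownames(m1)), ])
  expect_equal(mg3$lost_gene_report$lost_fraction, 0)
})

test_that("merge_platform validates platforms and intersection", {
  m1 <- matrix(rnorm(4), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  m2 <- matrix(rnorm(4), 2, 2, dimnames = list(c("C", "D"), c("s3", "s4")))
  d1 <- make_dataset("d1", "P1", m1, c("case", "control"))
  d2 <- make_dataset("d2", "P2", m2, c("case", "control"))
  expect_error(merge_platform(list(d1, d2)), "multiple platforms")
  d2$platform_id <- "P1"
  expect_error(merge_platform(list(d1, d2)), "empty")
})

test_that("merge_platform is invariant to dataset order and additive in samples", {
  set.seed(4)
  mk <- function(id, genes, samples) {
    m <- matrix(rnorm(length(genes) * length(samples), 8), length(genes),
                dimnames = list(genes, samples))
    make_dataset(id, "P", m, rep(c("case", "control"),
                                 length.out = length(samples)))
  }
  d1 <- mk("d1", c("A", "B", "C", "D"), c("s1", "s2", "s3"))
  d2 <- mk("d2", c("B", "C", "E"), c("s4", "s5"))
  d3 <- mk("d3", c("A", "B", "C"), c("s6", "s7"))
  a <- merge_platform(list(d1, d2, d3))
  b <- merge_platform(list(d3, d1, d2))
  expect_equal(ncol(a$matrix), 7L)
  expect_equal(rownames(a$matrix), rownames(b$matrix))
  expect_equal(a$matrix[, sort(colnames(a$matrix))],
               b$matrix[, sort(colnames(b$matrix))])
})

test_that("combat_adjust removes a known batch shift without touching labels", {
  set.seed(7)
  G <- 50; n <- 200
  mk <- function(id, shift) {
    m <- matrix(rnorm(G * n, 8, 1), G, n,
                dimnames = list(paste0("g", 1:G),
                                paste0(id, "_s", 1:n))) + shift
    make_dataset(id, "P", m, rep(c("case", "control"), each = n / 2))
  }
  mg <- merge_platform(list(mk("b1", 0), mk("b2", 2)))
  adj <- combat_adjust(mg, preserve_group = TRUE)
  expect_equal(dim(adj$matrix), dim(mg$matrix))
  expect_equal(adj$sample_meta, mg$sample_meta)

  b1 <- adj$sample_meta$dataset_id == "b1"
  gap <- rowMeans(adj$matrix[, b1]) - rowMeans(adj$matrix[, !b1])
  pre <- rowMeans(mg$matrix[, b1]) - rowMeans(mg$matrix[, !b1])
  # EB shrinkage leaves a per-gene residue of order the batch-mean SE,
  # so agreement is judged on the typical gene
  expect_lt(mean(abs(gap)), 0.1)
  expect_lt(mean(abs(gap)), 0.1 * mean(abs(pre)))
})

test_that("combat_adjust handles degenerate inputs as documented", {
  set.seed(8)
  mat <- matrix(rnorm(20, 8), 4, 5,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  # single batch: returned unchanged
  m1 <- make_merged(mat, rep(c("case", "control"), length.out = 5),
                    rep("b1", 5))
  expect_message(out <- combat_adjust(m1), "single batch")
  expect_equal(out$matrix, mat)

  # batch with one sample: refuse with advice
  m2 <- make_merged(mat, rep(c("case", "control"), length.out = 5),
                    c("b1", "b1", "b1", "b1", "b2"))
  expect_error(combat_adjust(m2), "single sample")

  # zero-variance gene passes through with a warning
  mat3 <- rbind(mat, flat = rep(5, 5))
  m3 <- make_merged(mat3, rep(c("case", "control"), length.out = 5),
                    c("b1", "b1", "b1", "b2", "b2"))
  expect_warning(out3 <- combat_adjust(m3, preserve_group = FALSE), "flat")
  expect_equal(out3$matrix["flat", ], mat3["flat", ])
})

test_that("combat_adjust matches an independently coded parametric EB oracle", {
  set.seed(3)
  G <- 2; n1 <- 4; n2 <- 5; n <- n1 + n2
  dat <- matrix(rnorm(G * n, 8, 1), G, n,
                dimnames = list(c("g1", "g2"), paste0("s", 1:n)))
  dat[, (n1 + 1):n] <- dat[, (n1 + 1):n] + 1.3
  batch <- rep(c("b1", "b2"), c(n1, n2))
  m <- make_merged(dat, rep(c("case", "control"), length.out = n), batch)
  got <- combat_adjust(m, preserve_group = FALSE)$matrix

  # hand-coded parametric empirical-Bayes location/scale adjustment:
  # standardize per gene against the batch-mean model, method-of-moments
  # normal/inverse-gamma priors, iterate posterior location/scale to
  # convergence, subtract/rescale, back-transform
  nb <- c(n1, n2)
  design <- stats::model.matrix(~ 0 + factor(batch))
  B.hat <- solve(crossprod(design)) %*% t(design) %*% t(dat)
  grand.mean <- crossprod(nb / n, B.hat)
  var.pooled <- ((dat - t(design %*% B.hat))^2) %*% rep(1 / n, n)
  stand.mean <- t(grand.mean) %*% t(rep(1, n))
  s.data <- (dat - stand.mean) / (sqrt(var.pooled) %*% t(rep(1, n)))
  idx <- list(1:n1, (n1 + 1):n)
  gamma.hat <- solve(crossprod(design)) %*% t(design) %*% t(s.data)
  delta.hat <- t(sapply(idx, function(i)
    apply(s.data[, i, drop = FALSE], 1, var)))
  gamma.bar <- rowMeans(gamma.hat)
  t2 <- apply(gamma.hat, 1, var)
  gs <- ds <- matrix(NA, 2, G)
  for (i in 1:2) {
    dvec <- delta.hat[i, ]
    mm <- mean(dvec); s2 <- var(dvec)
    a <- (2 * s2 + mm^2) / s2
    b <- (mm * s2 + mm^3) / s2
    g.old <- gamma.hat[i, ]; d.old <- dvec
    change <- 1
    while (change > 1e-4) {
      g.new <- (t2[i] * nb[i] * gamma.hat[i, ] + d.old * gamma.bar[i]) /
        (t2[i] * nb[i] + d.old)
      sum2 <- rowSums((s.data[, idx[[i]], drop = FALSE] -
                         g.new %*% t(rep(1, nb[i])))^2)
      d.new <- (0.5 * sum2 + b) / (nb[i] / 2 + a - 1)
      change <- max(abs(g.new - g.old) / abs(g.old),
                    abs(d.new - d.old) / abs(d.old))
      g.old <- g.new; d.old <- d.new
    }
    gs[i, ] <- g.old; ds[i, ] <- d.old
  }
  bayes <- s.data
  for (i in 1:2)
    bayes[, idx[[i]]] <- (s.data[, idx[[i]]] - gs[i, ] %*%
                            t(rep(1, nb[i]))) /
      (sqrt(ds[i, ]) %*% t(rep(1, nb[i])))
  oracle <- bayes * (sqrt(var.pooled) %*% t(rep(1, n))) + stand.mean
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("qc_summary quantifies batch structure numerically", {
  set.seed(9)
  G <- 40; n <- 50
  mk <- function(id, shift) {
    m <- matrix(rnorm(G * n, 8, 1), G, n,
                dimnames = list(paste0("g", 1:G),
                                paste0(id, "_s", 1:n))) + shift
    make_dataset(id, "P", m, rep(c("case", "control"), each = n / 2))
  }
  # batch-free data: PC1 is unrelated to batch
  clean <- merge_platform(list(mk("b1", 0), mk("b2", 0)))
  expect_lt(qc_summary(clean)$pc1_batch_r2, 0.1)

  # strong shift dominates PC1 before adjustment, collapses after
  shifted <- merge_platform(list(mk("b1", 0), mk("b2", 3)))
  before <- qc_summary(shifted)
  expect_gt(before$pc1_batch_r2, 0.9)
  after <- qc_summary(combat_adjust(shifted, preserve_group = TRUE))
  expect_lt(after$pc1_batch_r2, before$pc1_batch_r2 / 2)

  # constant matrix is flagged degenerate, quartiles all equal
  const <- make_merged(matrix(5, 3, 4,
                              dimnames = list(paste0("g", 1:3),
                                              paste0("s", 1:4))),
                       rep(c("case", "control"), 2), rep(c("b1", "b2"), 2))
  qc <- qc_summary(const)
  expect_true(qc$degenerate)
  expect_true(all(qc$sample_quartiles == 5))
})
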