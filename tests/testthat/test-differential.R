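test_that("identical estimates give t = 0 and p = 1", {
  ct <- contrast_parameter(list(estimate = 1.2, se = 0.3, df = 20),
                           list(estimate = 1.2, se = 0.4, df = 25))
  expect_equal(ct$t_stat, 0)
  expect_equal(ct$p_value, 1)
  expect_equal(ct$beta_star, 0)
})

test_that("Welch contrast matches hand-evaluated formulas", {
  ct <- contrast_parameter(list(estimate = 1, se = 0.5, df = 40),
                           list(estimate = 0, se = 0.5, df = 40))
  expect_equal(ct$beta_star, 1)
  expect_equal(ct$se_star, sqrt(0.5))
  expect_equal(ct$t_stat, 1 / sqrt(0.5), tolerance = 1e-12)
  # equal variances and df: Welch-Satterthwaite df is df_s + df_h
  expect_equal(ct$df, 80)
  expect_equal(ct$p_value, 2 * pt(-1 / sqrt(0.5), df = 80))
})

test_that("contrast is antisymmetric in the two groups", {
  set.seed(41)
  for (i in 1:20) {
    a <- list(estimate = rnorm(1), se = runif(1, 0.1, 1),
              df = sample(5:50, 1))
    b <- list(estimate = rnorm(1), se = runif(1, 0.1, 1),
              df = sample(5:50, 1))
    f <- contrast_parameter(a, b)
    r <- contrast_parameter(b, a)
    expect_equal(f$beta_star, -r$beta_star)
    expect_equal(f$t_stat, -r$t_stat)
    expect_equal(f$p_value, r$p_value)
    expect_equal(f$df, r$df)
  }
})

test_that("contrasts reject zero joint SE and non-finite inputs", {
  expect_error(contrast_parameter(list(estimate = 1, se = 0, df = 10),
                                  list(estimate = 0, se = 0, df = 10)),
               "zero")
  expect_error(contrast_parameter(list(estimate = NA, se = 1, df = 10),
                                  list(estimate = 0, se = 1, df = 10)),
               "finite")
})

test_that("null contrasts reject at the nominal rate", {
  set.seed(42)
  reps <- 2000
  n <- 40
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    f1 <- fit_node_regression(rnorm(n, 5), child = "g")
    f2 <- fit_node_regression(rnorm(n, 5), child = "g")
    p[r] <- contrast_parameter(
      list(estimate = f1$beta0, se = sqrt(f1$cov_beta[1, 1]),
           df = f1$df_resid),
      list(estimate = f2$beta0, se = sqrt(f2$cov_beta[1, 1]),
           df = f2$df_resid))$p_value
  }
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("BH adjustment matches hand computation and validates input", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  # monotone in p-rank, capped at 1
  set.seed(43)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1 & adj >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significant_set filters by FDR and respects alpha extremes", {
  d <- data.frame(pathway_id = "p", platform_id = "A",
                  type = c("node", "edge"), child = c("X", "Y"),
                  parent = c(NA, "X"), fdr = c(1, 1))
  expect_equal(nrow(significant_set(d, 0.05)), 0L)
  expect_equal(nrow(significant_set(d, alpha = 1.0000001)), 2L)
})

test_that("true contrasts are recovered with BH power as expected", {
  # 10 real effects among 100 parameters, effects in joint-SE units
  run <- function(effect, seeds) {
    se <- 0.2
    recovered <- false_disc <- numeric(seeds)
    for (s in seq_len(seeds)) {
      truth <- c(rep(effect * se * sqrt(2), 10), rep(0, 90))
      est_case <- rnorm(100, truth, se)
      est_ctrl <- rnorm(100, 0, se)
      p <- vapply(1:100, function(i)
        contrast_parameter(list(estimate = est_case[i], se = se, df = 60),
                           list(estimate = est_ctrl[i], se = se,
                                df = 60))$p_value, numeric(1))
      found <- which(bh_fdr(p) < 0.05)
      recovered[s] <- sum(found <= 10)
      false_disc[s] <- sum(found > 10) / max(length(found), 1)
    }
    list(recovered = recovered, fdr = mean(false_disc))
  }
  set.seed(44)
  # moderate (3 SE) effects: a clear majority is recovered on average
  r3 <- run(effect = 3, seeds = 100)
  expect_gte(mean(r3$recovered), 5)
  expect_lte(r3$fdr, 0.07)
  # strong (5 SE) effects: nearly all recovered in nearly every seed
  r5 <- run(effect = 5, seeds = 100)
  expect_gte(mean(r5$recovered >= 8), 0.9)
})

test_that("contrast_networks tests exactly the shared parameter set", {
  g <- parse_sif(c("A\tx\tB", "A\tx\tC", "B\tx\tC"), pathway_id = "p")
  set.seed(45)
  sim <- function(n) {
    a <- rnorm(n, 8)
    b <- 1 + 0.5 * a + rnorm(n)
    cc <- 2 + 0.3 * a - 0.4 * b + rnorm(n)
    m <- rbind(A = a, B = b, C = cc)
    colnames(m) <- paste0("s", seq_len(n))
    m
  }
  # case group too small to estimate C (needs 3 coefficients)
  mat <- cbind(sim(3), sim(40))
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  m <- make_merged(mat, rep(c("case", "control"), c(3, 40)), rep("d", 43))
  fc <- fit_network(g, m, "case")
  fh <- fit_network(g, m, "control")
  ct <- contrast_networks(fc, fh)
  # C unestimable in cases: its node and edge parameters are untestable
  expect_false("C" %in% ct$child)
  expect_true(all(grepl("C", attr(ct, "untestable"))))
  # testable set = intersection of the two groups' parameters
  expect_setequal(param_key(ct),
                  intersect(param_key(parameter_table(fc)),
                            param_key(parameter_table(fh))))
  expect_true(all(ct$fdr >= ct$p_value - 1e-12))
  expect_equal(ct$significant, ct$fdr < 0.05)
})

test_that("significant_counts reports the pathway x platform x type layout", {
  d <- data.frame(pathway_id = "p", platform_id = rep(c("A", "B"), each = 3),
                  type = c("node", "node", "edge"),
                  child = c("X", "Y", "Y"), parent = c(NA, NA, "X"),
                  fdr = c(0.01, 0.2, 0.03, 0.5, 0.01, 0.9))
  counts <- significant_counts(d, 0.05)
  expect_equal(counts$nodes[counts$platform_id == "A"], 1)
  expect_equal(counts$edges[counts$platform_id == "A"], 1)
  expect_equal(counts$nodes[counts$platform_id == "B"], 1)
  expect_equal(counts$edges[counts$platform_id == "B"], 0)
})
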