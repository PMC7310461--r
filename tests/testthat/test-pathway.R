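test_that("minimal KGML with one relation yields one edge", {
  kgml <- make_kgml(
    entries = list(list(id = "1", type = "gene", genes = "A"),
                   list(id = "2", type = "gene", genes = "B")),
    relations = list(list(entry1 = "1", entry2 = "2",
                          subtype = "activation")))
  g <- parse_kgml(kgml)
  expect_s3_class(g, "pathway_graph")
  expect_setequal(g$nodes, c("A", "B"))
  expect_equal(g$edges[, c("parent", "child")],
               data.frame(parent = "A", child = "B"))
  expect_equal(g$edges$relation, "activation")
})

test_that("KGML group entries expand so members inherit edges", {
  kgml <- make_kgml(
    entries = list(list(id = "1", type = "gene", genes = "A"),
                   list(id = "2", type = "gene", genes = "C"),
                   list(id = "3", type = "gene", genes = "D"),
                   list(id = "4", type = "group", components = c("2", "3"))),
    relations = list(list(entry1 = "1", entry2 = "4")))
  g <- parse_kgml(kgml)
  got <- paste(g$edges$parent, g$edges$child)
  expect_setequal(got, c("A C", "A D"))
})

test_that("KGML multi-gene entries and compounds are handled", {
  # entry listing two symbols expands to both; a compound in the middle
  # of a relation chain is collapsed to a direct gene-gene edge
  kgml <- make_kgml(
    entries = list(list(id = "1", type = "gene", genes = "A1, A2"),
                   list(id = "2", type = "compound", name = "cpd:C1"),
                   list(id = "3", type = "gene", genes = "B")),
    relations = list(list(entry1 = "1", entry2 = "2"),
                     list(entry1 = "2", entry2 = "3")))
  g <- parse_kgml(kgml)
  expect_setequal(paste(g$edges$parent, g$edges$child), c("A1 B", "A2 B"))
})

test_that("KGML with no relations yields nodes only; bad entries reported", {
  kgml <- make_kgml(
    entries = list(list(id = "1", type = "gene", genes = "A"),
                   list(id = "2", type = "gene")))   # no symbol
  g <- parse_kgml(kgml)
  expect_equal(g$nodes, "A")
  expect_equal(nrow(g$edges), 0L)
  expect_equal(g$skipped_entries$entry_id, "2")
  expect_error(parse_kgml("<pathway><entry></pathway>"), "malformed")
})

test_that("SIF parsing: edges, dedup, field validation", {
  g <- parse_sif("A\tactivation\tB")
  expect_equal(g$edges$parent, "A")
  expect_equal(g$edges$child, "B")

  g2 <- parse_sif(c("A\tactivation\tB", "A\tactivation\tB"))
  expect_equal(nrow(g2$edges), 1L)

  expect_error(parse_sif("A\tB"), "line 1")
})

test_that("SIF fixture round-trips and matches its unique pairs", {
  set.seed(11)
  pairs <- expand.grid(p = LETTERS[1:5], c = LETTERS[1:5],
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$p != pairs$c, ]
  pick <- pairs[sample(nrow(pairs), 10), ]
  lines <- sprintf("%s\tunknown\t%s", pick$p, pick$c)
  g <- parse_sif(lines, pathway_id = "fx")
  expect_setequal(paste(g$edges$parent, g$edges$child),
                  unique(paste(pick$p, pick$c)))

  f <- tempfile(fileext = ".sif")
  write_sif(g, f)
  g2 <- parse_sif(f, pathway_id = "fx")
  expect_equal(g2$edges, g$edges[order(g$edges$parent, g$edges$child), ],
               ignore_attr = TRUE)
  expect_equal(g2$nodes, g$nodes)
})

test_that("break_cycles is the identity on a DAG", {
  g <- parse_sif(c("A\tx\tB", "B\tx\tC", "A\tx\tC"))
  out <- break_cycles(g)
  expect_equal(out$edges, g$edges)
  expect_equal(nrow(out$removed_edges), 0L)
})

test_that("break_cycles removes the back-edge of a 2-cycle deterministically", {
  g <- parse_sif(c("A\tx\tB", "B\tx\tA"))
  out <- break_cycles(g)
  # DFS starts at A (lexicographic), so B -> A is the back-edge
  expect_equal(out$removed_edges[, c("parent", "child")],
               data.frame(parent = "B", child = "A"))
  expect_equal(paste(out$edges$parent, out$edges$child), "A B")
})

test_that("break_cycles yields acyclic graphs on random digraphs", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(4:9, 1)
    nodes <- paste0("G", seq_len(n))
    pairs <- expand.grid(p = nodes, c = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$p != pairs$c, ]
    pick <- pairs[sample(nrow(pairs), min(nrow(pairs), n * 2)), ]
    g <- pathway_graph("rnd", nodes = nodes,
                       edges = data.frame(parent = pick$p, child = pick$c))
    out <- break_cycles(g)
    # independent acyclicity oracle
    ig <- igraph::graph_from_data_frame(out$edges[, c("parent", "child")],
                                        vertices = nodes)
    expect_true(igraph::is_dag(ig))
    # edge partition invariant: removed + kept = original, disjoint
    cyc <- out$removed_edges[out$removed_edges$reason == "cycle", ]
    expect_equal(nrow(out$edges) + nrow(cyc), nrow(g$edges))
    expect_length(intersect(paste(out$edges$parent, out$edges$child),
                            paste(cyc$parent, cyc$child)), 0)
  }
})

test_that("parents_of is lexicographic, stable and validated", {
  g <- parse_sif(c("C\tx\tB", "A\tx\tB"))
  expect_equal(parents_of(g, "A"), character(0))
  expect_equal(parents_of(g, "B"), c("A", "C"))
  expect_identical(parents_of(g, "B"), parents_of(g, "B"))
  expect_error(parents_of(g, "ZZ"), "not in pathway")

  # brute-force edge-list scan oracle on a random fixture
  set.seed(5)
  nodes <- paste0("N", 1:8)
  pairs <- expand.grid(p = nodes, c = nodes, stringsAsFactors = FALSE)
  pick <- pairs[pairs$p != pairs$c, ][sample(49, 15), ]
  gg <- pathway_graph("fx", edges = data.frame(parent = pick$p,
                                               child = pick$c))
  for (v in gg$nodes) {
    brute <- sort(unique(pick$p[pick$c == v]))
    expect_equal(parents_of(gg, v), brute)
  }
})

test_that("self-loops and duplicate edges are cleaned at construction", {
  g <- pathway_graph("p", edges = data.frame(
    parent = c("A", "A", "B"), child = c("A", "B", "B")))
  expect_equal(paste(g$edges$parent, g$edges$child), "A B")
  expect_equal(sort(g$removed_edges$reason), c("self-loop", "self-loop"))
})

test_that("topological order errors on cycles and respects edges", {
  g <- parse_sif(c("A\tx\tB", "B\tx\tC"))
  expect_equal(topological_order(g), c("A", "B", "C"))
  cyc <- parse_sif(c("A\tx\tB", "B\tx\tA"))
  expect_error(topological_order(cyc), "cycle")
  expect_false(is_acyclic(cyc))
})
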