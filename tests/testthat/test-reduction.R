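test_that("collapsing preserves external adjacency and drops k-1 nodes per instance", {
  # triangle {a,b,c} with external neighbors x (of a and b) and y (of c)
  g <- read_network(c("a A", "b A", "c B", "x Q", "y Q"),
                    c("a b", "a c", "b c", "x a", "x b", "y c"))
  sel <- make_instances(list(c("a", "b", "c")))
  r <- collapse_instances(g, sel, iteration = 1)
  expect_equal(n_nodes(r), 3)                     # 5 - (3-1)
  sn <- graph_nodes(r)$id[graph_nodes(r)$is_supernode]
  expect_length(sn, 1)
  expect_setequal(paste(graph_edges(r)$from, graph_edges(r)$to),
                  paste(c(sn, sn), c("x", "y")))  # canonical order: SN < x, y
  expect_equal(n_edges(r), 2)                     # 6 - 3 internal - 1 merged dup
  expect_equal(graph_nodes(r)$label[match(sn, graph_nodes(r)$id)], "A-A-B")
  expect_identical(graph_nodes(r)$members[[match(sn, graph_nodes(r)$id)]],
                   c("a", "b", "c"))
})

test_that("an empty selection leaves the graph unchanged", {
  g <- random_lgraph(8, 0.3, seed = 2)
  expect_identical(collapse_instances(g, make_instances(list())), g)
})

test_that("two disjoint size-3 collapses drop four nodes and reject overlaps", {
  g <- read_network(c(sprintf("u%d A", 1:3), sprintf("v%d A", 1:3), "m B"),
                    c("u1 u2", "u2 u3", "v1 v2", "v2 v3", "u3 v1", "u1 m", "v3 m"))
  sel <- make_instances(list(c("u1", "u2", "u3"), c("v1", "v2", "v3")))
  r <- collapse_instances(g, sel)
  expect_equal(n_nodes(g) - n_nodes(r), 4)
  # the u3-v1 edge becomes a supernode-supernode edge
  sn <- graph_nodes(r)$id[graph_nodes(r)$is_supernode]
  expect_true(any(graph_edges(r)$from %in% sn & graph_edges(r)$to %in% sn))

  overlapping <- make_instances(list(c("u1", "u2", "u3"), c("u3", "v1", "v2")))
  expect_error(collapse_instances(g, overlapping), class = "supernoder_contract_error")
})

test_that("supernode labels are alphabetical regardless of member order", {
  g <- read_network(c("z B", "m A", "a C"), c("z m", "m a"))
  for (perm in list(c("z", "m", "a"), c("a", "z", "m"), c("m", "a", "z"))) {
    r <- collapse_instances(g, make_instances(list(perm)))
    expect_equal(graph_nodes(r)$label, "A-B-C")
  }
})

test_that("directed collapse keeps per-edge direction and may keep both ways", {
  g <- read_network(c("a A", "b A", "c A", "x Q", "y Q"),
                    c("a b", "b c", "c a", "x a", "b y"), directed = TRUE)
  r <- collapse_instances(g, make_instances(list(c("a", "b", "c"))))
  sn <- graph_nodes(r)$id[graph_nodes(r)$is_supernode]
  ed <- paste(graph_edges(r)$from, graph_edges(r)$to)
  expect_setequal(ed, c(paste("x", sn), paste(sn, "y")))
})

test_that("the pipeline recovers the planted benchmark in one iteration", {
  fx <- generate_planted_network(seed = 12)
  res <- run_pipeline(fx$graph, k = 3, t = 6, heuristic = "h1", seed = 3)
  rp <- tidy(res)
  expect_equal(rp$n_selected[2], 6L)
  expect_equal(rp$n_nodes[1] - rp$n_nodes[2], 12L)
  gl <- glance(res)
  expect_equal(gl$total_selected, 6)
  expect_equal(gl$initial_nodes - gl$final_nodes, 12)
})

test_that("a threshold above every class count stops the pipeline unchanged", {
  fx <- generate_planted_network(seed = 4)
  expect_message(
    res <- run_pipeline(fx$graph, k = 3, t = 1000, heuristic = "h1", seed = 1),
    "no frequent motif class")
  expect_length(res$graphs, 0)
  expect_equal(nrow(tidy(res)), 1)
})

test_that("supernodes from one round can form frequent motifs in the next", {
  g <- triangle_chain_fixture(6)
  res <- run_pipeline(g, k = 3, t = 6, heuristic = "h3", iterations = 2, seed = 1)
  rp <- tidy(res)
  expect_equal(rp$n_selected, c(NA, 18L, 6L))
  expect_equal(rp$n_nodes, c(54L, 18L, 6L))
  # verify the second-round census independently: the 18 supernodes form six
  # disjoint three-supernode paths, all in one isomorphism class
  g1 <- res$graphs[[1]]
  inst2 <- enumerate_k_subgraphs(g1, 3)
  expect_setequal(inst2$key, oracle_k_subgraphs(g1, 3))
  want <- oracle_classes(inst2, g1)
  expect_length(want, 1)
  expect_length(want[[1]], 6)

  # node counts never increase, and drop by exactly (k-1) x selected
  expect_true(all(diff(rp$n_nodes) <= 0))
  expect_equal(rp$n_nodes[-1], rp$n_nodes[-nrow(rp)] - 2L * rp$n_selected[-1])
})

test_that("pipeline runs are reproducible for every heuristic under a fixed seed", {
  fx <- generate_planted_network(seed = 20)
  for (h in c("h1", "h2", "h3", "h4", "h5")) {
    a <- run_pipeline(fx$graph, k = 3, t = 6, heuristic = h, seed = 8,
                      sample_size = 4)
    b <- run_pipeline(fx$graph, k = 3, t = 6, heuristic = h, seed = 8,
                      sample_size = 4)
    expect_identical(write_network(a$graphs[[1]]), write_network(b$graphs[[1]]),
                     info = h)
    expect_identical(tidy(a), tidy(b), info = h)
  }
})

test_that("pipeline outputs round-trip through the output directory", {
  fx <- generate_planted_network(seed = 12)
  res <- run_pipeline(fx$graph, k = 3, t = 6, heuristic = "h4", seed = 1)
  dir <- withr::local_tempdir()
  write_reduction(res, dir)
  expect_true(file.exists(file.path(dir, "nodes_1.txt")))
  g2 <- read_network(file.path(dir, "nodes_1.txt"), file.path(dir, "edges_1.txt"),
                     provenance = file.path(dir, "provenance_1.txt"))
  expect_identical(write_network(g2)$node_rows, write_network(res$graphs[[1]])$node_rows)
  rep2 <- utils::read.delim(file.path(dir, "report.tsv"))
  expect_equal(nrow(rep2), nrow(tidy(res)))
})

test_that("autoplot returns a ggplot of the reduction trajectory", {
  fx <- generate_planted_network(seed = 12)
  res <- run_pipeline(fx$graph, k = 3, t = 6, heuristic = "h1", seed = 3)
  expect_s3_class(autoplot(res), "ggplot")
})
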