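path_overlap_instances <- function() {
  g <- read_network(sprintf("n%d A", 1:7), sprintf("n%d n%d", 1:6, 2:7))
  list(graph = g,
       instances = make_instances(list(c("n1", "n2", "n3"),
                                       c("n3", "n4", "n5"),
                                       c("n5", "n6", "n7"))))
}

disjoint_instances <- function(n = 5) {
  ids <- sprintf("d%d_%d", rep(seq_len(n), each = 3), 1:3)
  g <- labeled_graph(data.frame(id = ids, label = "A"),
                     data.frame(from = ids[c(TRUE, FALSE, FALSE)],
                                to = ids[c(FALSE, TRUE, FALSE)]) |>
                       rbind(data.frame(from = ids[c(FALSE, TRUE, FALSE)],
                                        to = ids[c(FALSE, FALSE, TRUE)])))
  list(graph = g,
       instances = make_instances(split(ids, rep(seq_len(n), each = 3))))
}

test_that("the overlap graph connects exactly the instances sharing a node", {
  fx <- path_overlap_instances()
  og <- build_overlap_graph(fx$instances)
  expect_equal(og$adj, list(2L, c(1L, 3L), 2L))

  dj <- disjoint_instances(3)
  expect_equal(sum(lengths(build_overlap_graph(dj$instances)$adj)), 0)

  # quadratic all-pairs oracle on a random 50-instance fixture
  fx2 <- random_selection_fixture(101, n = 16, p = 0.35, max_inst = 50)
  og2 <- build_overlap_graph(fx2$instances)
  m <- nrow(fx2$instances)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    shares <- length(intersect(fx2$instances$nodes[[i]], fx2$instances$nodes[[j]])) > 0
    expect_equal(j %in% og2$adj[[i]], shares)
  }
})

test_that("branch-and-bound MIS is exact and capped", {
  fx <- path_overlap_instances()
  mis <- exact_mis(build_overlap_graph(fx$instances))
  expect_equal(mis$key, c("n1 n2 n3", "n5 n6 n7"))

  # overlap triangle: all three instances share node x
  g <- read_network(c("x A", sprintf("m%d A", 1:6)),
                    c("x m1", "x m3", "x m5", "m1 m2", "m3 m4", "m5 m6"))
  tri <- make_instances(list(c("x", "m1", "m2"), c("x", "m3", "m4"), c("x", "m5", "m6")))
  expect_equal(nrow(exact_mis(build_overlap_graph(tri))), 1)

  dj <- disjoint_instances(5)
  expect_equal(nrow(exact_mis(build_overlap_graph(dj$instances))), 5)

  for (seed in 1:10) {
    fxr <- random_selection_fixture(seed, n = 12, p = 0.35, max_inst = 12)
    og <- build_overlap_graph(fxr$instances)
    expect_equal(nrow(exact_mis(og)), oracle_mis_size(og))
  }

  many <- random_selection_fixture(7, n = 16, p = 0.5, max_inst = 30)
  expect_error(exact_mis(build_overlap_graph(many$instances)),
               class = "supernoder_parameter_error")
})

test_that("greedy elimination finds the path optimum and keeps disjoint sets maximal", {
  fx <- path_overlap_instances()
  sel <- h1_greedy(fx$instances, n_shuffles = 20, seed = 4)
  expect_equal(sel$key, c("n1 n2 n3", "n5 n6 n7"))

  dj <- disjoint_instances(4)
  expect_equal(nrow(h1_greedy(dj$instances, n_shuffles = 1, seed = 1)), 4)

  s1 <- h1_greedy(fx$instances, n_shuffles = 5, seed = 99)
  s2 <- h1_greedy(fx$instances, n_shuffles = 5, seed = 99)
  expect_identical(s1, s2)
})

test_that("the Ramsey heuristic resolves overlaps for any chunk size", {
  fx <- path_overlap_instances()
  for (ss in c(1, 2, 3, 10)) {
    sel <- h2_ramsey(fx$instances, sample_size = ss, seed = 5)
    expect_true(is_disjoint(sel))
    if (ss >= 3) expect_equal(nrow(sel), 2)
  }
  dj <- disjoint_instances(5)
  expect_equal(nrow(h2_ramsey(dj$instances, sample_size = 2, seed = 1)), 5)
})

test_that("ranked elimination prefers low motif degree and stays independent", {
  fx <- random_selection_fixture(55, n = 14, p = 0.3, max_inst = 30)
  md <- motif_degree(fx$graph, fx$instances)
  # spot-check the degree formula on undirected hosts
  idxdeg <- vapply(seq_len(nrow(md)), function(i) {
    nd <- md$nodes[[i]]
    ed <- graph_edges(fx$graph)
    host_deg <- sum(ed$from %in% nd) + sum(ed$to %in% nd)
    internal <- sum(ed$from %in% nd & ed$to %in% nd)
    host_deg - 2L * internal
  }, integer(1))
  expect_equal(md$degree, idxdeg)

  # two overlapping instances: the lower-degree one survives
  g <- read_network(c("a A", "b A", "c A", "d A", "e A", "x A", "y A", "z A"),
                    c("a b", "b c", "c d", "d e", "c x", "c y", "d z"))
  two <- make_instances(list(c("a", "b", "c"), c("c", "d", "e")))
  degs <- motif_degree(g, two)$degree
  sel <- h3_ranked_elimination(two, g)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$key, two$key[which.min(degs)])

  dj <- disjoint_instances(4)
  expect_equal(nrow(h3_ranked_elimination(dj$instances, dj$graph)), 4)

  s <- h3_ranked_elimination(fx$instances, fx$graph)
  expect_true(is_disjoint(s))
})

test_that("repeated ranked elimination recovers instances that H3 strands", {
  fx <- h3_adversarial_fixture()
  s3 <- h3_ranked_elimination(fx$instances, fx$graph)
  s4 <- h4_repeated_ranked(fx$instances, fx$graph)
  expect_equal(s3$key, "n4 n5 n6")
  expect_setequal(s4$key, c("n4 n5 n6", "n7 n8 n9"))
  expect_gt(nrow(s4), nrow(s3))
  mis <- exact_mis(build_overlap_graph(fx$instances))
  expect_equal(nrow(s4), nrow(mis))

  dj <- disjoint_instances(4)
  expect_equal(nrow(h4_repeated_ranked(dj$instances, dj$graph)), 4)
})

test_that("sampled ranked elimination removes the higher-overlap-degree endpoint", {
  # overlap star: a 4-node center instance shares one node with each leaf
  g <- read_network(c(sprintf("c%d A", 1:4), sprintf("l%d A", 1:8)),
                    c("c1 c2", "c2 c3", "c3 c4",
                      "c1 l1", "l1 l2", "c2 l3", "l3 l4",
                      "c3 l5", "l5 l6", "c4 l7", "l7 l8"))
  center <- c("c1", "c2", "c3", "c4")
  leaves <- list(c("c1", "l1", "l2"), c("c2", "l3", "l4"),
                 c("c3", "l5", "l6"), c("c4", "l7", "l8"))
  star <- make_instances(c(list(center), leaves))
  sel <- h5_sampled_ranked(star, sample_size = 10, seed = 3)
  expect_setequal(sel$key, make_instances(leaves)$key)
  expect_equal(nrow(exact_mis(build_overlap_graph(star))), 4)

  dj <- disjoint_instances(5)
  expect_equal(nrow(h5_sampled_ranked(dj$instances, sample_size = 2, seed = 1)), 5)

  fx <- random_selection_fixture(77, n = 14, p = 0.3, max_inst = 30)
  a <- h5_sampled_ranked(fx$instances, sample_size = 7, seed = 12)
  b <- h5_sampled_ranked(fx$instances, sample_size = 7, seed = 12)
  expect_identical(a, b)
  expect_true(is_disjoint(a))
})

test_that("every heuristic returns an independent set; H1/H4 are maximal", {
  for (seed in 1:20) {
    fx <- random_selection_fixture(seed, n = 14, p = 0.3, max_inst = 30)
    sels <- list(
      h1 = h1_greedy(fx$instances, n_shuffles = 3, seed = seed),
      h2 = h2_ramsey(fx$instances, sample_size = 6, seed = seed),
      h3 = h3_ranked_elimination(fx$instances, fx$graph),
      h4 = h4_repeated_ranked(fx$instances, fx$graph),
      h5 = h5_sampled_ranked(fx$instances, sample_size = 6, seed = seed))
    for (nm in names(sels)) {
      expect_true(is_disjoint(sels[[nm]]), info = paste(nm, "seed", seed))
    }
    for (nm in c("h1", "h4")) {
      used <- unlist(sels[[nm]]$nodes)
      addable <- vapply(setdiff(fx$instances$key, sels[[nm]]$key), function(kk) {
        nd <- fx$instances$nodes[[match(kk, fx$instances$key)]]
        !any(nd %in% used)
      }, logical(1))
      expect_false(any(addable), info = paste(nm, "maximality seed", seed))
    }
  }
})
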