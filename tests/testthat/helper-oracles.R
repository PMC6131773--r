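# Independent oracles (igraph-based) and shared fixture builders.

csort <- function(x) sort(x, method = "radix")

make_instances <- function(node_sets) {
  node_sets <- lapply(node_sets, csort)
  tibble::tibble(nodes = node_sets,
                 key = vapply(node_sets, paste, character(1), collapse = " "))
}

to_igraph <- function(g) {
  igraph::graph_from_data_frame(graph_edges(g), directed = g$directed,
                                vertices = graph_nodes(g)[, c("id", "label")])
}

# brute-force connected k-subgraph enumeration: all C(n, k) subsets, keep
# the ones whose induced subgraph is (weakly) connected
oracle_k_subgraphs <- function(g, k) {
  ids <- csort(graph_nodes(g)$id)
  if (k > length(ids)) return(character(0))
  ig <- to_igraph(g)
  subs <- utils::combn(ids, k, simplify = FALSE)
  keep <- vapply(subs, function(s) {
    igraph::is_connected(igraph::induced_subgraph(ig, s), mode = "weak")
  }, logical(1))
  vapply(subs[keep], paste, character(1), collapse = " ")
}

# label-preserving isomorphism of two induced subgraphs via igraph's VF2
oracle_isomorphic <- function(g, n1, n2) {
  ig <- to_igraph(g)
  s1 <- igraph::induced_subgraph(ig, n1)
  s2 <- igraph::induced_subgraph(ig, n2)
  all_lab <- csort(unique(graph_nodes(g)$label))
  igraph::is_isomorphic_to(
    s1, s2, method = "vf2",
    vertex.color1 = match(igraph::V(s1)$label, all_lab),
    vertex.color2 = match(igraph::V(s2)$label, all_lab))
}

# brute-force grouping into isomorphism classes (union-find over all pairs)
oracle_classes <- function(instances, g) {
  n <- nrow(instances)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ri <- find(i); rj <- find(j)
    if (ri != rj && oracle_isomorphic(g, instances$nodes[[i]], instances$nodes[[j]])) {
      parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(rows) csort(instances$key[rows]))
}

# exhaustive maximum independent set by subset enumeration (n <= 15)
oracle_mis_size <- function(og) {
  n <- og$n
  stopifnot(n <= 15)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    for (v in sel) if (any(og$adj[[v]] %in% sel)) { ok <- FALSE; break }
    if (ok) best <- length(sel)
  }
  best
}

random_lgraph <- function(n, p, labels = c("A", "B"), seed = 1, directed = FALSE) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    labs <- sample(labels, n, replace = TRUE)
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    hit <- stats::runif(nrow(pr)) < p
    from <- ids[pr[hit, 1]]
    to <- ids[pr[hit, 2]]
    if (directed) {
      flip <- stats::runif(length(from)) < 0.5
      tmp <- from[flip]; from[flip] <- to[flip]; to[flip] <- tmp
    }
    labeled_graph(data.frame(id = ids, label = labs),
                  data.frame(from = from, to = to), directed = directed)
  })
}

# a host graph plus a random subset of its connected triples, for testing
# selection heuristics
random_selection_fixture <- function(seed, n = 14, p = 0.3, max_inst = 40) {
  g <- random_lgraph(n, p, labels = c("A", "B", "C"), seed = seed)
  inst <- enumerate_k_subgraphs(g, 3)
  if (nrow(inst) > max_inst) {
    rows <- withr::with_seed(seed + 1000L, sample.int(nrow(inst), max_inst))
    inst <- inst[sort(rows), ]
  }
  list(graph = g, instances = inst)
}

# Chain fixture where ranked elimination (H3) strands a recoverable
# instance that repeated ranked elimination (H4) then picks up.
# Degrees: ma = 3 (kept by H3), mb = 4, mc = 5 (both discarded, stranding
# mr = {n7, n8, n9}, degree 5, which never enters the potential list).
h3_adversarial_fixture <- function() {
  core <- sprintf("n%d", 1:9)
  pend <- c("w1", "w2", "y1", "z1", "z2")
  nodes <- data.frame(id = c(core, pend), label = "L")
  edges <- rbind(
    data.frame(from = c("n4", "n5", "n6", "n7", "n3", "n4", "n8"),
               to = c("n5", "n6", "n7", "n8", "n4", "n9", "n9")),
    data.frame(from = c("n7", "n7", "n9", "n3", "n3"),
               to = c("w1", "w2", "y1", "z1", "z2")))
  g <- labeled_graph(nodes, edges)
  inst <- make_instances(list(c("n4", "n5", "n6"), c("n6", "n7", "n8"),
                              c("n3", "n4", "n9"), c("n7", "n8", "n9")))
  list(graph = g, instances = inst)
}

# Six disjoint chains of three (A,A,B)-triangles bridged A-to-A; triangles
# have motif degree <= 2 while bridge paths have degree >= 4, so ranked
# elimination deterministically selects all 18 triangles, and the collapsed
# graph is six supernode paths that form one frequent class.
triangle_chain_fixture <- function(n_copies = 6) {
  nodes <- NULL; edges <- NULL
  for (cp in seq_len(n_copies)) {
    for (tr in 1:3) {
      ids <- sprintf("c%d_t%d_%s", cp, tr, c("n1", "n2", "n3"))
      nodes <- rbind(nodes, data.frame(id = ids, label = c("A", "A", "B")))
      edges <- rbind(edges, data.frame(from = ids[c(1, 1, 2)], to = ids[c(2, 3, 3)]))
    }
    edges <- rbind(edges,
                   data.frame(from = sprintf("c%d_t1_n2", cp), to = sprintf("c%d_t2_n1", cp)),
                   data.frame(from = sprintf("c%d_t2_n2", cp), to = sprintf("c%d_t3_n1", cp)))
  }
  labeled_graph(nodes, edges)
}

# two non-isomorphic all-"A" shapes on 5 nodes with 5 edges each: a 5-cycle
# and a triangle with a pendant 2-path — identical label/degree signature
signature_collision_fixture <- function(n_copies = 4) {
  nodes <- NULL; edges <- NULL; cyc <- list(); tri <- list()
  for (cp in seq_len(n_copies)) {
    c_ids <- sprintf("cy%d_%d", cp, 1:5)
    t_ids <- sprintf("tr%d_%d", cp, 1:5)
    nodes <- rbind(nodes, data.frame(id = c(c_ids, t_ids), label = "A"))
    edges <- rbind(edges,
                   data.frame(from = c_ids, to = c_ids[c(2:5, 1)]),
                   data.frame(from = t_ids[c(1, 2, 3, 3, 4)], to = t_ids[c(2, 3, 1, 4, 5)]))
    cyc[[cp]] <- c_ids
    tri[[cp]] <- t_ids
  }
  list(graph = labeled_graph(nodes, edges),
       instances = make_instances(c(cyc, tri)))
}
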