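# Map instance node lists to integer vectors over the union of host nodes.
instance_ints <- function(instances) {
  pool <- rsort(unique(unlist(instances$nodes)))
  list(pool = pool, sets = lapply(instances$nodes, match, pool))
}

# Overlap adjacency among the instance rows `rows` (global indices), via an
# inverted host-node index. Returns a list of integer neighbor vectors
# parallel to `rows`.
overlap_adjacency <- function(sets, rows) {
  m <- length(rows)
  local_nodes <- unlist(sets[rows], use.names = FALSE)
  owner <- rep(seq_len(m), lengths(sets[rows]))
  groups <- split(owner, local_nodes)
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (g in groups) {
    if (length(g) > 1) {
      cmb <- utils::combn(g, 2L)
      pairs_a <- c(pairs_a, cmb[1L, ])
      pairs_b <- c(pairs_b, cmb[2L, ])
    }
  }
  a <- c(pairs_a, pairs_b); b <- c(pairs_b, pairs_a)
  key <- (a - 1) * m + b
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  o <- order(a, b)
  unname(split(b[o], factor(a[o], levels = seq_len(m))))
}

#' Build the overlap graph of a set of motif instances
#'
#' The overlap graph has one vertex per instance and an edge between two
#' instances iff they share at least one host node; an independent set in it
#' is exactly a pairwise node-disjoint (F3) selection. Adjacency is built
#' through an inverted host-node index, never by an all-pairs scan.
#'
#' @param instances an instance tibble.
#' @return An object of class `overlap_graph`: the instances, their
#'   adjacency lists and the vertex count.
#' @export
build_overlap_graph <- function(instances) {
  ii <- instance_ints(instances)
  adj <- overlap_adjacency(ii$sets, seq_len(nrow(instances)))
  structure(list(n = nrow(instances), adj = adj, instances = instances),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("An overlap graph: %d instances, %d overlap edges\n",
              x$n, sum(lengths(x$adj)) %/% 2L))
  invisible(x)
}

#' Exact maximum independent set of an overlap graph
#'
#' Branch-and-bound search, used as the optimum that the selection
#' heuristics approximate. Capped at 25 vertices.
#'
#' @param og an [build_overlap_graph()] result.
#' @return The instance tibble rows forming a maximum node-disjoint set.
#' @export
exact_mis <- function(og) {
  if (og$n > 25) abort("exact_mis is limited to 25 instances", class = "supernoder_parameter_error")
  adj <- og$adj
  best <- integer(0)
  bb <- function(P, cur) {
    # take all isolated vertices of the induced subgraph on P for free
    repeat {
      if (!length(P)) break
      degP <- vapply(P, function(v) sum(adj[[v]] %in% P), integer(1))
      iso <- P[degP == 0L]
      if (!length(iso)) break
      cur <- c(cur, iso)
      P <- setdiff(P, iso)
    }
    if (length(cur) > length(best)) best <<- cur
    if (!length(P) || length(cur) + length(P) <= length(best)) return(invisible(NULL))
    degP <- vapply(P, function(v) sum(adj[[v]] %in% P), integer(1))
    v <- P[which.max(degP)]
    bb(setdiff(P, c(v, adj[[v]])), c(cur, v))
    bb(setdiff(P, v), cur)
    invisible(NULL)
  }
  bb(seq_len(og$n), integer(0))
  og$instances[sort.int(best), ]
}

#' Disjoint-motif selection heuristics
#'
#' Five heuristics that extract a large pairwise node-disjoint (F3) subset
#' from the frequent motif set; all return an independent set of the overlap
#' graph and are deterministic for a fixed `seed`.
#'
#' * `h1_greedy()` (Greedy Elimination): scans a random shuffle of the
#'   instances, keeping each instance disjoint from everything kept so far,
#'   and returns the best of `n_shuffles` attempts. The result is maximal.
#' * `h2_ramsey()` (Ramsey): partitions the shuffled instances into chunks of
#'   `sample_size`, runs the recursive Ramsey independent-set procedure
#'   (branch on a vertex's non-neighbors and neighbors, keep the larger
#'   independent set) on each chunk's induced overlap subgraph, merges the
#'   survivors and repeats until no overlaps remain.
#' * `h3_ranked_elimination()` (Ranked Elimination): orders instances by
#'   ascending motif degree (see [motif_degree()]); for each host node the
#'   lowest-degree instance containing it becomes a potential supernode; the
#'   potential list is then scanned in rank order, dropping the
#'   higher-degree member of every overlapping pair. May miss recoverable
#'   instances, i.e. the result need not be maximal.
#' * `h4_repeated_ranked()` (Repeated Ranked Elimination): runs the H3
#'   procedure, then restricts the original instance list to instances fully
#'   contained in orphan nodes (covered by no selected instance) and
#'   repeats until no candidate instance remains. The result is maximal and
#'   never smaller than a single H3 pass.
#' * `h5_sampled_ranked()` (Sampled Ranked Elimination): chunk-samples as H2,
#'   builds the overlap subgraph on each chunk and processes instances in
#'   ascending overlap-degree order — conflict-free instances are kept, and
#'   of every conflicting pair the endpoint with the larger current overlap
#'   degree (ties: larger instance key) is removed; merges and repeats until
#'   no overlaps remain.
#'
#' Ties in every ordering are broken by the instance's sorted node-ID tuple
#' so that results are reproducible.
#'
#' @param instances an instance tibble (the pooled frequent motif set).
#' @param n_shuffles number of random shuffles tried by H1.
#' @param sample_size chunk size for the H2/H5 sampling stage.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param graph the host [labeled_graph()] (needed by H3/H4 for motif
#'   degrees).
#' @param max_rounds safety cap on H2/H5 merge cycles.
#' @return The selected rows of `instances`, in instance-key order.
#' @name selection_heuristics
NULL

#' @rdname selection_heuristics
#' @export
h1_greedy <- function(instances, n_shuffles = 5, seed = NULL) {
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1", class = "supernoder_parameter_error")
  n <- nrow(instances)
  if (n == 0) return(instances)
  ii <- instance_ints(instances)
  run <- function() {
    best <- integer(0)
    for (s in seq_len(n_shuffles)) {
      perm <- sample.int(n)
      used <- logical(length(ii$pool))
      sel <- integer(0)
      for (i in perm) {
        nd <- ii$sets[[i]]
        if (!any(used[nd])) {
          used[nd] <- TRUE
          sel <- c(sel, i)
        }
      }
      if (length(sel) > length(best)) best <- sel
    }
    best
  }
  sel <- maybe_seed(seed, run)
  instances[sort.int(sel), ]
}

ramsey_is <- function(inset, M) {
  v <- which(inset)
  if (!length(v)) return(integer(0))
  v <- v[1L]
  nb <- M[v, ] & inset
  rest <- inset
  rest[v] <- FALSE
  i1 <- c(v, ramsey_is(rest & !nb, M))
  i2 <- ramsey_is(nb, M)
  if (length(i2) > length(i1)) i2 else i1
}

has_overlap <- function(sets, rows) {
  anyDuplicated(unlist(sets[rows], use.names = FALSE)) > 0L
}

#' @rdname selection_heuristics
#' @export
h2_ramsey <- function(instances, sample_size = 1000, seed = NULL, max_rounds = 100) {
  if (sample_size < 1) abort("`sample_size` must be >= 1", class = "supernoder_parameter_error")
  n <- nrow(instances)
  if (n == 0) return(instances)
  ii <- instance_ints(instances)
  run <- function() {
    cur <- seq_len(n)
    eff <- sample_size
    for (round in seq_len(max_rounds)) {
      if (!has_overlap(ii$sets, cur)) return(cur)
      perm <- cur[sample.int(length(cur))]
      chunks <- split(perm, ceiling(seq_along(perm) / eff))
      keep <- integer(0)
      for (ch in chunks) {
        adjc <- overlap_adjacency(ii$sets, ch)
        M <- matrix(FALSE, length(ch), length(ch))
        for (a in seq_along(ch)) M[a, adjc[[a]]] <- TRUE
        is_local <- ramsey_is(rep(TRUE, length(ch)), M)
        keep <- c(keep, ch[is_local])
      }
      if (length(keep) == length(cur)) eff <- min(eff * 2L, length(cur))
      cur <- keep
    }
    abort("h2_ramsey did not converge within `max_rounds` cycles",
          class = "supernoder_iteration_error")
  }
  sel <- maybe_seed(seed, run)
  instances[sort.int(sel), ]
}

#' Motif degree of each instance
#'
#' The motif degree of an instance is the sum over its nodes of the
#' host-graph degree counting only edges that leave the instance, i.e. the
#' total degree minus twice the induced edge count. Low-degree instances are
#' less likely to overlap and are preferred by the ranked heuristics.
#'
#' @param graph the host [labeled_graph()].
#' @param instances an instance tibble.
#' @return `instances` with an added integer `degree` column.
#' @export
motif_degree <- function(graph, instances) {
  idx <- graph_index(graph)
  deg <- vapply(instances$nodes, function(nd) {
    m <- match(nd, idx$ids)
    if (anyNA(m)) abort("instance node(s) not in graph", class = "supernoder_referential_error")
    inset <- logical(idx$n)
    inset[m] <- TRUE
    if (!idx$directed) {
      sum(vapply(m, function(v) sum(!inset[idx$adj[[v]]]), integer(1)))
    } else {
      sum(vapply(m, function(v) {
        sum(!inset[idx$out_adj[[v]]]) + sum(!inset[idx$in_adj[[v]]])
      }, integer(1)))
    }
  }, integer(1))
  out <- instances
  out$degree <- deg
  out
}

# Shared H3 core over precomputed integer sets; returns selected row indices.
h3_core <- function(instances, graph, ii) {
  n <- nrow(instances)
  if (n == 0) return(integer(0))
  md <- motif_degree(graph, instances)
  keyrank <- match(md$key, rsort(md$key))
  ranked <- order(md$degree, keyrank)  # ascending degree, key tie-break
  best_for <- integer(length(ii$pool))
  for (r in ranked) {
    nd <- ii$sets[[r]]
    fresh <- nd[best_for[nd] == 0L]
    best_for[fresh] <- r
  }
  psn <- ranked[vapply(ranked, function(r) any(best_for[ii$sets[[r]]] == r), logical(1))]
  used <- logical(length(ii$pool))
  sel <- integer(0)
  for (r in psn) {
    nd <- ii$sets[[r]]
    if (!any(used[nd])) {
      used[nd] <- TRUE
      sel <- c(sel, r)
    }
  }
  sel
}

#' @rdname selection_heuristics
#' @export
h3_ranked_elimination <- function(instances, graph) {
  ii <- instance_ints(instances)
  sel <- h3_core(instances, graph, ii)
  instances[sort.int(sel), ]
}

#' @rdname selection_heuristics
#' @export
h4_repeated_ranked <- function(instances, graph) {
  n <- nrow(instances)
  if (n == 0) return(instances)
  ii <- instance_ints(instances)
  covered <- logical(length(ii$pool))
  selected <- integer(0)
  repeat {
    cand <- setdiff(which(!vapply(ii$sets, function(nd) any(covered[nd]), logical(1))),
                    selected)
    if (!length(cand)) break
    sub <- instances[cand, ]
    sel_local <- h3_core(sub, graph, list(pool = ii$pool, sets = ii$sets[cand]))
    if (!length(sel_local)) break
    sel <- cand[sel_local]
    selected <- c(selected, sel)
    for (r in sel) covered[ii$sets[[r]]] <- TRUE
  }
  instances[sort.int(selected), ]
}

# Degree-based conflict elimination within one chunk (H5 inner step).
# `ch` holds global row indices; returns the kept subset of `ch`.
resolve_by_degree <- function(ch, sets, keys) {
  m <- length(ch)
  if (m <= 1) return(ch)
  adjc <- overlap_adjacency(sets, ch)
  status <- rep("pending", m)   # pending / kept / removed
  deg0 <- lengths(adjc)
  keyrank <- match(keys[ch], rsort(keys[ch]))
  ord <- order(deg0, keyrank)
  curdeg <- function(x) sum(status[adjc[[x]]] != "removed")
  for (v in ord) {
    if (status[v] != "pending") next
    repeat {
      conf <- adjc[[v]][status[adjc[[v]]] != "removed"]
      if (!length(conf)) { status[v] <- "kept"; break }
      u <- conf[rorder(keys[ch[conf]])][1L]
      if (status[u] == "kept") { status[v] <- "removed"; break }
      dv <- curdeg(v); du <- curdeg(u)
      if (dv > du) { status[v] <- "removed"; break }
      if (du > dv) { status[u] <- "removed"; next }
      # tie: remove the larger instance-ID tuple
      loser <- if (rorder(c(keys[ch[v]], keys[ch[u]]))[1L] == 1L) u else v
      status[loser] <- "removed"
      if (loser == v) break
    }
  }
  ch[status == "kept"]
}

#' @rdname selection_heuristics
#' @export
h5_sampled_ranked <- function(instances, sample_size = 1000, seed = NULL, max_rounds = 100) {
  if (sample_size < 1) abort("`sample_size` must be >= 1", class = "supernoder_parameter_error")
  n <- nrow(instances)
  if (n == 0) return(instances)
  ii <- instance_ints(instances)
  run <- function() {
    cur <- seq_len(n)
    eff <- sample_size
    for (round in seq_len(max_rounds)) {
      if (!has_overlap(ii$sets, cur)) return(cur)
      perm <- cur[sample.int(length(cur))]
      chunks <- split(perm, ceiling(seq_along(perm) / eff))
      keep <- integer(0)
      for (ch in chunks) keep <- c(keep, resolve_by_degree(ch, ii$sets, instances$key))
      if (length(keep) == length(cur)) eff <- min(eff * 2L, length(cur))
      cur <- keep
    }
    abort("h5_sampled_ranked did not converge within `max_rounds` cycles",
          class = "supernoder_iteration_error")
  }
  sel <- maybe_seed(seed, run)
  instances[sort.int(sel), ]
}

#' Select disjoint motif instances with a named heuristic
#'
#' Dispatcher over the five heuristics (see [selection_heuristics]).
#'
#' @inheritParams selection_heuristics
#' @param heuristic one of `"h1"` .. `"h5"`.
#' @return The selected rows of `instances`.
#' @export
select_disjoint <- function(instances, graph, heuristic = c("h1", "h2", "h3", "h4", "h5"),
                            seed = NULL, n_shuffles = 5, sample_size = 1000) {
  heuristic <- match.arg(heuristic)
  switch(heuristic,
    h1 = h1_greedy(instances, n_shuffles = n_shuffles, seed = seed),
    h2 = h2_ramsey(instances, sample_size = sample_size, seed = seed),
    h3 = h3_ranked_elimination(instances, graph),
    h4 = h4_repeated_ranked(instances, graph),
    h5 = h5_sampled_ranked(instances, sample_size = sample_size, seed = seed)
  )
}
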