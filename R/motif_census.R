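# Per-member in/out degrees restricted to the induced subgraph.
induced_degrees <- function(members, idx) {
  inset <- logical(idx$n)
  inset[members] <- TRUE
  if (!idx$directed) {
    d <- vapply(members, function(v) sum(inset[idx$adj[[v]]]), integer(1))
    list(ind = d, outd = d, n_edges = sum(d) %/% 2L)
  } else {
    o <- vapply(members, function(v) sum(inset[idx$out_adj[[v]]]), integer(1))
    i <- vapply(members, function(v) sum(inset[idx$in_adj[[v]]]), integer(1))
    list(ind = i, outd = o, n_edges = sum(o))
  }
}

sig_entries <- function(members, idx) {
  d <- induced_degrees(members, idx)
  labs <- idx$labels[members]
  u <- rsort(unique(labs))
  m <- match(labs, u)
  tibble(label = u,
         n = as.integer(tabulate(m, length(u))),
         i = as.integer(vapply(seq_along(u), function(j) sum(d$ind[m == j]), integer(1))),
         o = as.integer(vapply(seq_along(u), function(j) sum(d$outd[m == j]), integer(1))))
}

sig_digest_entries <- function(entries) {
  paste(sprintf("%s=%d,%d,%d", entries$label, entries$n, entries$i, entries$o),
        collapse = ";")
}

#' Label/degree signature of a subgraph instance
#'
#' For each label occurring in the instance, the signature records how many
#' member nodes carry it and the sums of their in- and out-degrees counted
#' only over the induced edges; in an undirected graph in-degree and
#' out-degree both equal the plain degree. Entries are sorted
#' lexicographically by label and the digest is their canonical string, so
#' it is stable across runs and processes. Isomorphic instances always share
#' a digest; the converse does not hold, so the digest is a grouping
#' prefilter that must be refined by [are_isomorphic()].
#'
#' @param graph the host [labeled_graph()].
#' @param nodes character vector of the instance's node IDs.
#' @return A tibble with columns `label`, `n`, `i`, `o`, carrying the digest
#'   string in attribute `"digest"`.
#' @export
motif_signature <- function(graph, nodes) {
  idx <- graph_index(graph)
  members <- match(as.character(nodes), idx$ids)
  if (anyNA(members)) abort("instance node(s) not in graph", class = "supernoder_referential_error")
  entries <- sig_entries(members, idx)
  attr(entries, "digest") <- sig_digest_entries(entries)
  entries
}

# Induced adjacency matrix (k x k logical) for a member set, directed as stored.
induced_matrix <- function(members, idx) {
  k <- length(members)
  pos <- integer(idx$n)
  pos[members] <- seq_len(k)
  A <- matrix(FALSE, k, k)
  if (!idx$directed) {
    for (j in seq_len(k)) {
      nb <- idx$adj[[members[j]]]
      hit <- pos[nb]
      hit <- hit[hit > 0L]
      A[j, hit] <- TRUE
    }
  } else {
    for (j in seq_len(k)) {
      nb <- idx$out_adj[[members[j]]]
      hit <- pos[nb]
      hit <- hit[hit > 0L]
      A[j, hit] <- TRUE
    }
  }
  A
}

iso_backtrack <- function(A1, l1, A2, l2, directed) {
  k <- nrow(A1)
  d1o <- rowSums(A1); d1i <- colSums(A1)
  d2o <- rowSums(A2); d2i <- colSums(A2)
  used <- logical(k)
  mp <- integer(k)
  rec <- function(i) {
    if (i > k) return(TRUE)
    for (j in seq_len(k)) {
      if (used[j] || l1[i] != l2[j] || d1o[i] != d2o[j] || d1i[i] != d2i[j]) next
      ok <- TRUE
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        pj <- mp[prev]
        if (any(A1[i, prev] != A2[j, pj]) || any(A1[prev, i] != A2[pj, j])) ok <- FALSE
      }
      if (ok) {
        used[j] <<- TRUE
        mp[i] <<- j
        if (rec(i + 1L)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  rec(1L)
}

#' Label-preserving subgraph isomorphism
#'
#' Tests whether two instances of the same host graph are isomorphic: a
#' bijection between their node sets must preserve adjacency (and edge
#' direction in a directed graph) and node labels. Implemented as a
#' backtracking matcher with label and degree pruning.
#'
#' @param graph the host [labeled_graph()].
#' @param nodes1,nodes2 character vectors of node IDs of the two instances.
#' @return Logical scalar.
#' @export
are_isomorphic <- function(graph, nodes1, nodes2) {
  idx <- graph_index(graph)
  m1 <- match(as.character(nodes1), idx$ids)
  m2 <- match(as.character(nodes2), idx$ids)
  if (anyNA(m1) || anyNA(m2)) abort("instance node(s) not in graph", class = "supernoder_referential_error")
  iso_members(m1, m2, idx)
}

iso_members <- function(m1, m2, idx) {
  if (length(m1) != length(m2)) return(FALSE)
  l1 <- idx$labels[m1]
  l2 <- idx$labels[m2]
  if (!identical(rsort(l1), rsort(l2))) return(FALSE)
  A1 <- induced_matrix(m1, idx)
  A2 <- induced_matrix(m2, idx)
  if (sum(A1) != sum(A2)) return(FALSE)
  iso_backtrack(A1, l1, A2, l2, idx$directed)
}

#' Find frequent motif classes (F1 census)
#'
#' Buckets instances by their signature digest, refines each bucket that
#' reaches the threshold into true label-preserving isomorphism classes by
#' matching every instance against the class representatives (in instance
#' key order, first match wins), and returns the classes whose F1 count —
#' the plain instance count, overlaps allowed — is at least `t`. The union
#' of the returned classes' instances is the frequent motif set.
#'
#' @param instances an instance tibble from [enumerate_k_subgraphs()].
#' @param graph the host [labeled_graph()].
#' @param t frequency threshold, at least 1; a class is frequent when its
#'   F1 count is `>= t`.
#' @return A tibble with one row per frequent class: `digest`, `variant`
#'   (counter within a digest), `k`, `f1_count`, `representative` (list of
#'   node IDs) and `instances` (list of instance tibbles).
#' @export
find_frequent_motifs <- function(instances, graph, t) {
  t <- as.integer(t)
  if (is.na(t) || t < 1) abort("`t` must be an integer >= 1", class = "supernoder_parameter_error")
  empty <- tibble(digest = character(0), variant = integer(0), k = integer(0),
                  f1_count = integer(0), representative = list(), instances = list())
  if (nrow(instances) == 0) return(empty)
  idx <- graph_index(graph)
  members <- lapply(instances$nodes, function(nd) {
    m <- match(nd, idx$ids)
    if (anyNA(m)) abort("instance node(s) not in graph", class = "supernoder_referential_error")
    m
  })
  digests <- vapply(members, function(m) sig_digest_entries(sig_entries(m, idx)), character(1))

  out <- list()
  for (dg in rsort(unique(digests))) {
    rows <- which(digests == dg)
    if (length(rows) < t) next
    rows <- rows[rorder(instances$key[rows])]
    reps <- list()        # representative member vectors
    assign_to <- integer(length(rows))
    for (a in seq_along(rows)) {
      m <- members[[rows[a]]]
      hit <- 0L
      for (r in seq_along(reps)) {
        if (iso_members(m, reps[[r]], idx)) { hit <- r; break }
      }
      if (hit == 0L) {
        reps[[length(reps) + 1L]] <- m
        hit <- length(reps)
      }
      assign_to[a] <- hit
    }
    for (r in seq_along(reps)) {
      cls_rows <- rows[assign_to == r]
      if (length(cls_rows) < t) next
      out[[length(out) + 1L]] <- tibble(
        digest = dg, variant = r, k = length(reps[[r]]),
        f1_count = length(cls_rows),
        representative = list(idx$ids[reps[[r]]]),
        instances = list(instances[cls_rows, ])
      )
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Flat census report
#'
#' @param motifs the class tibble from [find_frequent_motifs()].
#' @return A tibble with one row per class (`digest`, `variant`, `k`,
#'   `f1_count`, `representative` as a space-joined ID string), suitable for
#'   writing as TSV.
#' @export
census_report <- function(motifs) {
  tibble(digest = motifs$digest, variant = motifs$variant, k = motifs$k,
         f1_count = motifs$f1_count,
         representative = vapply(motifs$representative, paste, character(1), collapse = " "))
}
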