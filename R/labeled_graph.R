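#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn inform
NULL

# locale-independent sorting/ordering (C collation via radix)
rsort <- function(x) sort(x, method = "radix")
rorder <- function(...) order(..., method = "radix")

maybe_seed <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}

#' Construct a labeled graph
#'
#' A labeled graph holds a node table (`id`, `label`, `is_supernode`,
#' `members`) and an edge table (`from`, `to`). Node IDs and labels are
#' whitespace-free strings; supernodes produced by [collapse_instances()]
#' carry the IDs of the nodes they replaced in the `members` list column.
#' Undirected edges are stored once under a canonical ordering; duplicate
#' edges are merged and self-loops are rejected.
#'
#' @param nodes data frame with columns `id` and `label` (and optionally
#'   `is_supernode`, `members`).
#' @param edges data frame with columns `from` and `to` (or any two columns,
#'   taken positionally), or `NULL` for an edgeless graph.
#' @param directed logical; treat edges as ordered pairs.
#' @return An object of class `labeled_graph`.
#' @examples
#' g <- labeled_graph(data.frame(id = c("1", "2", "3"), label = c("A", "A", "B")),
#'                    data.frame(from = c("1", "2"), to = c("2", "3")))
#' g
#' @export
labeled_graph <- function(nodes, edges = NULL, directed = FALSE) {
  nodes <- as_tibble(as.data.frame(nodes))
  if (!all(c("id", "label") %in% names(nodes))) {
    abort("`nodes` must have columns `id` and `label`", class = "supernoder_parse_error")
  }
  nodes$id <- as.character(nodes$id)
  nodes$label <- as.character(nodes$label)
  if (is.null(nodes[["members"]])) nodes$members <- replicate(nrow(nodes), character(0), simplify = FALSE)
  nodes$members <- lapply(nodes$members, function(m) if (is.null(m)) character(0) else as.character(m))
  if (is.null(nodes[["is_supernode"]])) nodes$is_supernode <- lengths(nodes$members) > 0L
  nodes$is_supernode <- as.logical(nodes$is_supernode)
  nodes <- nodes[c("id", "label", "is_supernode", "members")]

  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    abort(paste0("duplicate node ID(s): ", paste(dup, collapse = ", ")),
          class = "supernoder_identity_error")
  }
  if (any(grepl("[ \t]", nodes$id)) || any(grepl("[ \t]", nodes$label))) {
    abort("node IDs and labels may not contain whitespace", class = "supernoder_parse_error")
  }
  nodes <- nodes[rorder(nodes$id), ]

  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0) ||
      (!is.data.frame(edges) && length(edges) == 0)) {
    edges <- tibble(from = character(0), to = character(0))
  } else {
    edges <- as_tibble(as.data.frame(edges))
    if (!all(c("from", "to") %in% names(edges))) names(edges)[1:2] <- c("from", "to")
    edges <- tibble(from = as.character(edges$from), to = as.character(edges$to))
  }

  unknown <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(unknown)) {
    abort(paste0("edge endpoint(s) not defined as nodes: ", paste(rsort(unknown), collapse = ", ")),
          class = "supernoder_referential_error")
  }
  if (any(edges$from == edges$to)) {
    abort("self-loops are not allowed", class = "supernoder_selfloop_error")
  }

  # canonicalise + deduplicate using C-locale integer ranks
  u <- nodes$id
  rf <- match(edges$from, u)
  rt <- match(edges$to, u)
  if (!directed) {
    sw <- rf > rt
    tmp <- rf[sw]; rf[sw] <- rt[sw]; rt[sw] <- tmp
  }
  key <- (rf - 1) * length(u) + rt
  keep <- !duplicated(key)
  rf <- rf[keep]; rt <- rt[keep]
  o <- order(rf, rt)
  edges <- tibble(from = u[rf[o]], to = u[rt[o]])

  structure(list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
            class = "labeled_graph")
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("A labeled %s graph: %d nodes (%d supernodes), %d edges\n",
              if (x$directed) "directed" else "undirected",
              nrow(x$nodes), sum(x$nodes$is_supernode), nrow(x$edges)))
  invisible(x)
}

#' Node and edge tables of a labeled graph
#'
#' @param graph a [labeled_graph()].
#' @return A tibble: nodes (`id`, `label`, `is_supernode`, `members`) or
#'   edges (`from`, `to`).
#' @export
graph_nodes <- function(graph) graph$nodes

#' @rdname graph_nodes
#' @export
graph_edges <- function(graph) graph$edges

#' @rdname graph_nodes
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' @rdname graph_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

# Internal indexed view: node IDs in C-locale order, integer adjacency lists.
# `adj` is the undirected skeleton; `out_adj`/`in_adj` only for directed graphs.
graph_index <- function(g) {
  ids <- g$nodes$id
  n <- length(ids)
  ef <- match(g$edges$from, ids)
  et <- match(g$edges$to, ids)
  a <- c(ef, et); b <- c(et, ef)
  key <- (a - 1) * n + b
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  o <- order(a, b)
  adj <- unname(split(b[o], factor(a[o], levels = seq_len(n))))
  res <- list(ids = ids, labels = g$nodes$label, n = n, adj = adj,
              deg = lengths(adj), directed = g$directed)
  if (g$directed) {
    o1 <- order(ef, et)
    res$out_adj <- unname(split(et[o1], factor(ef[o1], levels = seq_len(n))))
    o2 <- order(et, ef)
    res$in_adj <- unname(split(ef[o2], factor(et[o2], levels = seq_len(n))))
  }
  res
}

# instance tibble: one row per connected k-subgraph; `nodes` holds the sorted
# host-node IDs, `key` their space-joined form (the identity of the instance)
new_instances <- function(node_list) {
  tibble(nodes = node_list,
         key = vapply(node_list, paste, character(1), collapse = " "))
}

empty_instances <- function() new_instances(list())

#' Check that a set of instances is pairwise node-disjoint
#'
#' @param instances an instance tibble as returned by
#'   [enumerate_k_subgraphs()] or any selection heuristic.
#' @return `TRUE` iff no host node occurs in more than one instance.
#' @export
is_disjoint <- function(instances) {
  !anyDuplicated(unlist(instances$nodes))
}
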