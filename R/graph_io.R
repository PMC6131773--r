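SUPERNODE_TAG <- "#supernode"

read_lines_arg <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) readLines(x) else as.character(x)
}

#' Read a labeled network from node and edge row lists
#'
#' The network format is two plain-text row lists: node rows `"ID label"`
#' (supernodes carry a trailing `#supernode` tag) and edge rows `"ID ID"`,
#' tokens separated by runs of blanks or tabs. Blank lines are ignored.
#' Supernode member lineage is not part of the primary format; it can be
#' restored from a provenance sidecar (see [write_network_files()]).
#'
#' @param nodes,edges a file path or a character vector of rows.
#' @param directed logical; read edges as ordered pairs.
#' @param provenance optional provenance sidecar (path or rows), each row
#'   `"supernodeID member1 member2 ..."`.
#' @return A [labeled_graph()].
#' @examples
#' g <- read_network(c("1 A", "2 B"), "1 2")
#' @export
read_network <- function(nodes, edges, directed = FALSE, provenance = NULL) {
  node_lines <- read_lines_arg(nodes)
  edge_lines <- read_lines_arg(edges)

  parse_rows <- function(lines) {
    toks <- strsplit(trimws(lines), "[ \t]+")
    keep <- vapply(toks, function(t) length(t) > 0 && any(nzchar(t)), logical(1))
    list(toks = toks[keep], lineno = which(keep))
  }

  np <- parse_rows(node_lines)
  bad <- which(!vapply(np$toks, function(t) {
    length(t) == 2 || (length(t) == 3 && t[3] == SUPERNODE_TAG)
  }, logical(1)))
  if (length(bad)) {
    abort(sprintf("malformed node row at line %d: expected 'ID label' or 'ID label %s'",
                  np$lineno[bad[1]], SUPERNODE_TAG),
          class = "supernoder_parse_error")
  }
  ntab <- tibble(
    id = vapply(np$toks, `[`, character(1), 1),
    label = vapply(np$toks, `[`, character(1), 2),
    is_supernode = lengths(np$toks) == 3L
  )

  ep <- parse_rows(edge_lines)
  bad <- which(lengths(ep$toks) != 2L)
  if (length(bad)) {
    abort(sprintf("malformed edge row at line %d: expected exactly two node IDs",
                  ep$lineno[bad[1]]),
          class = "supernoder_parse_error")
  }
  etab <- tibble(
    from = vapply(ep$toks, `[`, character(1), 1),
    to = vapply(ep$toks, `[`, character(1), 2)
  )

  # duplicate edges are tolerated but reported once
  ekey <- if (directed) paste(etab$from, etab$to) else {
    paste(pmin(etab$from, etab$to), pmax(etab$from, etab$to))
  }
  ndup <- sum(duplicated(ekey))
  if (ndup > 0) warn(sprintf("deduplicated %d duplicate edge row(s)", ndup))

  g <- labeled_graph(ntab, etab, directed = directed)
  if (!is.null(provenance)) g <- apply_provenance(g, provenance)
  g
}

apply_provenance <- function(graph, provenance) {
  lines <- read_lines_arg(provenance)
  toks <- strsplit(trimws(lines), "[ \t]+")
  toks <- toks[lengths(toks) >= 2]
  for (t in toks) {
    i <- match(t[1], graph$nodes$id)
    if (is.na(i)) {
      abort(paste0("provenance refers to unknown node: ", t[1]),
            class = "supernoder_referential_error")
    }
    if (!graph$nodes$is_supernode[i]) {
      abort(paste0("provenance refers to a non-supernode: ", t[1]),
            class = "supernoder_referential_error")
    }
    graph$nodes$members[[i]] <- t[-1]
  }
  graph
}

#' Serialize a labeled network to node and edge rows
#'
#' Rows are sorted by ID so the output is byte-stable: writing, re-reading
#' and writing again yields identical rows.
#'
#' @param graph a [labeled_graph()].
#' @return A list with character vectors `node_rows`, `edge_rows` and
#'   `provenance_rows` (one row per supernode with recorded members).
#' @export
write_network <- function(graph) {
  nd <- graph$nodes
  node_rows <- ifelse(nd$is_supernode,
                      paste(nd$id, nd$label, SUPERNODE_TAG),
                      paste(nd$id, nd$label))
  edge_rows <- if (nrow(graph$edges)) paste(graph$edges$from, graph$edges$to) else character(0)
  has_members <- nd$is_supernode & lengths(nd$members) > 0
  prov <- vapply(which(has_members), function(i) {
    paste(c(nd$id[i], nd$members[[i]]), collapse = " ")
  }, character(1))
  list(node_rows = as.character(node_rows), edge_rows = edge_rows,
       provenance_rows = prov)
}

#' @rdname write_network
#' @param node_path,edge_path,provenance_path output file paths; the
#'   provenance sidecar is written only when a path is given.
#' @export
write_network_files <- function(graph, node_path, edge_path, provenance_path = NULL) {
  rows <- write_network(graph)
  writeLines(rows$node_rows, node_path)
  writeLines(rows$edge_rows, edge_path)
  if (!is.null(provenance_path)) writeLines(rows$provenance_rows, provenance_path)
  invisible(rows)
}

#' Label hierarchies
#'
#' A label hierarchy maps each base label to an ordered ancestor chain
#' (position 1 = the base label itself, later positions coarser), emulating
#' Gene Ontology or taxonomic level tables. The file format is TSV: first
#' column the base label, subsequent columns its ancestors from fine to
#' coarse; chains may have different lengths.
#'
#' @param x a file path or character vector of TSV rows.
#' @return A named list of character chains.
#' @export
read_hierarchy <- function(x) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines))]
  chains <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(chains) < 1) || any(!nzchar(vapply(chains, `[`, character(1), 1)))) {
    abort("every hierarchy row needs at least a base label", class = "supernoder_parse_error")
  }
  stats::setNames(chains, vapply(chains, `[`, character(1), 1))
}

#' @rdname read_hierarchy
#' @param hierarchy a named list of ancestor chains.
#' @param path output file path.
#' @export
write_hierarchy <- function(hierarchy, path) {
  writeLines(vapply(hierarchy, paste, character(1), collapse = "\t"), path)
  invisible(hierarchy)
}

#' Remap node labels to a coarser hierarchy level
#'
#' Replaces each node label by the entry at position
#' `min(level, chain length - 1)` of its ancestor chain (level 0 = the base
#' label). Topology and node IDs are untouched, so motif discovery can be
#' repeated at increasing abstraction; coarser labels can only merge
#' isomorphism classes, never split them.
#'
#' @param graph a [labeled_graph()].
#' @param hierarchy a named list of ancestor chains (see [read_hierarchy()]).
#' @param level non-negative integer hierarchy level.
#' @param missing what to do with labels absent from the hierarchy:
#'   `"error"` (default) or `"keep"` the original label.
#' @return A [labeled_graph()] with remapped labels.
#' @export
map_labels <- function(graph, hierarchy, level, missing = c("error", "keep")) {
  missing <- match.arg(missing)
  level <- as.integer(level)
  if (is.na(level) || level < 0) abort("`level` must be a non-negative integer",
                                       class = "supernoder_parameter_error")
  labs <- graph$nodes$label
  pos <- match(labs, names(hierarchy))
  if (anyNA(pos) && missing == "error") {
    absent <- rsort(unique(labs[is.na(pos)]))
    abort(paste0("label(s) missing from hierarchy: ", paste(absent, collapse = ", ")),
          class = "supernoder_hierarchy_error")
  }
  new_labs <- labs
  hit <- which(!is.na(pos))
  new_labs[hit] <- vapply(pos[hit], function(p) {
    chain <- hierarchy[[p]]
    chain[[min(level, length(chain) - 1L) + 1L]]
  }, character(1))
  nd <- graph$nodes
  nd$label <- new_labs
  labeled_graph(nd, graph$edges, directed = graph$directed)
}
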