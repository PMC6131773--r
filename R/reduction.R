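#' Collapse disjoint motif instances into supernodes
#'
#' Each selected instance is replaced by one fresh supernode labelled with
#' the alphabetical concatenation of its members' labels (joined by `"-"`).
#' External connections are preserved: an edge from an outside node to any
#' member becomes an edge to the supernode, and an edge between members of
#' two different selected instances becomes an edge between their
#' supernodes. Internal instance edges disappear, parallel resulting edges
#' are merged, no self-loops are created, and untouched nodes and edges are
#' unchanged. Collapsing a size-k instance removes k-1 nodes.
#'
#' @param graph the host [labeled_graph()].
#' @param selected an instance tibble of pairwise node-disjoint instances.
#' @param iteration integer used in the supernode ID scheme
#'   `"SN<iteration>_<counter>"`.
#' @return The reduced [labeled_graph()].
#' @export
collapse_instances <- function(graph, selected, iteration = 1L) {
  if (nrow(selected) == 0) return(graph)
  if (!is_disjoint(selected)) {
    abort("selected instances overlap; collapse requires pairwise node-disjoint instances",
          class = "supernoder_contract_error")
  }
  members_all <- unlist(selected$nodes)
  if (!all(members_all %in% graph$nodes$id)) {
    abort("selected instance node(s) not in graph", class = "supernoder_referential_error")
  }
  sel <- selected[rorder(selected$key), ]
  sn_ids <- character(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    cand <- sprintf("SN%d_%d", as.integer(iteration), i)
    while (cand %in% graph$nodes$id) cand <- paste0(cand, "x")
    sn_ids[i] <- cand
  }

  nd <- graph$nodes
  lab_of <- stats::setNames(nd$label, nd$id)
  remap <- stats::setNames(rep(sn_ids, lengths(sel$nodes)), unlist(sel$nodes))

  sn_rows <- tibble(
    id = sn_ids,
    label = vapply(sel$nodes, function(m) paste(rsort(lab_of[m]), collapse = "-"), character(1)),
    is_supernode = TRUE,
    members = lapply(sel$nodes, rsort)
  )
  keep <- !(nd$id %in% names(remap))
  new_nodes <- dplyr::bind_rows(nd[keep, ], sn_rows)

  ed <- graph$edges
  f <- ifelse(ed$from %in% names(remap), remap[ed$from], ed$from)
  t2 <- ifelse(ed$to %in% names(remap), remap[ed$to], ed$to)
  live <- f != t2
  labeled_graph(new_nodes, tibble(from = f[live], to = t2[live]), directed = graph$directed)
}

#' Run the recursive supernode-extraction pipeline
#'
#' Per iteration: enumerate connected k-subgraphs, bucket them into frequent
#' motif classes at threshold `t` (F1 counting), select a large pairwise
#' node-disjoint subset with the chosen heuristic, and collapse it into
#' supernodes. The loop stops early with a notice when no class reaches the
#' threshold or the selection is empty — after a few iterations networks
#' typically stop shrinking.
#'
#' @param graph the input [labeled_graph()].
#' @param k motif size (>= 3).
#' @param t frequency threshold (>= 1); a class is frequent when its F1
#'   count is `>= t`.
#' @param heuristic one of `"h1"` .. `"h5"` (see [selection_heuristics]).
#' @param iterations maximum number of reduction rounds.
#' @param seed optional integer seed covering all randomness in the run.
#' @param n_shuffles,sample_size heuristic parameters.
#' @param sampling_probs per-depth enumeration probabilities (default 1 =
#'   exhaustive; the census presumes the full F1 count).
#' @param per_class if `TRUE`, selection runs class by class (in digest
#'   order, later classes restricted to still-unused nodes) instead of on
#'   the pooled frequent motif set.
#' @param verbose log per-stage timings.
#' @return An object of class `supernoder_reduction`: the initial graph, the
#'   graph after each executed iteration, and a per-iteration report tibble
#'   (`iteration`, `n_classes`, `n_frequent_instances`, `n_selected`,
#'   `n_nodes`, `n_edges`; iteration 0 records the input sizes).
#' @examples
#' fx <- generate_planted_network(seed = 7)
#' res <- run_pipeline(fx$graph, k = 3, t = 6, heuristic = "h1", seed = 1)
#' tidy(res)
#' @export
run_pipeline <- function(graph, k, t, heuristic = c("h1", "h2", "h3", "h4", "h5"),
                         iterations = 1, seed = NULL, n_shuffles = 5,
                         sample_size = 1000, sampling_probs = 1,
                         per_class = FALSE, verbose = FALSE) {
  heuristic <- match.arg(heuristic)
  k <- as.integer(k); t <- as.integer(t); iterations <- as.integer(iterations)
  if (is.na(k) || k < 3) abort("`k` must be >= 3", class = "supernoder_parameter_error")
  if (is.na(t) || t < 1) abort("`t` must be >= 1", class = "supernoder_parameter_error")
  if (is.na(iterations) || iterations < 1) abort("`iterations` must be >= 1",
                                                 class = "supernoder_parameter_error")
  say <- function(...) if (verbose) inform(sprintf(...))
  timed <- function(what, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    say("  %s: %.2fs", what, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  run <- function() {
    graphs <- list()
    rows <- list(tibble(iteration = 0L, n_classes = NA_integer_,
                        n_frequent_instances = NA_integer_, n_selected = NA_integer_,
                        n_nodes = n_nodes(graph), n_edges = n_edges(graph)))
    cur <- graph
    for (it in seq_len(iterations)) {
      say("iteration %d (%d nodes, %d edges)", it, n_nodes(cur), n_edges(cur))
      inst <- timed("enumeration", enumerate_k_subgraphs(cur, k, sampling_probs))
      classes <- timed("census", find_frequent_motifs(inst, cur, t))
      if (nrow(classes) == 0) {
        inform(sprintf("iteration %d: no frequent motif class at t=%d; stopping", it, t))
        break
      }
      sel <- timed("selection", {
        if (!per_class) {
          cand <- dplyr::bind_rows(classes$instances)
          cand <- cand[rorder(cand$key), ]
          select_disjoint(cand, cur, heuristic, seed = NULL,
                          n_shuffles = n_shuffles, sample_size = sample_size)
        } else {
          used <- character(0)
          picks <- list()
          for (ci in seq_len(nrow(classes))) {
            cnd <- classes$instances[[ci]]
            free <- !vapply(cnd$nodes, function(nd) any(nd %in% used), logical(1))
            cnd <- cnd[free, ]
            if (nrow(cnd) == 0) next
            s <- select_disjoint(cnd, cur, heuristic, seed = NULL,
                                 n_shuffles = n_shuffles, sample_size = sample_size)
            picks[[length(picks) + 1L]] <- s
            used <- c(used, unlist(s$nodes))
          }
          if (length(picks)) {
            out <- dplyr::bind_rows(picks)
            out[rorder(out$key), ]
          } else empty_instances()
        }
      })
      if (nrow(sel) == 0) {
        inform(sprintf("iteration %d: empty disjoint selection; stopping", it))
        break
      }
      cur <- timed("collapse", collapse_instances(cur, sel, iteration = it))
      graphs[[it]] <- cur
      rows[[length(rows) + 1L]] <- tibble(
        iteration = it, n_classes = nrow(classes),
        n_frequent_instances = sum(classes$f1_count),
        n_selected = nrow(sel),
        n_nodes = n_nodes(cur), n_edges = n_edges(cur))
    }
    list(graphs = graphs, report = dplyr::bind_rows(rows))
  }
  res <- maybe_seed(seed, run)
  structure(list(initial = graph, graphs = res$graphs, report = res$report,
                 params = list(k = k, t = t, heuristic = heuristic,
                               iterations = iterations, seed = seed,
                               n_shuffles = n_shuffles, sample_size = sample_size,
                               per_class = per_class)),
            class = "supernoder_reduction")
}

#' @export
print.supernoder_reduction <- function(x, ...) {
  p <- x$params
  cat(sprintf("Recursive supernode extraction: k=%d, t=%d, heuristic=%s\n",
              p$k, p$t, p$heuristic))
  cat(sprintf("%d iteration(s) executed; %d -> %d nodes, %d -> %d edges\n",
              length(x$graphs), n_nodes(x$initial),
              if (length(x$graphs)) n_nodes(x$graphs[[length(x$graphs)]]) else n_nodes(x$initial),
              n_edges(x$initial),
              if (length(x$graphs)) n_edges(x$graphs[[length(x$graphs)]]) else n_edges(x$initial)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-iteration reduction report
#'
#' @param x a `supernoder_reduction` object.
#' @param ... unused.
#' @return The report tibble (iteration 0 = input sizes).
#' @export
tidy.supernoder_reduction <- function(x, ...) x$report

#' One-row summary of a reduction run
#'
#' @param x a `supernoder_reduction` object.
#' @param ... unused.
#' @return A one-row tibble: iterations executed, initial/final node and
#'   edge counts, total instances collapsed and the node reduction fraction.
#' @export
glance.supernoder_reduction <- function(x, ...) {
  fin <- if (length(x$graphs)) x$graphs[[length(x$graphs)]] else x$initial
  tibble(iterations = length(x$graphs),
         initial_nodes = n_nodes(x$initial), final_nodes = n_nodes(fin),
         initial_edges = n_edges(x$initial), final_edges = n_edges(fin),
         total_selected = sum(x$report$n_selected, na.rm = TRUE),
         node_reduction = 1 - n_nodes(fin) / n_nodes(x$initial))
}

#' Plot the reduction trajectory
#'
#' Node and edge counts against the iteration index.
#'
#' @param object a `supernoder_reduction` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.supernoder_reduction <- function(object, ...) {
  rp <- object$report
  df <- dplyr::bind_rows(
    tibble(iteration = rp$iteration, count = rp$n_nodes, quantity = "nodes"),
    tibble(iteration = rp$iteration, count = rp$n_edges, quantity = "edges")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$count,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "count", colour = NULL,
                  title = "Network size under recursive supernode extraction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write per-iteration pipeline outputs
#'
#' Writes, for each executed iteration `i`, `nodes_<i>.txt` and
#' `edges_<i>.txt` in the two-list network format, a provenance sidecar
#' `provenance_<i>.txt` (one row per supernode: its ID then its member IDs),
#' plus the report as `report.tsv`.
#'
#' @param x a `supernoder_reduction` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reduction <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(x$graphs)) {
    write_network_files(x$graphs[[i]],
                        file.path(dir, sprintf("nodes_%d.txt", i)),
                        file.path(dir, sprintf("edges_%d.txt", i)),
                        file.path(dir, sprintf("provenance_%d.txt", i)))
  }
  utils::write.table(x$report, file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
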