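#' Enumerate connected k-node subgraph instances
#'
#' Enumerates every connected k-node subgraph of the host graph exactly once
#' using the ESU enumeration tree, or an unbiased random subset of it when
#' per-depth sampling probabilities below 1 are supplied (RAND-ESU): the
#' recursion at depth d proceeds with probability `sampling_probs[d]`, so
#' the expected number of instances returned is the exhaustive count times
#' the product of the probabilities. Connectivity is judged on the
#' undirected skeleton; for directed graphs edge directions still matter in
#' the census stage.
#'
#' @param graph a [labeled_graph()].
#' @param k motif size, at least 3.
#' @param sampling_probs per-depth success probabilities in (0, 1]; a scalar
#'   is recycled. All 1 (the default) gives exact enumeration.
#' @param seed optional integer seed for the sampled mode.
#' @return An instance tibble with columns `nodes` (list of sorted host-node
#'   IDs) and `key` (their space-joined form).
#' @examples
#' g <- read_network(c("a X", "b X", "c Y", "d Y"), c("a b", "b c", "c d"))
#' enumerate_k_subgraphs(g, 3)
#' @export
enumerate_k_subgraphs <- function(graph, k, sampling_probs = 1, seed = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 3) abort("`k` must be an integer >= 3", class = "supernoder_parameter_error")
  probs <- rep_len(as.numeric(sampling_probs), k)
  if (any(is.na(probs)) || any(probs <= 0) || any(probs > 1)) {
    abort("`sampling_probs` must lie in (0, 1]", class = "supernoder_parameter_error")
  }
  idx <- graph_index(graph)
  if (idx$n == 0) abort("`graph` has no nodes", class = "supernoder_parameter_error")
  if (k > idx$n) return(empty_instances())
  random <- any(probs < 1)
  sets <- maybe_seed(seed, function() esu_enumerate(idx$adj, idx$n, k, probs, random))
  new_instances(lapply(sets, function(v) idx$ids[v]))
}

# ESU over integer node indices 1..n (the C-locale order of the IDs).
# Returns a list of sorted integer vectors.
esu_enumerate <- function(adj, n, k, probs, random) {
  acc <- new.env(parent = emptyenv())
  acc$res <- vector("list", 256L)
  acc$i <- 0L
  push <- function(v) {
    i <- acc$i + 1L
    if (i > length(acc$res)) acc$res <- c(acc$res, vector("list", length(acc$res)))
    acc$res[[i]] <- v
    acc$i <- i
  }

  extend <- function(sub, ext, v, blocked) {
    depth <- length(sub) + 1L
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      if (random && stats::runif(1) > probs[depth]) next
      if (depth == k) {
        push(sort.int(c(sub, w)))
      } else {
        nb <- adj[[w]]
        add <- nb[nb > v & !blocked[nb]]
        blocked2 <- blocked
        blocked2[add] <- TRUE
        extend(c(sub, w), c(ext, add), v, blocked2)
      }
    }
  }

  for (v in seq_len(n)) {
    if (random && stats::runif(1) > probs[1L]) next
    nb <- adj[[v]]
    ext <- nb[nb > v]
    blocked <- logical(n)
    blocked[v] <- TRUE
    blocked[nb] <- TRUE
    extend(v, ext, v, blocked)
  }
  acc$res[seq_len(acc$i)]
}
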