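#' Generate a synthetic labeled network with planted motifs
#'
#' Builds an Erdős–Rényi background with random labels, plants
#' `n_planted` pairwise node-disjoint copies of a labeled motif shape, and
#' sparsely attaches each planted node to the background. Defaults emulate
#' the benchmark used throughout the package's tests: six disjoint (A,A,B)
#' triangles on a sparse 60-node background whose fifteen-letter label alphabet
#' is disjoint from the slot labels, so the planted class has exactly six
#' F1 instances and background subgraphs are spread over so many label
#' combinations that no background class reaches that frequency.
#'
#' With `ensure_no_extra = TRUE` the generator verifies by exhaustive
#' enumeration that attachments created no unintended copy of the planted
#' class and resamples the attachments otherwise, so "planted count = true
#' F1 count" fixtures are constructible.
#'
#' @param n_planted number of disjoint motif copies to plant.
#' @param motif_edges two-column matrix/data frame of slot indices (1..k)
#'   giving the motif shape; must be connected. Default: a triangle.
#' @param slot_labels labels of the k slots. Default `c("A", "A", "B")`.
#' @param n_background number of background nodes.
#' @param background_edge_prob Erdős–Rényi edge probability of the background.
#' @param attach_prob probability of an edge from each planted node to one
#'   random background node.
#' @param label_alphabet labels for background nodes.
#' @param directed build a directed graph (edges oriented as given /
#'   low-to-high at random for background).
#' @param seed integer seed; the same seed gives a byte-identical network.
#' @param ensure_no_extra verify that the planted class has exactly
#'   `n_planted` instances, resampling attachments if not.
#' @param max_tries attachment resampling attempts before giving up.
#' @return A list with `graph` (a [labeled_graph()]) and `planted` (the
#'   ground-truth instance tibble).
#' @export
generate_planted_network <- function(n_planted = 6,
                                     motif_edges = cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)),
                                     slot_labels = c("A", "A", "B"),
                                     n_background = 60,
                                     background_edge_prob = 0.01,
                                     attach_prob = 0.05,
                                     label_alphabet = LETTERS[3:17],
                                     directed = FALSE,
                                     seed = NULL,
                                     ensure_no_extra = TRUE,
                                     max_tries = 25) {
  k <- length(slot_labels)
  me <- as.matrix(motif_edges)
  storage.mode(me) <- "integer"
  if (ncol(me) != 2 || any(is.na(me)) || any(me < 1) || any(me > k)) {
    abort("`motif_edges` must be a two-column matrix of slot indices in 1..k",
          class = "supernoder_parameter_error")
  }
  if (k >= 3 && !slots_connected(me, k)) {
    abort("the motif shape must be connected", class = "supernoder_parameter_error")
  }
  if (n_planted < 0 || n_background < 0) {
    abort("counts must be non-negative", class = "supernoder_parameter_error")
  }
  if (n_background == 0 && n_planted == 0) {
    abort("the network would be empty", class = "supernoder_parameter_error")
  }

  run <- function() {
    bg_ids <- if (n_background > 0) sprintf("b%03d", seq_len(n_background)) else character(0)
    bg_labels <- if (n_background > 0) sample(label_alphabet, n_background, replace = TRUE) else character(0)
    bg_edges <- NULL
    if (n_background > 1) {
      pr <- which(upper.tri(matrix(0, n_background, n_background)), arr.ind = TRUE)
      hit <- stats::runif(nrow(pr)) < background_edge_prob
      bg_edges <- tibble(from = bg_ids[pr[hit, 1]], to = bg_ids[pr[hit, 2]])
    }

    pl_ids <- character(0); pl_labels <- character(0); pl_edges <- NULL
    truth <- list()
    for (cp in seq_len(n_planted)) {
      ids <- sprintf("p%02d_%d", cp, seq_len(k))
      pl_ids <- c(pl_ids, ids)
      pl_labels <- c(pl_labels, slot_labels)
      pl_edges <- rbind(pl_edges, data.frame(from = ids[me[, 1]], to = ids[me[, 2]]))
      truth[[cp]] <- rsort(ids)
    }

    nodes <- tibble(id = c(bg_ids, pl_ids), label = c(bg_labels, pl_labels))

    sample_attachments <- function() {
      if (n_background == 0 || attach_prob <= 0 || length(pl_ids) == 0) return(NULL)
      hit <- stats::runif(length(pl_ids)) < attach_prob
      if (!any(hit)) return(NULL)
      tibble(from = pl_ids[hit],
             to = bg_ids[sample.int(n_background, sum(hit), replace = TRUE)])
    }

    build <- function(att) {
      labeled_graph(nodes, dplyr::bind_rows(as.data.frame(bg_edges),
                                            as.data.frame(pl_edges),
                                            as.data.frame(att)),
                    directed = directed)
    }

    att <- sample_attachments()
    g <- build(att)
    if (ensure_no_extra && n_planted > 0 && k >= 3) {
      for (try in seq_len(max_tries)) {
        inst <- enumerate_k_subgraphs(g, k)
        idx <- graph_index(g)
        rep_m <- match(truth[[1]], idx$ids)
        n_copies <- sum(vapply(inst$nodes, function(nd) {
          iso_members(match(nd, idx$ids), rep_m, idx)
        }, logical(1)))
        if (n_copies == n_planted) break
        if (try == max_tries) {
          abort("could not build a fixture without extra motif copies; background labels may collide with slot labels",
                class = "supernoder_fixture_error")
        }
        att <- sample_attachments()
        g <- build(att)
      }
    }
    list(graph = g, planted = new_instances(truth))
  }
  maybe_seed(seed, run)
}

slots_connected <- function(me, k) {
  seen <- logical(k)
  seen[1] <- TRUE
  repeat {
    grow <- FALSE
    for (r in seq_len(nrow(me))) {
      a <- me[r, 1]; b <- me[r, 2]
      if (seen[a] != seen[b]) { seen[a] <- seen[b] <- TRUE; grow <- TRUE }
    }
    if (!grow) break
  }
  all(seen)
}

#' Generate a random balanced label hierarchy
#'
#' Builds ancestor chains of length `depth` for each base label by growing a
#' balanced tree with branching factor `fanout` from a single root: level
#' `l` (0 = base, `depth - 1` = coarsest) has `min(n, fanout^(depth-1-l))`
#' categories named `H<l>_<index>`, and labels are assigned to leaves in a
#' random but balanced way. For any `depth >= 2` the coarsest level is a
#' single shared root.
#'
#' @param label_alphabet base labels.
#' @param depth chain length (>= 1); `depth = 1` means each chain is just
#'   the base label.
#' @param fanout branching factor of the ancestor tree.
#' @param seed integer seed.
#' @return A named list of ancestor chains (see [read_hierarchy()]).
#' @export
generate_hierarchy <- function(label_alphabet, depth = 3, fanout = 2, seed = NULL) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1) abort("`depth` must be >= 1", class = "supernoder_parameter_error")
  if (fanout < 1) abort("`fanout` must be >= 1", class = "supernoder_parameter_error")
  labs <- as.character(label_alphabet)
  run <- function() {
    n <- length(labs)
    if (depth == 1) return(stats::setNames(lapply(labs, identity), labs))
    n_leaf_groups <- fanout^(depth - 1L)
    ord <- sample.int(n)
    leaf_of <- integer(n)
    leaf_of[ord] <- (seq_len(n) - 1L) %% n_leaf_groups   # balanced random assignment
    chains <- lapply(seq_len(n), function(i) {
      chain <- labs[i]
      for (l in seq_len(depth - 1L)) {
        anc <- leaf_of[i] %/% fanout^l
        chain <- c(chain, sprintf("H%d_%02d", l, anc))
      }
      chain
    })
    stats::setNames(chains, labs)
  }
  maybe_seed(seed, run)
}
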