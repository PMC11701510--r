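#' Time-respecting shortest path over a cluster network
#'
#' A Dijkstra variant in which an edge may only be traversed toward a node
#' whose mean Timer Angle strictly exceeds that of the current node, so
#' every returned trajectory respects Timer time. Distances are initialised
#' to zero at the source and infinity elsewhere; at each step the unvisited
#' node with the smallest tentative distance is settled and its neighbours
#' are relaxed only when the angle constraint holds. Because the constraint
#' orients every usable edge by angle, the searched graph is acyclic and
#' the usual nonnegative-weight optimality argument applies. Among
#' equal-cost optima the lexicographically smallest node-id sequence is
#' returned, which makes the output deterministic.
#'
#' @param network A `tocky_network` from [build_network()].
#' @param source,destination Cluster ids present in the network.
#' @param epsilon Non-negative slack on the angle comparison: traversal
#'   from `u` to `v` is allowed when `angle(v) - angle(u) > -epsilon`. The
#'   default 0 gives the strict "destination exceeds origin" rule; a tiny
#'   positive value tolerates numerically equal means (and, if large, can
#'   reintroduce cycles — use with care).
#' @return Object of class `tocky_path`: list with `node_sequence` (empty
#'   when unreachable), `total_cost`, `reachable`, `angles` (mean Timer
#'   Angle along the path), `source`, `destination`.
#' @examples
#' nodes <- tibble::tibble(cluster = 1:3, CCA1 = c(0, 1, 3), CCA2 = 0,
#'                         mean_angle = c(10, 20, 30), mean_intensity = 1,
#'                         n_cells = 10)
#' net <- build_network(nodes)
#' dijkstra_tocky(net, 1, 3)
#' @export
dijkstra_tocky <- function(network, source, destination, epsilon = 0) {
  stopifnot(inherits(network, "tocky_network"), epsilon >= 0)
  ids <- network$nodes$cluster
  if (!source %in% ids) stop("Unknown source node: ", source, call. = FALSE)
  if (!destination %in% ids) {
    stop("Unknown destination node: ", destination, call. = FALSE)
  }
  sol <- dijkstra_all(network, source, epsilon)
  i <- match(destination, ids)
  if (!is.finite(sol$dist[i])) {
    return(structure(
      list(node_sequence = ids[0], total_cost = Inf, reachable = FALSE,
           angles = numeric(0), source = source, destination = destination),
      class = "tocky_path"
    ))
  }
  seq_ids <- sol$paths[[i]]
  structure(
    list(node_sequence = seq_ids,
         total_cost = sol$dist[i],
         reachable = TRUE,
         angles = network$nodes$mean_angle[match(seq_ids, ids)],
         source = source, destination = destination),
    class = "tocky_path"
  )
}

#' Shortest angle-increasing paths from one source to all nodes
#'
#' One-to-all variant of [dijkstra_tocky()]; convenient for choosing
#' destinations and for deriving several trajectories from a common origin.
#'
#' @inheritParams dijkstra_tocky
#' @return Tibble with one row per node: `cluster`, `reachable`,
#'   `total_cost` and `path` (list-column of node-id vectors).
#' @export
shortest_path_tree <- function(network, source, epsilon = 0) {
  stopifnot(inherits(network, "tocky_network"))
  ids <- network$nodes$cluster
  if (!source %in% ids) stop("Unknown source node: ", source, call. = FALSE)
  sol <- dijkstra_all(network, source, epsilon)
  tibble::tibble(
    cluster = ids,
    reachable = is.finite(sol$dist),
    total_cost = sol$dist,
    path = sol$paths
  )
}

# Core angle-constrained Dijkstra. Returns dist and lexicographically
# smallest shortest path per node (paths as vectors of cluster ids).
dijkstra_all <- function(network, source, epsilon) {
  ids <- network$nodes$cluster
  ang <- network$nodes$mean_angle
  m <- length(ids)
  adj <- vector("list", m)
  e <- network$edges
  for (r in seq_len(nrow(e))) {
    i <- match(e$from[r], ids)
    j <- match(e$to[r], ids)
    w <- e$weight[r]
    if (ang[j] - ang[i] > -epsilon && (epsilon > 0 || ang[j] > ang[i])) {
      adj[[i]] <- rbind(adj[[i]], c(j, w))
    }
    if (ang[i] - ang[j] > -epsilon && (epsilon > 0 || ang[i] > ang[j])) {
      adj[[j]] <- rbind(adj[[j]], c(i, w))
    }
  }
  dist <- rep(Inf, m)
  paths <- rep(list(NULL), m)
  s <- match(source, ids)
  dist[s] <- 0
  paths[[s]] <- ids[s]
  visited <- logical(m)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    ties <- cand[dist[cand] == dist[u]]
    if (length(ties) > 1) {
      # settle the tie whose path is lexicographically smallest
      u <- ties[[lex_min_index(paths[ties])]]
    }
    visited[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        nd <- dist[u] + nb[r, 2]
        np <- c(paths[[u]], ids[v])
        if (nd < dist[v] ||
            (nd == dist[v] && lex_less(np, paths[[v]]))) {
          dist[v] <- nd
          paths[[v]] <- np
        }
      }
    }
  }
  list(dist = dist, paths = paths)
}

# TRUE when sequence a precedes sequence b lexicographically
lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

lex_min_index <- function(path_list) {
  best <- 1L
  for (i in seq_along(path_list)[-1]) {
    if (lex_less(path_list[[i]], path_list[[best]])) best <- i
  }
  best
}

#' @export
print.tocky_path <- function(x, ...) {
  if (!x$reachable) {
    cat("<tocky_path> ", x$source, " -> ", x$destination,
        ": unreachable under the Timer Angle constraint\n", sep = "")
  } else {
    cat("<tocky_path> ", paste(x$node_sequence, collapse = " -> "),
        "  (cost ", format(x$total_cost, digits = 4), ")\n", sep = "")
  }
  invisible(x)
}

#' Path as a tibble
#' @param x A `tocky_path`.
#' @param ... Unused.
#' @return Tibble: `ordinal`, `cluster`, `mean_angle`.
#' @method tidy tocky_path
#' @export
tidy.tocky_path <- function(x, ...) {
  tibble::tibble(
    ordinal = seq_along(x$node_sequence),
    cluster = x$node_sequence,
    mean_angle = x$angles
  )
}

#' Trim overlapping trajectories to their novel segments
#'
#' Given an ordered list of trajectories sharing early segments (as when
#' several destinations are reached from one origin), each later path is
#' truncated at its last node shared with any earlier path; that shared
#' node becomes its source and the cost is recomputed over the remaining
#' edges. This reproduces the convention of omitting already-reported
#' segments from subsequent trajectories.
#'
#' @param paths List of `tocky_path` objects, in reporting order.
#' @param network The `tocky_network` the paths were found on (for edge
#'   weights when recomputing costs).
#' @return List of `tocky_path` objects of the same length.
#' @export
trim_overlapping_paths <- function(paths, network) {
  stopifnot(length(paths) >= 1,
            all(vapply(paths, inherits, logical(1), "tocky_path")))
  seen <- character(0)
  out <- paths
  wt <- function(a, b) {
    e <- network$edges
    hit <- (e$from == a & e$to == b) | (e$from == b & e$to == a)
    e$weight[hit][1]
  }
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!p$reachable || i == 1) {
      seen <- union(seen, as.character(p$node_sequence))
      next
    }
    shared <- which(as.character(p$node_sequence) %in% seen)
    if (length(shared)) {
      cut <- max(shared)
      keep <- seq(cut, length(p$node_sequence))
      p$node_sequence <- p$node_sequence[keep]
      p$angles <- p$angles[keep]
      p$source <- p$node_sequence[1]
      p$total_cost <- if (length(keep) > 1) {
        sum(purrr::map2_dbl(p$node_sequence[-length(p$node_sequence)],
                            p$node_sequence[-1], wt))
      } else 0
      out[[i]] <- p
    }
    seen <- union(seen, as.character(p$node_sequence))
  }
  out
}
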