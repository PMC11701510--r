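# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (enumeration, normal equations, reference
# formulas) so agreement is informative.

# Exhaustive minimum over all simple paths whose node angles strictly
# increase; returns list(cost, reachable). Operates on a tocky_network.
brute_force_tocky_path <- function(network, source, destination) {
  ids <- network$nodes$cluster
  ang <- network$nodes$mean_angle
  e <- network$edges
  wt <- matrix(NA_real_, length(ids), length(ids))
  for (r in seq_len(nrow(e))) {
    i <- match(e$from[r], ids)
    j <- match(e$to[r], ids)
    wt[i, j] <- wt[j, i] <- e$weight[r]
  }
  s <- match(source, ids)
  d <- match(destination, ids)
  best <- Inf
  recurse <- function(u, visited, cost) {
    if (u == d) {
      best <<- min(best, cost)
      return()
    }
    for (v in seq_along(ids)) {
      if (!visited[v] && !is.na(wt[u, v]) && ang[v] > ang[u]) {
        visited[v] <- TRUE
        recurse(v, visited, cost + wt[u, v])
        visited[v] <- FALSE
      }
    }
  }
  vis <- logical(length(ids))
  vis[s] <- TRUE
  if (s == d) return(list(cost = 0, reachable = TRUE))
  recurse(s, vis, 0)
  list(cost = best, reachable = is.finite(best))
}

# Smallest distance threshold connecting all points, by scanning the sorted
# distinct pairwise distances and flood-filling.
brute_force_connecting_threshold <- function(xy) {
  D <- as.matrix(dist(xy))
  cand <- sort(unique(D[upper.tri(D)]))
  for (thr in cand) {
    adj <- D <= thr
    seen <- logical(nrow(adj))
    seen[1] <- TRUE
    repeat {
      nxt <- which(!seen & colSums(adj[seen, , drop = FALSE]) > 0)
      if (!length(nxt)) break
      seen[nxt] <- TRUE
    }
    if (all(seen)) return(thr)
  }
  stop("unreachable")
}

# Column-wise ordinary least squares fitted values of S on Z, via lm().
ols_fitted_oracle <- function(S, Z) {
  apply(S, 2, function(y) unname(fitted(lm(y ~ 0 + Z[, 1] + Z[, 2]))))
}

# Benjamini-Hochberg step-up, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Random small network with random angles and centroid positions.
random_network <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- tibble::tibble(
    cluster = seq_len(n_nodes),
    CCA1 = runif(n_nodes, -2, 2),
    CCA2 = runif(n_nodes, -2, 2),
    mean_angle = runif(n_nodes, 0, 90),
    mean_intensity = runif(n_nodes, 0.2, 2),
    n_cells = sample(5:50, n_nodes, replace = TRUE)
  )
  suppressWarnings(build_network(nodes))
}

# Tiny two-blob marker dataset with known membership, for clustering tests.
two_blob_cells <- function(n_per = 60, seed = 42) {
  set.seed(seed)
  markers <- c("A", "B", "C")
  lo <- matrix(rnorm(n_per * 3, mean = 1500, sd = 120), n_per, 3)
  hi <- matrix(rnorm(n_per * 3, mean = 4000, sd = 120), n_per, 3)
  cells <- tibble::as_tibble(as.data.frame(rbind(lo, hi)))
  names(cells) <- markers
  cells$Timer.Blue <- 500
  cells$Timer.Red <- 500
  panel <- tocky_panel(
    markers = markers,
    timer_blue = "Timer.Blue", timer_red = "Timer.Red",
    marker_thresholds = c(A = 1000, B = 1000, C = 1000),
    timer_thresholds = c(400, 400)
  )
  list(cells = cells, panel = panel,
       truth = rep(c(1L, 2L), each = n_per))
}

# Dominant-archetype recovery check for the planted cohort chain: the path's
# clusters, mapped to their majority archetype among Timer-positive members,
# must climb the chain 1..n_arch in order without omission.
chain_recovered <- function(pipe, truth) {
  if (!pipe$path$reachable) return(FALSE)
  tp_idx <- which(pipe$cells$timer_positive)
  arch <- truth$archetype[tp_idx]
  cl <- pipe$cells$cluster[tp_idx]
  dominant <- vapply(split(arch, cl), function(a) {
    as.integer(names(which.max(table(a))))
  }, integer(1))
  seq_arch <- dominant[as.character(pipe$path$node_sequence)]
  seq_arch <- seq_arch[c(TRUE, diff(seq_arch) != 0)]
  n_arch <- max(truth$archetype)
  identical(as.integer(seq_arch), seq_len(n_arch))
}
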