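# Per-node topology suite for directed AOP networks.
#
# Path-based metrics (betweenness, stress, out-eccentricity, simple-path
# occurrence) ignore self-loops: a shortest path never uses one and a simple
# path cannot repeat a node. Degrees, in contrast, count a self-loop once
# inbound and once outbound (so it contributes 2 to total degree), keeping
# the identity mean(total degree) = 2|E|/|V| over all edges.

# adjacency list of node indices, self-loops removed, optional adjacent-only
edge_index <- function(network, include_non_adjacent = TRUE) {
  nodes <- network$nodes$title
  edges <- network$edges
  keep <- !edges$self_loop
  if (!include_non_adjacent) keep <- keep & edges$adjacency == "adjacent"
  e <- edges[keep, , drop = FALSE]
  adj <- rep(list(integer()), length(nodes))
  if (nrow(e)) {
    ui <- match(e$upstream, nodes)
    vi <- match(e$downstream, nodes)
    for (k in seq_along(ui)) adj[[ui[k]]] <- c(adj[[ui[k]]], vi[k])
  }
  list(adj = adj, n = length(nodes), titles = nodes)
}

# single-source BFS: geodesic distances and shortest-path counts
bfs_counts <- function(adj, n, s) {
  dist <- rep(NA_integer_, n)
  sigma <- numeric(n)
  dist[s] <- 0L
  sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          nxt <- c(nxt, v)
          sigma[v] <- sigma[v] + sigma[u]
        } else if (dist[v] == dist[u] + 1L) {
          sigma[v] <- sigma[v] + sigma[u]
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

all_pairs_counts <- function(g) {
  D <- matrix(NA_integer_, g$n, g$n)
  S <- matrix(0, g$n, g$n)
  for (s in seq_len(g$n)) {
    b <- bfs_counts(g$adj, g$n, s)
    D[s, ] <- b$dist
    S[s, ] <- b$sigma
  }
  list(D = D, S = S)
}

#' Node degrees and mean total degree
#'
#' @param network an `aop_network`.
#' @param include_non_adjacent include non-adjacent edges (default `TRUE`).
#' @return tibble `title`, `in_degree`, `out_degree`, `total_degree`;
#'   attribute `"mean_total_degree"` rounded half-up to 2 decimals (`NA`
#'   for an empty network).
#' @export
degree_stats <- function(network, include_non_adjacent = TRUE) {
  nodes <- network$nodes$title
  edges <- network$edges
  if (!include_non_adjacent) edges <- edges[edges$adjacency == "adjacent", ]
  indeg <- vapply(nodes, function(t) sum(edges$downstream == t), integer(1))
  outdeg <- vapply(nodes, function(t) sum(edges$upstream == t), integer(1))
  out <- tibble::tibble(
    title = nodes,
    in_degree = unname(indeg),
    out_degree = unname(outdeg),
    total_degree = unname(indeg + outdeg)
  )
  attr(out, "mean_total_degree") <-
    if (length(nodes)) round_half_up(mean(out$total_degree), 2) else NA_real_
  out
}

#' Shortest-path betweenness centrality
#'
#' Standard directed betweenness over ordered reachable pairs `(s, t)` with
#' `s != v != t`, crediting a node fractionally across equally short paths.
#' Disconnected pairs are skipped. `mode = "raw"` leaves the sums
#' unnormalised (the convention of desktop network analysers);
#' `"pair_normalised"` divides by `(N-1)(N-2)`.
#'
#' @param network an `aop_network`.
#' @param mode `"raw"` or `"pair_normalised"`.
#' @param include_non_adjacent include non-adjacent edges.
#' @return named numeric vector over node titles.
#' @export
betweenness_centrality <- function(network, mode = c("raw", "pair_normalised"),
                                   include_non_adjacent = TRUE) {
  mode <- match.arg(mode)
  g <- edge_index(network, include_non_adjacent)
  res <- path_centralities(g)
  out <- res$betweenness
  if (mode == "pair_normalised" && g$n > 2) {
    out <- out / ((g$n - 1) * (g$n - 2))
  }
  setNames(out, g$titles)
}

#' Stress centrality
#'
#' Total number of shortest paths (over all ordered node pairs) in which a
#' node is internal -- the unfractionated cousin of betweenness, flagging
#' convergence hubs.
#'
#' @inheritParams betweenness_centrality
#' @return named integer-valued numeric vector over node titles.
#' @export
stress_centrality <- function(network, include_non_adjacent = TRUE) {
  g <- edge_index(network, include_non_adjacent)
  setNames(path_centralities(g)$stress, g$titles)
}

path_centralities <- function(g) {
  ap <- all_pairs_counts(g)
  D <- ap$D
  S <- ap$S
  n <- g$n
  bet <- numeric(n)
  str <- numeric(n)
  if (n >= 3) {
    for (v in seq_len(n)) {
      for (s in seq_len(n)) {
        if (s == v || is.na(D[s, v])) next
        reach <- which(!is.na(D[s, ]) & !is.na(D[v, ]))
        ts <- reach[reach != s & reach != v &
                      D[s, reach] == D[s, v] + D[v, reach]]
        if (!length(ts)) next
        thru <- S[s, v] * S[v, ts]
        str[v] <- str[v] + sum(thru)
        bet[v] <- bet[v] + sum(thru / S[s, ts])
      }
    }
  }
  list(betweenness = bet, stress = str)
}

#' Out-eccentricity
#'
#' For every node, the geodesic distance to its farthest *reachable*
#' downstream node. Sinks (nothing reachable) score 0; unreachable nodes do
#' not enter the maximum, so the value is always finite.
#'
#' @inheritParams betweenness_centrality
#' @return named integer vector over node titles.
#' @export
out_eccentricity <- function(network, include_non_adjacent = TRUE) {
  g <- edge_index(network, include_non_adjacent)
  D <- all_pairs_counts(g)$D
  ecc <- vapply(seq_len(g$n), function(v) {
    d <- D[v, -v]
    d <- d[!is.na(d)]
    if (length(d)) max(d) else 0L
  }, integer(1))
  setNames(ecc, g$titles)
}

#' Convergent / divergent flow classification
#'
#' A node with more inbound than outbound connections is a convergence
#' point (downstream recipient); more outbound than inbound marks a
#' divergence point (upstream initiator); equal degrees are balanced.
#'
#' @param in_degree,out_degree non-negative integer vectors.
#' @return character vector: `"convergent"`, `"divergent"` or `"balanced"`.
#' @export
classify_flow <- function(in_degree, out_degree) {
  if (length(in_degree) != length(out_degree)) {
    abort("Degree vectors must have equal length.")
  }
  dplyr::case_when(
    in_degree > out_degree ~ "convergent",
    out_degree > in_degree ~ "divergent",
    TRUE ~ "balanced"
  )
}

#' MIE-to-AO simple path occurrence
#'
#' Enumerates every simple directed path from each MIE-role node to each
#' AO-role node and counts, per node, the paths in which it appears as an
#' internal node (not an endpoint). Also returns the distribution of path
#' lengths in edges. Self-loops never participate (a simple path cannot
#' repeat a node). Enumeration aborts if the number of paths exceeds `cap`,
#' which signals a pathologically dense input rather than a real AOP
#' network.
#'
#' @inheritParams betweenness_centrality
#' @param cap maximum number of paths to enumerate before aborting.
#' @return list with `occurrence` (named integer vector),
#'   `path_length_histogram` (named integer vector keyed by edge count) and
#'   `n_paths`.
#' @export
simple_path_occurrence <- function(network, include_non_adjacent = TRUE,
                                   cap = 1e6) {
  g <- edge_index(network, include_non_adjacent)
  roles <- network$nodes$role
  sources <- which(roles == "MIE")
  sinks <- which(roles == "AO")
  occ <- integer(g$n)
  hist_env <- new.env(parent = emptyenv())
  n_paths <- 0L

  if (length(sources) && length(sinks)) {
    is_sink <- rep(FALSE, g$n)
    is_sink[sinks] <- TRUE
    for (s in sources) {
      onpath <- rep(FALSE, g$n)
      stack <- integer(g$n)
      depth <- 0L
      dfs <- function(u) {
        depth <<- depth + 1L
        stack[depth] <<- u
        onpath[u] <<- TRUE
        if (is_sink[u] && depth >= 2L) {
          n_paths <<- n_paths + 1L
          if (n_paths > cap) {
            abort(sprintf("Simple-path enumeration exceeded the cap of %g paths.", cap))
          }
          if (depth > 2L) {
            internal <- stack[2:(depth - 1L)]
            occ[internal] <<- occ[internal] + 1L
          }
          key <- as.character(depth - 1L)
          hist_env[[key]] <- (hist_env[[key]] %||% 0L) + 1L
        }
        for (v in g$adj[[u]]) if (!onpath[v]) dfs(v)
        onpath[u] <<- FALSE
        depth <<- depth - 1L
      }
      dfs(s)
    }
  }
  keys <- ls(hist_env)
  histogram <- setNames(
    vapply(keys, function(k) hist_env[[k]], integer(1)),
    keys
  )
  histogram <- histogram[order(as.integer(names(histogram)))]
  list(
    occurrence = setNames(occ, g$titles),
    path_length_histogram = histogram,
    n_paths = n_paths
  )
}

#' Combined importance score
#'
#' Each component metric is min--max normalised to [0, 1] over the node set
#' (a zero-range component contributes 0 for every node) and the normalised
#' components are summed. The score is therefore invariant under affine
#' rescaling of any single input. The ranking is descending by score with
#' ties broken lexicographically by title.
#'
#' @param metrics tibble containing `title` and the component columns.
#' @param components character vector of column names to combine.
#' @return `metrics` with added `combined_score` and `rank` columns.
#' @export
combined_importance <- function(metrics,
                                components = c("total_degree", "betweenness", "stress")) {
  missing_cols <- setdiff(components, names(metrics))
  if (length(missing_cols)) {
    abort(sprintf("Unknown component metric(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  minmax <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  }
  score <- Reduce(`+`, lapply(components, function(cmp) minmax(metrics[[cmp]])))
  if (nrow(metrics) == 0) score <- numeric()
  metrics$combined_score <- score
  ord <- order(-metrics$combined_score, metrics$title)
  metrics$rank <- integer(nrow(metrics))
  metrics$rank[ord] <- seq_len(nrow(metrics))
  metrics
}

#' Full per-node topology metrics table
#'
#' Computes the complete metric suite on one network: degrees, betweenness,
#' stress, out-eccentricity, combined importance score with ranking, flow
#' classification and MIE-to-AO simple-path occurrence.
#'
#' @inheritParams betweenness_centrality
#' @param betweenness_mode `"raw"` (default) or `"pair_normalised"`.
#' @param path_cap cap for the simple-path enumeration.
#' @return tibble, one row per node, with attributes `"mean_total_degree"`,
#'   `"path_length_histogram"` and `"n_simple_paths"`.
#' @export
network_metrics <- function(network, include_non_adjacent = TRUE,
                            betweenness_mode = c("raw", "pair_normalised"),
                            path_cap = 1e6) {
  betweenness_mode <- match.arg(betweenness_mode)
  deg <- degree_stats(network, include_non_adjacent)
  bet <- betweenness_centrality(network, betweenness_mode, include_non_adjacent)
  str <- stress_centrality(network, include_non_adjacent)
  ecc <- out_eccentricity(network, include_non_adjacent)
  spo <- simple_path_occurrence(network, include_non_adjacent, cap = path_cap)

  out <- deg
  out$role <- network$nodes$role[match(out$title, network$nodes$title)]
  out$betweenness <- unname(bet[out$title])
  out$stress <- unname(str[out$title])
  out$eccentricity <- unname(ecc[out$title])
  out$flow_class <- classify_flow(out$in_degree, out$out_degree)
  out$simple_path_occurrence <- unname(spo$occurrence[out$title])
  out <- combined_importance(out)
  out <- out[, c("title", "role", "in_degree", "out_degree", "total_degree",
                 "betweenness", "stress", "eccentricity", "combined_score",
                 "rank", "flow_class", "simple_path_occurrence")]
  attr(out, "mean_total_degree") <- attr(deg, "mean_total_degree")
  attr(out, "path_length_histogram") <- spo$path_length_histogram
  attr(out, "n_simple_paths") <- spo$n_paths
  out
}
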