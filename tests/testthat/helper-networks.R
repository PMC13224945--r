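# Shared helpers: quick network construction and exhaustive path-enumeration
# oracles used to validate the BFS/DFS-based metric implementations.

toy_network <- function(from, to, roles = NULL, adjacency = NULL) {
  titles <- sort(unique(c(from, to)))
  role <- stats::setNames(rep("KE", length(titles)), titles)
  if (!is.null(roles)) role[names(roles)] <- roles
  nodes <- tibble::tibble(title = titles, role = unname(role[titles]))
  edges <- tibble::tibble(
    upstream = from, downstream = to,
    adjacency = if (is.null(adjacency)) rep("adjacent", length(from)) else adjacency
  )
  aop_network(nodes, edges)
}

# random directed graph as an aop_network: n nodes, edge prob p, two MIEs
# and two AOs, optional self-loop
random_network <- function(seed, n_range = 4:9, p = 0.2) {
  set.seed(seed)
  n <- sample(n_range, 1)
  titles <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(from = titles, to = titles, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  from <- pairs$from[keep]
  to <- pairs$to[keep]
  if (stats::runif(1) < 0.3) { # occasional self-loop, must be ignored by paths
    v <- sample(titles, 1)
    from <- c(from, v)
    to <- c(to, v)
  }
  special <- sample(titles, 4)
  roles <- stats::setNames(c("MIE", "MIE", "AO", "AO"), special)
  if (!length(from)) { # ensure at least one edge so the network is non-trivial
    from <- titles[1]
    to <- titles[2]
  }
  adjacency <- sample(c("adjacent", "non-adjacent"), length(from),
                      replace = TRUE, prob = c(0.85, 0.15))
  toy_network(from, to, roles = roles, adjacency = adjacency)
}

# adjacency list of node indices, self-loops dropped (oracle-side rebuild)
oracle_adj <- function(network) {
  titles <- network$nodes$title
  e <- network$edges[!network$edges$self_loop, , drop = FALSE]
  adj <- rep(list(integer()), length(titles))
  for (k in seq_len(nrow(e))) {
    u <- match(e$upstream[k], titles)
    adj[[u]] <- c(adj[[u]], match(e$downstream[k], titles))
  }
  list(adj = adj, n = length(titles), titles = titles)
}

# every simple path starting at s, as integer node sequences (length >= 2)
oracle_paths_from <- function(g, s) {
  paths <- list()
  path <- integer(0)
  onp <- logical(g$n)
  dfs <- function(u) {
    path[length(path) + 1L] <<- u
    onp[u] <<- TRUE
    if (length(path) > 1L) paths[[length(paths) + 1L]] <<- path
    for (v in g$adj[[u]]) if (!onp[v]) dfs(v)
    onp[u] <<- FALSE
    path <<- path[-length(path)]
  }
  dfs(s)
  paths
}

# brute-force betweenness, stress and out-eccentricity from full simple-path
# enumeration: geodesics are the minimum-length simple paths per pair
oracle_path_metrics <- function(network) {
  g <- oracle_adj(network)
  bet <- numeric(g$n)
  str <- numeric(g$n)
  ecc <- integer(g$n)
  for (s in seq_len(g$n)) {
    paths <- oracle_paths_from(g, s)
    if (!length(paths)) next
    ends <- vapply(paths, function(p) p[length(p)], integer(1))
    for (t in unique(ends)) {
      pt <- paths[ends == t]
      lens <- lengths(pt) - 1L
      L <- min(lens)
      ecc[s] <- max(ecc[s], L)
      shortest <- pt[lens == L]
      sigma <- length(shortest)
      for (p in shortest) {
        if (length(p) > 2L) {
          internal <- p[2:(length(p) - 1L)]
          str[internal] <- str[internal] + 1
          bet[internal] <- bet[internal] + 1 / sigma
        }
      }
    }
  }
  list(betweenness = stats::setNames(bet, g$titles),
       stress = stats::setNames(str, g$titles),
       eccentricity = stats::setNames(ecc, g$titles))
}

# brute-force MIE->AO simple path occurrence + length histogram
oracle_spo <- function(network) {
  g <- oracle_adj(network)
  roles <- network$nodes$role
  occ <- integer(g$n)
  lens <- integer(0)
  for (s in which(roles == "MIE")) {
    paths <- oracle_paths_from(g, s)
    for (p in paths) {
      if (roles[p[length(p)]] == "AO") {
        lens <- c(lens, length(p) - 1L)
        if (length(p) > 2L) {
          internal <- p[2:(length(p) - 1L)]
          occ[internal] <- occ[internal] + 1L
        }
      }
    }
  }
  histogram <- table(lens)
  list(occurrence = stats::setNames(occ, g$titles),
       path_length_histogram = stats::setNames(as.integer(histogram),
                                               names(histogram)),
       n_paths = length(lens))
}
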