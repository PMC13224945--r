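# Directed AOP network assembly: merge parallel relationships asserted by
# several AOPs into single attributed edges, keep self-loops, and summarise
# composition. Edges always point upstream -> downstream (cause -> effect).

EVIDENCE_LEVELS <- c("High", "Moderate", "Low", "Not Specified")

strongest_category <- function(categories) {
  EVIDENCE_LEVELS[min(match(categories, EVIDENCE_LEVELS))]
}

#' Construct an AOP network object
#'
#' Low-level constructor validating the network invariants: edge endpoints
#' must exist among the nodes, duplicate `(upstream, downstream)` pairs are
#' forbidden (parallel relationships are merged by [build_network()]), and
#' node roles must be MIE/KE/AO. Nodes and edges are stored sorted so that
#' the representation is canonical: networks built from permuted inputs
#' compare identical.
#'
#' @param nodes tibble with at least `title`, `role`; optionally
#'   `member_ids`, `aops` list-columns.
#' @param edges tibble with at least `upstream`, `downstream`, `adjacency`;
#'   optionally `evidence`, `quant`, `source_aops`, `raw_evidence`,
#'   `raw_quant`.
#' @param manifest free-form provenance list.
#' @return an `aop_network` object.
#' @export
aop_network <- function(nodes, edges, manifest = list()) {
  nodes <- strip_table_attrs(nodes)
  edges <- strip_table_attrs(edges)
  if (!all(c("title", "role") %in% names(nodes))) {
    abort("`nodes` needs columns 'title' and 'role'.")
  }
  if (anyDuplicated(nodes$title)) abort("Node titles must be unique.")
  if (!all(nodes$role %in% ROLE_LEVELS)) abort("Node roles must be MIE, KE or AO.")
  if (!"member_ids" %in% names(nodes)) nodes$member_ids <- as.list(nodes$title)
  if (!"aops" %in% names(nodes)) nodes$aops <- rep(list(character()), nrow(nodes))
  if (nrow(edges)) {
    if (!all(c("upstream", "downstream", "adjacency") %in% names(edges))) {
      abort("`edges` needs columns 'upstream', 'downstream' and 'adjacency'.")
    }
    missing_ep <- setdiff(union(edges$upstream, edges$downstream), nodes$title)
    if (length(missing_ep)) {
      abort(sprintf("Edge endpoint(s) not in the node set: %s",
                    paste(missing_ep, collapse = ", ")))
    }
    if (anyDuplicated(edges[, c("upstream", "downstream")])) {
      abort("Duplicate (upstream, downstream) pairs; merge parallel KERs first.")
    }
    if (!all(edges$adjacency %in% ADJACENCY_LEVELS)) {
      abort("Edge adjacency must be 'adjacent' or 'non-adjacent'.")
    }
  } else {
    edges <- empty_edge_table()
  }
  if (!"evidence" %in% names(edges)) edges$evidence <- rep("Not Specified", nrow(edges))
  if (!"quant" %in% names(edges)) edges$quant <- rep("Not Specified", nrow(edges))
  if (!"source_aops" %in% names(edges)) {
    edges$source_aops <- rep(list(character()), nrow(edges))
  }
  edges$self_loop <- edges$upstream == edges$downstream

  nodes <- dplyr::arrange(nodes, .data$title)
  edges <- dplyr::arrange(edges, .data$upstream, .data$downstream)
  structure(list(nodes = nodes, edges = edges, manifest = manifest),
            class = "aop_network")
}

empty_edge_table <- function() {
  tibble::tibble(
    upstream = character(), downstream = character(),
    adjacency = character(), evidence = character(), quant = character(),
    source_aops = list(), raw_evidence = list(), raw_quant = list(),
    n_kers = integer(), self_loop = logical()
  )
}

#' Build the directed AOP network from a roster and remapped relationships
#'
#' Parallel relationships (the same canonical `(upstream, downstream)` pair
#' asserted by several AOPs) merge into one edge: source AOPs are unioned,
#' adjacency resolves adjacent-wins (the more direct mechanistic claim), and
#' evidence / quantitative understanding resolve to the strongest recoded
#' category present (High > Moderate > Low > Not Specified), with every
#' contributing raw label retained for audit. Self-loops are kept.
#'
#' @param roster harmonised roster ([apply_merge_map()]).
#' @param kers remapped relationships ([remap_kers()]).
#' @param manifest optional provenance list.
#' @return an `aop_network`.
#' @export
build_network <- function(roster, kers, manifest = list()) {
  if (nrow(kers) == 0) {
    return(aop_network(roster, empty_edge_table(),
                       c(manifest, list(n_input_kers = 0L))))
  }
  edges <- kers |>
    dplyr::group_by(.data$upstream, .data$downstream) |>
    dplyr::summarise(
      adjacency = if (any(.data$adjacency == "adjacent")) "adjacent" else "non-adjacent",
      evidence = strongest_category(recode_evidence(.data$evidence_raw)),
      quant = strongest_category(recode_quant(.data$quant_raw)),
      source_aops = list(sort(unique(.data$aop_id))),
      raw_evidence = list(sort(.data$evidence_raw)),
      raw_quant = list(sort(.data$quant_raw)),
      n_kers = dplyr::n(),
      .groups = "drop"
    )
  aop_network(roster, edges,
              c(manifest, list(n_input_kers = nrow(kers))))
}

#' Summarise network composition
#'
#' Node counts by role, edge counts by adjacency, self-loop count and the
#' key event sharing histogram (how many nodes belong to 1, 2, ... source
#' AOPs), each with percentages rounded half-up to two decimals.
#'
#' @param network an `aop_network`.
#' @return list of class `aop_composition`.
#' @export
composition_summary <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  roles <- vapply(ROLE_LEVELS, function(r) sum(nodes$role == r), integer(1))
  adj <- vapply(ADJACENCY_LEVELS, function(a) sum(edges$adjacency == a), integer(1))
  n_aops_per_node <- lengths(nodes$aops)
  sharing <- if (nrow(nodes)) table(factor(n_aops_per_node)) else table(integer())
  sharing_counts <- setNames(as.integer(sharing), names(sharing))
  structure(list(
    n_nodes = nrow(nodes),
    n_edges = nrow(edges),
    roles = roles,
    role_pct = pct_of(roles, nrow(nodes)),
    adjacency = adj,
    adjacency_pct = pct_of(adj, nrow(edges)),
    self_loops = sum(edges$self_loop),
    sharing = sharing_counts,
    sharing_pct = pct_of(sharing_counts, nrow(nodes)),
    source_aops = sort(unique(unlist(nodes$aops)))
  ), class = "aop_composition")
}

#' @export
print.aop_composition <- function(x, ...) {
  cat(sprintf("AOP network: %d nodes (%s), %d edges\n",
              x$n_nodes,
              paste(sprintf("%d %s", x$roles, names(x$roles)), collapse = ", "),
              x$n_edges))
  cat(sprintf("  adjacency: %s\n",
              paste(sprintf("%d %s (%.2f%%)", x$adjacency, names(x$adjacency),
                            x$adjacency_pct), collapse = ", ")))
  cat(sprintf("  self-loops: %d\n", x$self_loops))
  if (length(x$sharing)) {
    cat("  nodes per AOP-membership count: ",
        paste(sprintf("%s:%d", names(x$sharing), x$sharing), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.aop_network <- function(x, ...) {
  print(composition_summary(x))
  invisible(x)
}

#' Induced subnetwork
#'
#' Filters nodes and/or edges by predicates and returns the induced graph;
#' edges with a dropped endpoint are removed.
#'
#' @param network an `aop_network`.
#' @param node_keep logical vector over `network$nodes` rows, or a function
#'   of the node tibble returning one; `NULL` keeps all.
#' @param edge_keep same for edges; `NULL` keeps all.
#' @param drop_self_loops convenience flag removing self-loops (used for
#'   export to viewers that cannot render them).
#' @return an `aop_network`.
#' @export
subnetwork <- function(network, node_keep = NULL, edge_keep = NULL,
                       drop_self_loops = FALSE) {
  nodes <- network$nodes
  edges <- network$edges
  nk <- if (is.null(node_keep)) rep(TRUE, nrow(nodes))
        else if (is.function(node_keep)) node_keep(nodes) else node_keep
  ek <- if (is.null(edge_keep)) rep(TRUE, nrow(edges))
        else if (is.function(edge_keep)) edge_keep(edges) else edge_keep
  if (drop_self_loops) ek <- ek & !edges$self_loop
  nodes <- nodes[nk, , drop = FALSE]
  ek <- ek & edges$upstream %in% nodes$title & edges$downstream %in% nodes$title
  aop_network(nodes, edges[ek, , drop = FALSE], network$manifest)
}

#' Convert an AOP network to an igraph graph
#'
#' List-valued attributes (member ids, source AOPs, raw labels) are
#' collapsed with `";"` so every attribute is a plain character vector, as
#' required by graph interchange formats.
#'
#' @param network an `aop_network`.
#' @return a directed `igraph` graph.
#' @export
as_igraph <- function(network) {
  v <- tibble::tibble(
    name = network$nodes$title,
    role = network$nodes$role,
    member_ids = vapply(network$nodes$member_ids, paste, character(1), collapse = ";"),
    aops = vapply(network$nodes$aops, paste, character(1), collapse = ";")
  )
  e <- tibble::tibble(
    from = network$edges$upstream,
    to = network$edges$downstream,
    adjacency = network$edges$adjacency,
    evidence = network$edges$evidence,
    quant = network$edges$quant,
    source_aops = vapply(network$edges$source_aops, paste, character(1), collapse = ";")
  )
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}
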