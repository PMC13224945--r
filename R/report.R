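# Summary reporting and network export (SIF, GraphML, categorical overlay).

#' Headline summary report for an AOP network
#'
#' Collects the composition, evidence and quantitative-understanding
#' distributions, flow-class counts, KC coverage and detection-method
#' coverage into one machine-readable structure. Percentages are rounded
#' half-up to two decimals, except the "any quantitative understanding"
#' share which is conventionally printed at one decimal.
#'
#' @param network an `aop_network`.
#' @param metrics optional [network_metrics()] table (adds flow-class
#'   counts and the mean total degree).
#' @param kc_table optional KC table for coverage.
#' @param sections optional measurement sections for method coverage.
#' @return list of class `aop_summary_report`; serialise with
#'   [report_json()] or print for a human-readable rendering.
#' @export
summary_report <- function(network, metrics = NULL, kc_table = NULL,
                           sections = NULL) {
  comp <- composition_summary(network)
  edges <- network$edges
  n_edges <- nrow(edges)

  ev_counts <- vapply(EVIDENCE_LEVELS, function(lv) sum(edges$evidence == lv),
                      integer(1))
  q_counts <- vapply(EVIDENCE_LEVELS, function(lv) sum(edges$quant == lv),
                     integer(1))
  n_quant_any <- sum(has_quant(edges$quant))

  rep_obj <- list(
    composition = comp,
    evidence = list(counts = ev_counts, pct = pct_of(ev_counts, n_edges)),
    quant = list(
      counts = q_counts,
      pct = pct_of(q_counts, n_edges),
      n_any = n_quant_any,
      pct_any = pct_of(n_quant_any, n_edges, digits = 1)
    )
  )

  if (!is.null(metrics)) {
    fc <- c(convergent = sum(metrics$flow_class == "convergent"),
            divergent = sum(metrics$flow_class == "divergent"),
            balanced = sum(metrics$flow_class == "balanced"))
    rep_obj$flow <- list(counts = fc, pct = pct_of(fc, nrow(metrics)))
    rep_obj$mean_total_degree <- attr(metrics, "mean_total_degree")
    rep_obj$path_length_histogram <- attr(metrics, "path_length_histogram")
  }
  if (!is.null(kc_table)) {
    kc <- kc_coverage(network, kc_table)
    rep_obj$kc <- list(n_mapped = kc$n_mapped, n_unmapped = kc$n_unmapped,
                       pct_mapped = kc$pct_mapped,
                       pct_unmapped = kc$pct_unmapped,
                       per_kc = kc$per_kc, absent_kcs = kc$absent_kcs)
  }
  if (!is.null(sections)) {
    cat_tbl <- build_method_catalogue(network, sections)
    cov <- attr(cat_tbl, "coverage")
    rep_obj$methods <- list(n_with_method = cov$n_with_method,
                            pct_with_method = cov$pct_with_method)
  }
  structure(rep_obj, class = "aop_summary_report")
}

#' @export
print.aop_summary_report <- function(x, ...) {
  print(x$composition)
  cat("  evidence       : ",
      paste(sprintf("%s %d (%.2f%%)", names(x$evidence$counts),
                    x$evidence$counts, x$evidence$pct), collapse = ", "), "\n")
  cat(sprintf("  quantified KERs: %d (%.1f%%)\n", x$quant$n_any, x$quant$pct_any))
  if (!is.null(x$flow)) {
    cat("  flow classes   : ",
        paste(sprintf("%s %d", names(x$flow$counts), x$flow$counts),
              collapse = ", "), "\n")
    cat(sprintf("  mean total degree: %.2f\n", x$mean_total_degree))
  }
  if (!is.null(x$kc)) {
    cat(sprintf("  KC-mapped nodes: %d (%.2f%%); absent KCs: %s\n",
                x$kc$n_mapped, x$kc$pct_mapped,
                if (length(x$kc$absent_kcs)) paste(x$kc$absent_kcs, collapse = ", ")
                else "none"))
  }
  if (!is.null(x$methods)) {
    cat(sprintf("  nodes with detection methods: %d (%.2f%%)\n",
                x$methods$n_with_method, x$methods$pct_with_method))
  }
  invisible(x)
}

#' Serialise a summary report to JSON
#'
#' @param report an `aop_summary_report`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to file).
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass_deep(report), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# fixed, documented categorical palette for overlays
overlay_palette <- function() {
  c("High" = "#1a9850", "Moderate" = "#fee08b", "Low" = "#fdae61",
    "Not Specified" = "#bdbdbd",
    "adjacent" = "#2166ac", "non-adjacent" = "#b2182b",
    "MIE" = "#66bd63", "KE" = "#ffffbf", "AO" = "#d73027")
}

#' Export an AOP network
#'
#' Writes the network in one of three plain-text interchange formats:
#' \describe{
#'   \item{`sif`}{one line per edge, `upstream<TAB>relation<TAB>downstream`,
#'     relation being the adjacency class.}
#'   \item{`graphml`}{typed node/edge attributes via igraph; re-importable
#'     with [read_graphml_network()].}
#'   \item{`overlay`}{a categorical overlay TSV for interactive map
#'     platforms: comment headers `#VERSION=`, `#NAME=`, `#DESCRIPTION=`,
#'     then `name<TAB>value<TAB>color` rows mapping each edge (or node) to
#'     its category under a fixed palette.}
#' }
#'
#' @param network an `aop_network`.
#' @param path output file path.
#' @param format `"sif"`, `"graphml"` or `"overlay"`.
#' @param overlay_attribute which categorical attribute to overlay:
#'   `"evidence"`, `"quant"`, `"adjacency"` (edge-level) or `"role"`
#'   (node-level).
#' @param drop_self_loops drop self-loops before export, for parity with
#'   viewers that cannot render them.
#' @param name,description overlay metadata strings.
#' @return the path, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("sif", "graphml", "overlay"),
                           overlay_attribute = c("evidence", "quant",
                                                 "adjacency", "role"),
                           drop_self_loops = FALSE,
                           name = "aopnet overlay",
                           description = "Categorical annotation overlay") {
  format <- match.arg(format)
  if (drop_self_loops) network <- subnetwork(network, drop_self_loops = TRUE)
  edges <- network$edges
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", edges$upstream, edges$adjacency,
                       edges$downstream), path)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    overlay_attribute <- match.arg(overlay_attribute)
    pal <- overlay_palette()
    if (overlay_attribute == "role") {
      nm <- network$nodes$title
      val <- network$nodes$role
    } else {
      nm <- sprintf("%s -> %s", edges$upstream, edges$downstream)
      val <- edges[[overlay_attribute]]
    }
    lines <- c(
      "#VERSION=1.0",
      sprintf("#NAME=%s", name),
      sprintf("#DESCRIPTION=%s", description),
      "name\tvalue\tcolor",
      sprintf("%s\t%s\t%s", nm, val, unname(pal[val]))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Re-import a GraphML export as an AOP network
#'
#' Inverse of `export_network(..., format = "graphml")`: attributes
#' collapsed with `";"` on export are split back into list-columns.
#'
#' @param path GraphML file written by [export_network()].
#' @return an `aop_network` (manifest records the source file).
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  split_col <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                  function(v) v[nzchar(v)])
  nodes <- tibble::tibble(
    title = igraph::vertex_attr(g, "name"),
    role = igraph::vertex_attr(g, "role"),
    member_ids = split_col(igraph::vertex_attr(g, "member_ids")),
    aops = split_col(igraph::vertex_attr(g, "aops"))
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- tibble::tibble(
    upstream = el[, 1],
    downstream = el[, 2],
    adjacency = igraph::edge_attr(g, "adjacency"),
    evidence = igraph::edge_attr(g, "evidence"),
    quant = igraph::edge_attr(g, "quant"),
    source_aops = split_col(igraph::edge_attr(g, "source_aops"))
  )
  aop_network(nodes, edges, manifest = list(source = path))
}
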