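# Evidence recoding, key characteristic coverage and the detection-method
# catalogue.

#' Recode raw evidence labels into analysis categories
#'
#' AOP-Wiki relationship entries carry a mixed vocabulary of weight-of-
#' evidence labels. For analysis, "High" and "Strong" are grouped under
#' `High`; "Not Specified", "NA" and blanks are consolidated under
#' `Not Specified`. Matching is case-insensitive; unknown labels map to
#' `Not Specified` with a warning. The mapping is total and idempotent.
#'
#' @param raw character vector of raw labels.
#' @return character vector of categories: `"High"`, `"Moderate"`, `"Low"`
#'   or `"Not Specified"`.
#' @export
recode_evidence <- function(raw) {
  key <- tolower(blank_to_na_label(raw))
  out <- dplyr::case_when(
    key %in% c("high", "strong") ~ "High",
    key == "moderate" ~ "Moderate",
    key == "low" ~ "Low",
    key %in% c("not specified", "na") ~ "Not Specified",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    warn(sprintf("Unknown evidence label(s) mapped to 'Not Specified': %s",
                 paste(unique(raw[is.na(out)]), collapse = ", ")))
    out[is.na(out)] <- "Not Specified"
  }
  out
}

#' Recode quantitative-understanding labels
#'
#' Same scheme as [recode_evidence()]. A relationship "has quantitative
#' understanding" when its category is anything other than `Not Specified`;
#' see [has_quant()].
#'
#' @inheritParams recode_evidence
#' @return character vector of categories.
#' @export
recode_quant <- function(raw) {
  recode_evidence(raw)
}

#' Does a recoded quantitative-understanding category count as quantified?
#'
#' @param category character vector of recoded categories.
#' @return logical vector, `TRUE` unless `"Not Specified"`.
#' @export
has_quant <- function(category) {
  category != "Not Specified"
}

#' Key characteristic coverage of a network
#'
#' Node-level KC sets are the union of the KC mappings of all member event
#' ids. Reports, over the node set, how many nodes map to at least one key
#' characteristic, per-KC node counts (over the full KC1--KC12 vocabulary)
#' and which KCs are absent from the network.
#'
#' @param network an `aop_network`.
#' @param kc_table tibble (`event_id`, `kc_id`) as from [read_kc_table()].
#' @return list with `per_node` tibble (`title`, `kcs`, `n_kc`, `mapped`),
#'   counts `n_mapped` / `n_unmapped`, percentages, `per_kc` counts and
#'   `absent_kcs`.
#' @export
kc_coverage <- function(network, kc_table) {
  sets <- kc_sets(kc_table)
  per_node_kcs <- lapply(network$nodes$member_ids, function(ids) {
    sort(unique(unlist(sets[intersect(ids, names(sets))])))
  })
  per_node <- tibble::tibble(
    title = network$nodes$title,
    kcs = per_node_kcs,
    n_kc = lengths(per_node_kcs),
    mapped = lengths(per_node_kcs) > 0
  )
  per_kc <- vapply(KC_LEVELS, function(kc) {
    sum(vapply(per_node_kcs, function(s) kc %in% s, logical(1)))
  }, integer(1))
  n_nodes <- nrow(per_node)
  list(
    per_node = per_node,
    n_mapped = sum(per_node$mapped),
    n_unmapped = sum(!per_node$mapped),
    pct_mapped = pct_of(sum(per_node$mapped), n_nodes),
    pct_unmapped = pct_of(sum(!per_node$mapped), n_nodes),
    per_kc = per_kc,
    absent_kcs = names(per_kc)[per_kc == 0]
  )
}

#' Modality keyword lexicon
#'
#' The shipped, editable lexicon classifying detection-method free text into
#' in vivo / in vitro / in silico modalities by case-insensitive substring
#' matching. Stored as package data (`extdata/modality_lexicon.tsv`) so
#' users can supply their own.
#'
#' @param path optional path to a custom two-column TSV (`term`,
#'   `modality`).
#' @return tibble with columns `term`, `modality`.
#' @export
modality_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "modality_lexicon.tsv",
                                package = "aopnet", mustWork = TRUE)
  tbl <- read_tsv_strict(path)
  if (!all(c("term", "modality") %in% names(tbl))) {
    abort("A modality lexicon needs columns 'term' and 'modality'.")
  }
  tibble::tibble(term = tolower(tbl$term), modality = tbl$modality)
}

#' Build the detection-method catalogue
#'
#' Joins measurement sections to network nodes: each node's text is the
#' concatenation over its member event ids (each chunk prefixed with the
#' contributing id, so provenance survives the merge). Modalities are tagged
#' from the text via [modality_lexicon()]. A node "has a method" exactly
#' when its concatenated text is non-empty after whitespace normalisation.
#'
#' @param network an `aop_network`.
#' @param sections tibble (`event_id`, `text`) as from
#'   [extract_measurement_sections()].
#' @param lexicon modality lexicon tibble; default the shipped one.
#' @return tibble, one row per node: `title`, `member_ids`,
#'   `measurement_text`, `modalities` (list), `has_method`; attribute
#'   `"coverage"` holds `n_with_method` and `pct_with_method`.
#' @export
build_method_catalogue <- function(network, sections,
                                   lexicon = modality_lexicon()) {
  txt_by_id <- setNames(sections$text, normalise_event_id(sections$event_id))
  entries <- lapply(network$nodes$member_ids, function(ids) {
    ids <- sort(ids)
    chunks <- txt_by_id[intersect(ids, names(txt_by_id))]
    chunks <- chunks[!is.na(chunks) & nzchar(trimws(chunks))]
    if (!length(chunks)) return("")
    paste(sprintf("[%s] %s", names(chunks), unname(chunks)), collapse = "\n")
  })
  text <- unlist(entries)
  lowered <- tolower(text)
  modalities <- lapply(lowered, function(t) {
    if (!nzchar(t)) return(character())
    hit <- vapply(lexicon$term, function(term) grepl(term, t, fixed = TRUE),
                  logical(1))
    sort(unique(lexicon$modality[hit]))
  })
  out <- tibble::tibble(
    title = network$nodes$title,
    member_ids = network$nodes$member_ids,
    measurement_text = text,
    modalities = modalities,
    has_method = nzchar(trimws(text))
  )
  attr(out, "coverage") <- list(
    n_with_method = sum(out$has_method),
    pct_with_method = pct_of(sum(out$has_method), nrow(out))
  )
  out
}
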