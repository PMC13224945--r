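# Reading and writing AOP-Wiki style tables and XML dumps.
#
# All tabular inputs are UTF-8, tab-separated, header row first, no quoting.
# Column names in real exports vary between releases, so every reader takes a
# `column_map` translating logical field names to the file's headers.

ROLE_LEVELS <- c("MIE", "KE", "AO")
ADJACENCY_LEVELS <- c("adjacent", "non-adjacent")
KC_LEVELS <- paste0("KC", 1:12)

# dialect alias tables for the role column
role_alias <- function(x) {
  key <- gsub("[^a-z]", "", tolower(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("mie", "molecularinitiatingevent")] <- "MIE"
  out[key %in% c("ke", "keyevent")] <- "KE"
  out[key %in% c("ao", "adverseoutcome")] <- "AO"
  out
}

adjacency_alias <- function(x) {
  key <- gsub("[^a-z]", "", tolower(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key == "adjacent"] <- "adjacent"
  out[key == "nonadjacent"] <- "non-adjacent"
  out
}

read_tsv_strict <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    quote = "", na = character(), progress = FALSE,
    show_col_types = FALSE
  )
}

check_column_map <- function(tbl, column_map, needed, path) {
  missing_logical <- setdiff(needed, names(column_map))
  if (length(missing_logical)) {
    abort(sprintf(
      "`column_map` must name columns for: %s",
      paste(missing_logical, collapse = ", ")
    ))
  }
  absent <- setdiff(unname(column_map[needed]), names(tbl))
  if (length(absent)) {
    abort(sprintf(
      "Column(s) %s not found in '%s'. Available headers: %s",
      paste0("'", absent, "'", collapse = ", "), path,
      paste(names(tbl), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Read an AOP-Wiki key events dataset
#'
#' Parses the tab-separated key events export (one row per AOP membership of
#' a key event) into validated records. Rows failing validation (blank ids,
#' unrecognised role labels) are not silently dropped: they are collected,
#' with their row numbers and a reason, in the `"errors"` attribute of the
#' returned tibble.
#'
#' @param path path to a TSV file.
#' @param column_map named character vector mapping the logical fields
#'   `aop`, `event`, `title`, `role` to the file's column headers.
#' @return a tibble with columns `aop_id`, `event_id`, `title`, `role`
#'   (`"MIE"`, `"KE"` or `"AO"`); attribute `"errors"` holds rejected rows.
#' @export
read_ke_dataset <- function(path,
                            column_map = c(aop = "aop_id", event = "event_id",
                                           title = "title", role = "role")) {
  tbl <- read_tsv_strict(path)
  if (nrow(tbl) == 0) {
    out <- tibble::tibble(aop_id = character(), event_id = character(),
                          title = character(), role = character())
    attr(out, "errors") <- tibble::tibble(row = integer(), reason = character())
    return(out)
  }
  check_column_map(tbl, column_map, c("aop", "event", "title", "role"), path)
  raw <- tibble::tibble(
    aop_id = trimws(tbl[[column_map[["aop"]]]]),
    event_id = normalise_event_id(tbl[[column_map[["event"]]]]),
    title = tbl[[column_map[["title"]]]],
    role = role_alias(tbl[[column_map[["role"]]]])
  )
  bad <- !nzchar(raw$aop_id) | !nzchar(raw$event_id) | is.na(raw$role)
  errors <- tibble::tibble(
    row = which(bad),
    reason = dplyr::case_when(
      !nzchar(raw$aop_id[bad]) ~ "empty aop_id",
      !nzchar(raw$event_id[bad]) ~ "empty event_id",
      TRUE ~ "unrecognised role label"
    )
  )
  out <- raw[!bad, ]
  attr(out, "errors") <- errors
  out
}

#' Read a key event relationship (KER) table
#'
#' One row per directed relationship asserted by a source AOP. Blank or
#' NA-like evidence and quantitative-understanding labels are normalised to
#' the sentinel `"NA"` (recoding to analysis categories happens later, see
#' [recode_evidence()]). Rows whose upstream and downstream event coincide
#' are legitimate self-relationships and are flagged, not rejected.
#'
#' @param path path to a TSV file.
#' @param column_map named character vector mapping `aop`, `upstream`,
#'   `downstream`, `adjacency`, `evidence`, `quant` to the file's headers.
#' @return tibble with columns `aop_id`, `upstream_event`, `downstream_event`,
#'   `adjacency`, `evidence_raw`, `quant_raw`, `self_loop`; attribute
#'   `"errors"` as in [read_ke_dataset()].
#' @export
read_ker_table <- function(path,
                           column_map = c(aop = "aop_id",
                                          upstream = "upstream_event",
                                          downstream = "downstream_event",
                                          adjacency = "adjacency",
                                          evidence = "evidence",
                                          quant = "quantitative_understanding")) {
  tbl <- read_tsv_strict(path)
  if (nrow(tbl) == 0) {
    out <- empty_ker_table()
    attr(out, "errors") <- tibble::tibble(row = integer(), reason = character())
    return(out)
  }
  check_column_map(tbl, column_map,
                   c("aop", "upstream", "downstream", "adjacency", "evidence", "quant"),
                   path)
  raw <- tibble::tibble(
    aop_id = trimws(tbl[[column_map[["aop"]]]]),
    upstream_event = normalise_event_id(tbl[[column_map[["upstream"]]]]),
    downstream_event = normalise_event_id(tbl[[column_map[["downstream"]]]]),
    adjacency = adjacency_alias(tbl[[column_map[["adjacency"]]]]),
    evidence_raw = blank_to_na_label(tbl[[column_map[["evidence"]]]]),
    quant_raw = blank_to_na_label(tbl[[column_map[["quant"]]]])
  )
  bad <- !nzchar(raw$aop_id) | !nzchar(raw$upstream_event) |
    !nzchar(raw$downstream_event) | is.na(raw$adjacency)
  errors <- tibble::tibble(
    row = which(bad),
    reason = dplyr::case_when(
      is.na(raw$adjacency[bad]) ~ "unrecognised adjacency label",
      TRUE ~ "empty identifier"
    )
  )
  out <- raw[!bad, ]
  out$self_loop <- out$upstream_event == out$downstream_event
  attr(out, "errors") <- errors
  out
}

empty_ker_table <- function() {
  tibble::tibble(
    aop_id = character(), upstream_event = character(),
    downstream_event = character(), adjacency = character(),
    evidence_raw = character(), quant_raw = character(),
    self_loop = logical()
  )
}

#' Extract "How It Is Measured or Detected" sections from an XML dump
#'
#' Reads the supported subset of an AOP-Wiki XML release: `<key-event>`
#' elements carrying an `id` attribute and a `<measured>` child with the
#' free-text detection-method section. Requested ids absent from the dump
#' yield an empty-text section flagged `missing`.
#'
#' @param xml_path path to the XML file.
#' @param event_ids character vector of event ids to look up.
#' @return tibble with columns `event_id`, `text`, `missing`, `source`.
#' @export
extract_measurement_sections <- function(xml_path, event_ids) {
  doc <- xml2::read_xml(xml_path) # malformed XML -> xml2 parse error w/ line
  nodes <- xml2::xml_find_all(doc, ".//key-event")
  ids <- normalise_event_id(xml2::xml_attr(nodes, "id"))
  texts <- vapply(nodes, function(nd) {
    m <- xml2::xml_find_first(nd, "./measured")
    if (inherits(m, "xml_missing")) "" else xml2::xml_text(m)
  }, character(1))
  lookup <- setNames(texts, ids)
  event_ids <- normalise_event_id(event_ids)
  found <- event_ids %in% ids
  tibble::tibble(
    event_id = event_ids,
    text = ifelse(found, unname(lookup[event_ids]), ""),
    missing = !found,
    source = "xml"
  )
}

#' Read a key characteristic (KC) mapping table
#'
#' Two-column TSV (`event_id`, `kc_id`) associating key events with key
#' characteristics of cardiovascular toxicants (KC1--KC12); multiple rows per
#' event accumulate into a set.
#'
#' @param path path to a TSV file.
#' @return de-duplicated tibble with columns `event_id`, `kc_id`.
#' @export
read_kc_table <- function(path) {
  tbl <- read_tsv_strict(path)
  if (nrow(tbl) == 0) {
    return(tibble::tibble(event_id = character(), kc_id = character()))
  }
  if (!all(c("event_id", "kc_id") %in% names(tbl))) {
    abort(sprintf("KC table must have columns 'event_id' and 'kc_id'; found: %s",
                  paste(names(tbl), collapse = ", ")))
  }
  out <- tibble::tibble(
    event_id = normalise_event_id(tbl$event_id),
    kc_id = toupper(trimws(tbl$kc_id))
  )
  unknown <- setdiff(unique(out$kc_id), KC_LEVELS)
  if (length(unknown)) {
    abort(sprintf("Unknown KC label(s): %s (must be KC1..KC12)",
                  paste(unknown, collapse = ", ")))
  }
  dplyr::distinct(out)
}

#' Convert a KC table to a per-event set-valued map
#'
#' @param kc_table tibble as returned by [read_kc_table()].
#' @return named list: event id -> character vector of KC ids (sorted).
#' @export
kc_sets <- function(kc_table) {
  if (nrow(kc_table) == 0) return(setNames(list(), character()))
  sp <- split(kc_table$kc_id, kc_table$event_id)
  lapply(sp, function(x) sort(unique(x)))
}

# -- writers (used by the fixture generator and for round-trips) -------------

write_ke_dataset <- function(records, path) {
  readr::write_tsv(records[, c("aop_id", "event_id", "title", "role")], path,
                   quote = "none", progress = FALSE)
}

write_ker_table <- function(kers, path) {
  out <- kers[, c("aop_id", "upstream_event", "downstream_event",
                  "adjacency", "evidence_raw", "quant_raw")]
  names(out)[names(out) == "evidence_raw"] <- "evidence"
  names(out)[names(out) == "quant_raw"] <- "quantitative_understanding"
  readr::write_tsv(out, path, quote = "none", progress = FALSE)
}

write_measurement_xml <- function(sections, path) {
  doc <- xml2::xml_new_root("aop-wiki-dump")
  keep <- sections[!sections$missing & nzchar(sections$text), , drop = FALSE]
  for (i in seq_len(nrow(keep))) {
    ke <- xml2::xml_add_child(doc, "key-event", id = keep$event_id[i])
    xml2::xml_add_child(ke, "measured", keep$text[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

write_kc_table <- function(kc_table, path) {
  readr::write_tsv(kc_table[, c("event_id", "kc_id")], path,
                   quote = "none", progress = FALSE)
}
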