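# Key event harmonisation: collapse duplicated events into canonical nodes
# via an explicit expert merge map, standardise titles, resolve roles and
# AOP membership, and remap relationships onto the canonical roster.

#' Standardise a key event title
#'
#' Trims whitespace and upper-cases the first alphabetic character, keeping
#' internal case untouched. A leading mixed-case token such as `"hERG"`
#' (lowercase letters followed by uppercase, the shape of a gene symbol) is
#' left alone so symbol-initial titles keep their conventional casing.
#' Blank titles and the literal `"NA"` are drop signals, returned as `NA`.
#'
#' @param raw character vector of raw titles.
#' @return character vector; `NA` marks entries to drop.
#' @export
#' @examples
#' standardise_title(c("oxidative stress", "NA", "hERG channel blockade"))
standardise_title <- function(raw) {
  x <- trimws(as.character(raw))
  x[is.na(x) | !nzchar(x) | x == "NA"] <- NA_character_
  vapply(x, function(t) {
    if (is.na(t)) return(NA_character_)
    first_word <- sub("[\\s].*$", "", t, perl = TRUE)
    if (grepl("^[a-z]+[A-Z]", first_word)) return(t) # gene-symbol-style token
    m <- regexpr("[A-Za-z]", t)
    if (m > 0) substr(t, m, m) <- toupper(substr(t, m, m))
    t
  }, character(1), USE.NAMES = FALSE)
}

validate_merge_map <- function(merge_map) {
  if (is.null(merge_map) || nrow(merge_map) == 0) {
    return(tibble::tibble(canonical_title = character(), event_id = character()))
  }
  if (!all(c("canonical_title", "event_id") %in% names(merge_map))) {
    abort("A merge map needs columns 'canonical_title' and 'event_id'.")
  }
  mm <- tibble::tibble(
    canonical_title = standardise_title(merge_map$canonical_title),
    event_id = normalise_event_id(merge_map$event_id)
  )
  if (anyNA(mm$canonical_title)) abort("Merge map canonical titles may not be blank/NA.")
  dup <- mm$event_id[duplicated(mm$event_id)]
  if (length(dup)) {
    abort(sprintf("Merge map is not injective: event id(s) %s appear in more than one entry.",
                  paste(unique(dup), collapse = ", ")))
  }
  mm
}

#' Resolve the role of a merged node
#'
#' Precedence AO > MIE > KE: a node absorbing an adverse outcome stays an
#' adverse outcome (terminal endpoints are preserved); initiating events win
#' over intermediates.
#'
#' @param member_roles character vector of member record roles.
#' @return single role, `"AO"`, `"MIE"` or `"KE"`.
#' @export
resolve_role <- function(member_roles) {
  if (!length(member_roles)) abort("`member_roles` must be non-empty.")
  if (any(member_roles == "AO")) return("AO")
  if (any(member_roles == "MIE")) return("MIE")
  "KE"
}

#' Collapse key event records into canonical harmonised nodes
#'
#' Event ids named in the merge map are grouped under the map's canonical
#' title; all remaining ids become nodes titled by their standardised title.
#' Distinct unmapped ids whose standardised titles collide are treated as
#' duplicates and merged automatically, with a warning. Records whose title
#' standardises to the drop signal are removed (kept in the `"dropped"`
#' attribute); merge map ids absent from the records are reported in the
#' `"unknown_map_ids"` attribute, not an error, since a subset corpus may
#' legitimately lack them.
#'
#' @param records key event records ([read_ke_dataset()] output).
#' @param merge_map tibble with columns `canonical_title`, `event_id`
#'   (or `NULL` for title-only grouping).
#' @return roster tibble, one row per node: `title`, `role`, `member_ids`
#'   (list), `aops` (list), `n_members`, `n_aops`; sorted by title.
#' @export
apply_merge_map <- function(records, merge_map = NULL) {
  mm <- validate_merge_map(merge_map)
  std <- standardise_title(records$title)
  dropped <- records[is.na(std), , drop = FALSE]
  recs <- records[!is.na(std), , drop = FALSE]
  recs$std_title <- std[!is.na(std)]

  unknown <- setdiff(mm$event_id, recs$event_id)
  if (length(unknown)) {
    warn(sprintf("Merge map id(s) not present in the records: %s",
                 paste(unknown, collapse = ", ")))
  }

  if (nrow(recs) == 0) {
    out <- tibble::tibble(title = character(), role = character(),
                          member_ids = list(), aops = list(),
                          n_members = integer(), n_aops = integer())
    attr(out, "dropped") <- dropped
    attr(out, "unknown_map_ids") <- unknown
    return(out)
  }

  # one entity per event id; deterministic representative title
  per_id <- recs |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      own_title = sort(.data$std_title)[1],
      roles = list(.data$role),
      aops = list(sort(unique(.data$aop_id))),
      .groups = "drop"
    )
  canon <- setNames(mm$canonical_title, mm$event_id)
  per_id$canonical <- ifelse(per_id$event_id %in% names(canon),
                             unname(canon[per_id$event_id]), per_id$own_title)

  collided <- per_id |>
    dplyr::filter(!(.data$event_id %in% names(canon))) |>
    dplyr::count(.data$canonical) |>
    dplyr::filter(.data$n > 1)
  if (nrow(collided)) {
    warn(sprintf(
      "Distinct unmapped event ids share a standardised title and were merged: %s",
      paste(collided$canonical, collapse = "; ")
    ))
  }

  out <- per_id |>
    dplyr::group_by(title = .data$canonical) |>
    dplyr::summarise(
      role = resolve_role(unlist(.data$roles)),
      member_ids = list(sort(unique(.data$event_id))),
      aops = list(sort(unique(unlist(.data$aops)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_members = lengths(.data$member_ids),
      n_aops = lengths(.data$aops)
    ) |>
    dplyr::arrange(.data$title)

  attr(out, "dropped") <- dropped
  attr(out, "unknown_map_ids") <- unknown
  out
}

#' Remap key event relationships onto the harmonised roster
#'
#' Replaces raw event-id endpoints with canonical node titles. Relationships
#' whose endpoints merge into the same node become self-loops and are
#' retained. Relationships with an endpoint that resolves to no node are
#' collected in the `"unresolved"` attribute rather than failing the run.
#'
#' @param kers KER records ([read_ker_table()] output).
#' @param roster harmonised roster ([apply_merge_map()] output).
#' @return tibble of remapped relationships: `upstream`, `downstream`
#'   (canonical titles), `adjacency`, `evidence_raw`, `quant_raw`, `aop_id`,
#'   `self_loop`.
#' @export
remap_kers <- function(kers, roster) {
  id2node <- if (nrow(roster)) {
    rep(roster$title, lengths(roster$member_ids)) |>
      setNames(unlist(roster$member_ids))
  } else {
    setNames(character(), character())
  }
  up <- unname(id2node[kers$upstream_event])
  dn <- unname(id2node[kers$downstream_event])
  unresolved <- kers[is.na(up) | is.na(dn), , drop = FALSE]
  keep <- !is.na(up) & !is.na(dn)
  out <- tibble::tibble(
    upstream = up[keep],
    downstream = dn[keep],
    adjacency = kers$adjacency[keep],
    evidence_raw = kers$evidence_raw[keep],
    quant_raw = kers$quant_raw[keep],
    aop_id = kers$aop_id[keep]
  )
  out$self_loop <- out$upstream == out$downstream
  attr(out, "unresolved") <- unresolved
  out
}

#' Harmonise a whole fixture bundle
#'
#' Runs [apply_merge_map()] on the bundle's key event dataset and
#' [remap_kers()] on its relationship table.
#'
#' @param bundle an `aop_bundle` (see [generate_fixture()]).
#' @return list with elements `roster` and `kers`.
#' @export
harmonise_bundle <- function(bundle) {
  roster <- apply_merge_map(bundle$ke_dataset, bundle$merge_map)
  list(roster = roster, kers = remap_kers(bundle$ker_table, roster))
}
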