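# Screening funnel: keyword search over key event titles, a second pass over
# AOP titles, categorised exclusions and explicit expert re-inclusions, with
# the full audit trail kept as sets so the funnel counts always reconstruct.

#' Default cardiotoxicity screening keywords
#'
#' The heart-specific keyword list used to flag candidate AOPs. Vascular
#' keywords are deliberately absent: pathway-level inclusion pulls in linked
#' vascular events once any cardiac event matches.
#'
#' @return character vector of lowercase keywords.
#' @export
cardiotox_keywords <- function() {
  c("heart", "cardio", "cardiac", "ventricular", "ventricle",
    "myocardial", "myocardium", "atrial", "atrio", "atrium")
}

#' Build a screening configuration
#'
#' @param keywords character vector of search terms; matching is
#'   case-insensitive substring matching (so `"cardio"` matches
#'   "Cardiovascular" and `"atrio"` matches "atrioventricular").
#' @param exclusion_rules named list: category label -> character vector of
#'   AOP ids to exclude. Rule order is the precedence order when an id would
#'   match several categories.
#' @param reinclusions character vector of AOP ids to re-include after
#'   exclusion (each must appear in some exclusion rule).
#' @return a `screening_config` list.
#' @export
screening_config <- function(keywords = cardiotox_keywords(),
                             exclusion_rules = list(),
                             reinclusions = character()) {
  if (!length(keywords) || !all(nzchar(keywords))) {
    abort("`keywords` must be a non-empty character vector.")
  }
  if (length(exclusion_rules)) {
    if (is.null(names(exclusion_rules)) || anyDuplicated(names(exclusion_rules)) ||
        any(!nzchar(names(exclusion_rules)))) {
      abort("`exclusion_rules` must be a uniquely named list of id vectors.")
    }
  }
  structure(
    list(keywords = tolower(as.character(keywords)),
         exclusion_rules = lapply(exclusion_rules, as.character),
         reinclusions = as.character(reinclusions)),
    class = "screening_config"
  )
}

title_matches <- function(titles, keywords) {
  lowered <- tolower(as.character(titles))
  hit <- rep(FALSE, length(lowered))
  for (kw in keywords) hit <- hit | grepl(kw, lowered, fixed = TRUE)
  hit
}

#' Keyword screen over key event titles
#'
#' Flags an AOP when at least one of its KE/AO record titles contains at
#' least one keyword (case-insensitive substring). All roles are scanned.
#'
#' @param records key event records ([read_ke_dataset()] output).
#' @param config a [screening_config()].
#' @return sorted character vector of flagged AOP ids.
#' @export
keyword_screen <- function(records, config = screening_config()) {
  if (nrow(records) == 0) return(character())
  hits <- title_matches(records$title, config$keywords)
  sort(unique(records$aop_id[hits]))
}

#' Keyword screen over AOP titles
#'
#' Same matching rule as [keyword_screen()], applied to whole-pathway titles
#' (the manual second pass that catches AOPs whose event titles carry no
#' cardiac keyword).
#'
#' @param aop_titles named character vector: AOP id -> title.
#' @param config a [screening_config()].
#' @return sorted character vector of flagged AOP ids.
#' @export
title_screen <- function(aop_titles, config = screening_config()) {
  if (!length(aop_titles)) return(character())
  if (is.null(names(aop_titles))) abort("`aop_titles` must be named by AOP id.")
  sort(unique(names(aop_titles)[title_matches(aop_titles, config$keywords)]))
}

#' Apply exclusion and re-inclusion rules to screening candidates
#'
#' Every excluded AOP receives exactly one category (first matching rule
#' wins; overlaps raise a warning). Re-included ids must have been excluded
#' first -- re-including a never-excluded id signals a mis-specified
#' configuration and is an error.
#'
#' @param candidates either a character vector of candidate AOP ids, or a
#'   list with elements `keyword` and `title` (ids flagged by each pass).
#' @param config a [screening_config()] carrying `exclusion_rules` and
#'   `reinclusions`.
#' @return a `screening_report` list with sets `candidates_keyword`,
#'   `candidates_title`, `excluded` (named: id -> category), `reincluded`,
#'   `included`, and a `counts` vector reconstructing the funnel.
#' @export
apply_exclusions <- function(candidates, config) {
  if (is.list(candidates)) {
    kw <- sort(unique(as.character(candidates$keyword %||% character())))
    ti <- sort(unique(as.character(candidates$title %||% character())))
  } else {
    kw <- sort(unique(as.character(candidates)))
    ti <- character()
  }
  pool <- sort(union(kw, ti))

  rule_ids <- unique(unlist(config$exclusion_rules, use.names = FALSE))
  bad_reinc <- setdiff(config$reinclusions, rule_ids)
  if (length(bad_reinc)) {
    abort(sprintf("Re-inclusion of id(s) never excluded by any rule: %s",
                  paste(bad_reinc, collapse = ", ")))
  }

  excluded <- character() # named: id -> category
  for (cat in names(config$exclusion_rules)) {
    ids <- intersect(config$exclusion_rules[[cat]], pool)
    overlap <- intersect(ids, names(excluded))
    if (length(overlap)) {
      warn(sprintf("AOP id(s) %s match several exclusion categories; keeping '%s'.",
                   paste(overlap, collapse = ", "), excluded[overlap][1]))
      ids <- setdiff(ids, overlap)
    }
    excluded[ids] <- cat
  }

  reincluded <- intersect(config$reinclusions, names(excluded))
  included <- sort(union(setdiff(pool, names(excluded)), reincluded))

  structure(
    list(
      candidates_keyword = kw,
      candidates_title = ti,
      excluded = excluded[sort(names(excluded))],
      reincluded = sort(reincluded),
      included = included,
      counts = c(
        n_keyword = length(kw),
        n_title = length(ti),
        n_candidates = length(pool),
        n_excluded = length(excluded),
        n_reincluded = length(reincluded),
        n_included = length(included)
      )
    ),
    class = "screening_report"
  )
}

#' Run the complete screening funnel
#'
#' Convenience wrapper: keyword screen over event titles, title screen over
#' AOP titles, then exclusions and re-inclusions.
#'
#' @param records key event records.
#' @param aop_titles named character vector of AOP titles (optional).
#' @param config a [screening_config()].
#' @return a `screening_report`; see [apply_exclusions()].
#' @export
screen_aops <- function(records, aop_titles = character(), config = screening_config()) {
  apply_exclusions(
    list(keyword = keyword_screen(records, config),
         title = title_screen(aop_titles, config)),
    config
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("AOP screening funnel\n")
  cat(sprintf("  keyword candidates : %d\n", x$counts[["n_keyword"]]))
  cat(sprintf("  title candidates   : %d\n", x$counts[["n_title"]]))
  cat(sprintf("  total candidates   : %d\n", x$counts[["n_candidates"]]))
  cat(sprintf("  excluded           : %d\n", x$counts[["n_excluded"]]))
  cat(sprintf("  re-included        : %d\n", x$counts[["n_reincluded"]]))
  cat(sprintf("  included           : %d\n", x$counts[["n_included"]]))
  invisible(x)
}

#' Documented cardiotoxicity screening inputs
#'
#' The AOP-Wiki screening of August 2025 for cardiotoxicity, as recorded in
#' the published curation: 19 AOPs flagged by the key event keyword search,
#' 3 more by the AOP title search, five exclusion categories, and one
#' expert re-inclusion (AOP:448, whose relationships are described in an
#' associated publication rather than in the wiki entry).
#'
#' @return list with elements `keyword`, `title` (candidate id vectors) and
#'   a ready-made `config` ([screening_config()]).
#' @export
cardiotox_screening_inputs <- function() {
  keyword <- paste0("AOP:", c(16, 21, 94, 104, 138, 150, 177, 186, 261, 304,
                              377, 426, 427, 433, 436, 456, 479, 480, 539))
  title <- paste0("AOP:", c(438, 448, 515))
  config <- screening_config(
    exclusion_rules = list(
      "lack of KER information" = paste0("AOP:", c(186, 377, 448)),
      "all rights reserved"     = paste0("AOP:", c(438, 515)),
      "COVID-19 related"        = paste0("AOP:", c(426, 427)),
      "vasculature and development related" = paste0("AOP:", c(304, 436)),
      "fish specific"           = "AOP:539"
    ),
    reinclusions = "AOP:448"
  )
  list(keyword = keyword, title = title, config = config)
}
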