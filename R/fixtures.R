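# Seeded generator of AOP-Wiki-like fixture collections. Every downstream
# stage of the pipeline is testable offline against these bundles.
#
# Topology model: each AOP is a backbone chain MIE -> KE ... -> AO (so at
# least one source-to-sink path always exists), plus optional within-AOP
# skip edges emitted as non-adjacent relationships. Key events are drawn
# from a cross-AOP shared pool with a configurable probability, which is
# what creates multi-AOP hub nodes after harmonisation.

#' Specify a synthetic AOP fixture
#'
#' @param n_aops number of AOPs to generate.
#' @param events_per_aop integer range `c(min, max)` of events per AOP
#'   backbone (minimum 3: MIE, at least one KE, AO).
#' @param ke_share_prob probability that a backbone event is drawn from the
#'   pool of events already minted for earlier AOPs (role-matched) rather
#'   than newly minted.
#' @param adjacency_fraction fraction of emitted relationships that are
#'   adjacent; the complement is generated as non-adjacent skip edges.
#' @param evidence named numeric vector over the raw evidence vocabulary
#'   (`High`, `Strong`, `Moderate`, `Low`, `Not Specified`, `NA`): either
#'   sampling probabilities (values in [0,1], summing to 1) or exact counts
#'   (which must sum to the number of generated relationship rows).
#' @param quant same, for quantitative understanding.
#' @param methods_coverage fraction of unique event ids given a non-empty
#'   measurement section.
#' @param kc_coverage fraction of unique event ids mapped to at least one
#'   key characteristic.
#' @param seed integer RNG seed; fixed seed implies byte-identical bundles.
#' @return a validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_aops = 13,
                         events_per_aop = c(5, 9),
                         ke_share_prob = 0.2,
                         adjacency_fraction = 0.86,
                         evidence = c(High = 0.30, Strong = 0.24,
                                      Moderate = 0.16, Low = 0.04,
                                      "Not Specified" = 0.13, "NA" = 0.13),
                         quant = c(High = 0.13, Strong = 0.0,
                                   Moderate = 0.14, Low = 0.10,
                                   "Not Specified" = 0.35, "NA" = 0.28),
                         methods_coverage = 0.44,
                         kc_coverage = 0.78,
                         seed = 1L) {
  assert_scalar_count(n_aops, "n_aops")
  if (n_aops < 1) abort("`n_aops` must be positive.")
  if (length(events_per_aop) != 2 || any(events_per_aop < 3) ||
      events_per_aop[1] > events_per_aop[2]) {
    abort("`events_per_aop` must be a range c(min, max) with min >= 3.")
  }
  assert_probability(ke_share_prob, "ke_share_prob")
  assert_probability(adjacency_fraction, "adjacency_fraction")
  if (adjacency_fraction <= 0) abort("`adjacency_fraction` must be > 0.")
  assert_probability(methods_coverage, "methods_coverage")
  assert_probability(kc_coverage, "kc_coverage")
  for (nm in c("evidence", "quant")) {
    v <- get(nm)
    if (is.null(names(v)) || any(!nzchar(names(v))) || any(v < 0)) {
      abort(sprintf("`%s` must be a named non-negative vector.", nm))
    }
  }
  assert_scalar_count(seed, "seed")
  structure(
    list(n_aops = as.integer(n_aops),
         events_per_aop = as.integer(events_per_aop),
         ke_share_prob = ke_share_prob,
         adjacency_fraction = adjacency_fraction,
         evidence = evidence, quant = quant,
         methods_coverage = methods_coverage,
         kc_coverage = kc_coverage,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

label_vector <- function(weights, n, what) {
  if (any(weights > 1) || isTRUE(all.equal(sum(weights), round(sum(weights)))) &&
      sum(weights) > 1.5) {
    counts <- setNames(as.integer(round(weights)), names(weights))
    if (sum(counts) != n) {
      abort(sprintf(
        "`%s` given as counts must sum to the number of KER rows (%d), got %d.",
        what, n, sum(counts)))
    }
    sample(rep(names(counts), counts))
  } else {
    sample(names(weights), n, replace = TRUE, prob = weights)
  }
}

#' Generate a synthetic AOP fixture bundle
#'
#' Deterministic for a fixed seed. The bundle satisfies referential
#' integrity (every relationship endpoint appears in the key events
#' dataset) and every AOP has at least one MIE-to-AO directed path by
#' construction.
#'
#' @param spec a [fixture_spec()].
#' @return an `aop_bundle`: list with tibbles `ke_dataset`, `ker_table`,
#'   `measurement_sections`, `kc_table`, `merge_map` and a `manifest` list.
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) spec <- do.call(fixture_spec, spec)
  with_preserved_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  counter <- 9000L
  mint <- function(role) {
    counter <<- counter + 1L
    id <- sprintf("KE%d", counter)
    title <- sprintf("%s event %s",
                     c(MIE = "Initiating", KE = "Intermediate", AO = "Outcome")[[role]],
                     id)
    list(id = id, title = title, role = role)
  }
  pool <- list(MIE = list(), KE = list(), AO = list())

  ke_rows <- list()
  ker_rows <- list()
  for (a in seq_len(spec$n_aops)) {
    aop_id <- sprintf("AOP:9%02d", a)
    sizes <- seq(spec$events_per_aop[1], spec$events_per_aop[2])
    L <- sizes[sample.int(length(sizes), 1)]
    roles <- c("MIE", rep("KE", L - 2), "AO")
    chain <- vector("list", L)
    for (i in seq_len(L)) {
      role <- roles[i]
      reuse <- length(pool[[role]]) > 0 &&
        stats::runif(1) < spec$ke_share_prob
      ev <- NULL
      if (reuse) {
        in_chain <- vapply(chain[seq_len(i - 1)],
                           function(e) if (is.null(e)) "" else e$id, character(1))
        avail <- Filter(function(e) !(e$id %in% in_chain), pool[[role]])
        if (length(avail)) ev <- avail[[sample.int(length(avail), 1)]]
      }
      if (is.null(ev)) {
        ev <- mint(role)
        pool[[role]] <- c(pool[[role]], list(ev))
      }
      chain[[i]] <- ev
    }
    ke_rows[[a]] <- tibble::tibble(
      aop_id = aop_id,
      event_id = vapply(chain, `[[`, character(1), "id"),
      title = vapply(chain, `[[`, character(1), "title"),
      role = roles
    )
    ids <- ke_rows[[a]]$event_id
    edges <- tibble::tibble(
      aop_id = aop_id,
      upstream_event = ids[-L],
      downstream_event = ids[-1],
      adjacency = "adjacent"
    )
    n_skip <- round((L - 1) * (1 - spec$adjacency_fraction) /
                      spec$adjacency_fraction)
    if (n_skip > 0 && L >= 3) {
      starts <- sample(seq_len(L - 2), min(n_skip, L - 2))
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        aop_id = aop_id,
        upstream_event = ids[starts],
        downstream_event = ids[starts + 2],
        adjacency = "non-adjacent"
      ))
    }
    ker_rows[[a]] <- edges
  }
  ke_dataset <- dplyr::bind_rows(ke_rows)
  ker_table <- dplyr::bind_rows(ker_rows)
  n_kers <- nrow(ker_table)
  ker_table$evidence_raw <- blank_to_na_label(
    label_vector(spec$evidence, n_kers, "evidence"))
  ker_table$quant_raw <- blank_to_na_label(
    label_vector(spec$quant, n_kers, "quant"))
  ker_table$self_loop <- ker_table$upstream_event == ker_table$downstream_event

  ids <- sort(unique(ke_dataset$event_id))
  n_methods <- round(spec$methods_coverage * length(ids))
  with_methods <- sort(sample(ids, n_methods))
  assay_texts <- c(
    "Quantified by ELISA in cardiomyocyte culture supernatants.",
    "Whole-cell patch clamp recording of ionic currents.",
    "Echocardiography under anaesthesia; ejection fraction readout.",
    "Computational model simulation of channel kinetics.",
    "Histopathology of cardiac tissue sections at necropsy."
  )
  measurement_sections <- tibble::tibble(
    event_id = ids,
    text = ifelse(ids %in% with_methods,
                  assay_texts[(match(ids, with_methods) - 1) %% length(assay_texts) + 1],
                  ""),
    missing = !(ids %in% with_methods),
    source = "xml"
  )

  n_kc <- round(spec$kc_coverage * length(ids))
  kc_ids <- sort(sample(ids, n_kc))
  kc_table <- if (length(kc_ids)) {
    dplyr::bind_rows(lapply(seq_along(kc_ids), function(i) {
      k <- sample(KC_LEVELS, sample(1:3, 1))
      tibble::tibble(event_id = kc_ids[i], kc_id = sort(k))
    }))
  } else {
    tibble::tibble(event_id = character(), kc_id = character())
  }

  structure(
    list(
      ke_dataset = ke_dataset,
      ker_table = ker_table,
      measurement_sections = measurement_sections,
      kc_table = kc_table,
      merge_map = tibble::tibble(canonical_title = character(),
                                 event_id = character()),
      manifest = list(
        generator = "aopnet::generate_fixture",
        spec = unclass(spec),
        n_ke_rows = nrow(ke_dataset),
        n_ker_rows = n_kers,
        n_unique_events = length(ids)
      )
    ),
    class = "aop_bundle"
  )
}

#' @export
print.aop_bundle <- function(x, ...) {
  cat(sprintf(
    "AOP fixture bundle: %d KE rows (%d unique events, %d AOPs), %d KER rows\n",
    nrow(x$ke_dataset), length(unique(x$ke_dataset$event_id)),
    length(unique(x$ke_dataset$aop_id)), nrow(x$ker_table)))
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Emits the bundle in the package's default dialect: `ke_dataset.tsv`,
#' `ker_table.tsv`, `measurements.xml`, `kc_table.tsv`, `merge_map.tsv` and
#' `manifest.json`. The files round-trip losslessly through
#' [read_fixture()].
#'
#' @param bundle an `aop_bundle`.
#' @param dir output directory (created if missing).
#' @param dialect file dialect; only `"default"` is currently defined.
#' @return named vector of written paths, invisibly.
#' @export
write_fixture <- function(bundle, dir, dialect = "default") {
  if (!identical(dialect, "default")) {
    abort(sprintf("Unknown dialect '%s'.", dialect))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    ke_dataset = file.path(dir, "ke_dataset.tsv"),
    ker_table = file.path(dir, "ker_table.tsv"),
    measurements = file.path(dir, "measurements.xml"),
    kc_table = file.path(dir, "kc_table.tsv"),
    merge_map = file.path(dir, "merge_map.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_ke_dataset(bundle$ke_dataset, paths[["ke_dataset"]])
  write_ker_table(bundle$ker_table, paths[["ker_table"]])
  write_measurement_xml(bundle$measurement_sections, paths[["measurements"]])
  write_kc_table(bundle$kc_table, paths[["kc_table"]])
  readr::write_tsv(bundle$merge_map, paths[["merge_map"]], quote = "none",
                   progress = FALSE)
  writeLines(jsonlite::toJSON(bundle$manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             paths[["manifest"]])
  invisible(paths)
}

#' Read a fixture bundle written by [write_fixture()]
#'
#' @param dir directory holding the fixture files.
#' @return an `aop_bundle`.
#' @export
read_fixture <- function(dir) {
  ke <- read_ke_dataset(file.path(dir, "ke_dataset.tsv"))
  ker <- read_ker_table(file.path(dir, "ker_table.tsv"))
  attr(ke, "errors") <- NULL
  attr(ker, "errors") <- NULL
  sections <- extract_measurement_sections(file.path(dir, "measurements.xml"),
                                           sort(unique(ke$event_id)))
  kc <- read_kc_table(file.path(dir, "kc_table.tsv"))
  mm_path <- file.path(dir, "merge_map.tsv")
  mm <- if (file.exists(mm_path)) {
    tbl <- read_tsv_strict(mm_path)
    tibble::tibble(
      canonical_title = if ("canonical_title" %in% names(tbl))
        as.character(tbl$canonical_title) else character(),
      event_id = if ("event_id" %in% names(tbl))
        as.character(tbl$event_id) else character()
    )
  } else {
    tibble::tibble(canonical_title = character(), event_id = character())
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(
    list(ke_dataset = ke, ker_table = ker, measurement_sections = sections,
         kc_table = kc, merge_map = mm, manifest = manifest),
    class = "aop_bundle"
  )
}
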