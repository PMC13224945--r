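test_that("evidence recoding groups the raw vocabulary as documented", {
  expect_equal(recode_evidence(c("Strong", "High", "moderate", "LOW")),
               c("High", "High", "Moderate", "Low"))
  expect_equal(recode_evidence(c("NA", "", "Not Specified", "n/a")),
               rep("Not Specified", 4))
  expect_warning(out <- recode_evidence("Weak-ish"), "Unknown")
  expect_equal(out, "Not Specified")
  # idempotent and total: recoding the categories returns the categories
  cats <- c("High", "Moderate", "Low", "Not Specified")
  expect_equal(recode_evidence(cats), cats)
})

test_that("quantitative understanding recodes the same way and flags quantified edges", {
  expect_equal(recode_quant("Strong"), "High")
  expect_equal(has_quant(c("High", "Low", "Not Specified")),
               c(TRUE, TRUE, FALSE))
})

test_that("KC coverage unions member-id mappings and reports absent KCs", {
  roster <- tibble::tibble(
    title = c("Merged", "Solo", "Unmapped"), role = "KE",
    member_ids = list(c("KE1", "KE2"), "KE3", "KE4"),
    aops = list("AOP:1", "AOP:1", "AOP:1")
  )
  net <- aop_network(roster, tibble::tibble(
    upstream = "Merged", downstream = "Solo", adjacency = "adjacent"))
  kc <- kc_coverage(net, tibble::tibble(
    event_id = c("KE1", "KE2", "KE2", "KE3"),
    kc_id = c("KC1", "KC1", "KC8", "KC10")))
  expect_equal(kc$per_node$kcs[kc$per_node$title == "Merged"][[1]],
               c("KC1", "KC8"))
  expect_equal(kc$n_mapped, 2)
  expect_equal(kc$n_unmapped, 1)
  expect_true("KC7" %in% kc$absent_kcs)
  expect_false("KC8" %in% kc$absent_kcs)
  # empty mapping: nothing mapped
  expect_equal(kc_coverage(net, tibble::tibble(event_id = character(),
                                               kc_id = character()))$n_mapped, 0)
})

test_that("method catalogue concatenates member texts with provenance and tags modalities", {
  roster <- tibble::tibble(
    title = c("Merged", "Empty"), role = "KE",
    member_ids = list(c("KE1", "KE2"), "KE3"),
    aops = list("AOP:1", "AOP:1")
  )
  net <- aop_network(roster, tibble::tibble(
    upstream = "Merged", downstream = "Empty", adjacency = "adjacent"))
  sections <- tibble::tibble(
    event_id = c("KE1", "KE2", "KE3"),
    text = c("Whole-cell patch clamp recording.",
             "Echocardiography in anaesthetised animals.", "   ")
  )
  cat_tbl <- build_method_catalogue(net, sections)
  merged <- cat_tbl[cat_tbl$title == "Merged", ]
  expect_true(merged$has_method)
  expect_match(merged$measurement_text, "\\[KE1\\]")
  expect_match(merged$measurement_text, "\\[KE2\\]")
  expect_setequal(merged$modalities[[1]], c("in vitro", "in vivo"))
  expect_false(cat_tbl$has_method[cat_tbl$title == "Empty"])
  expect_equal(attr(cat_tbl, "coverage")$n_with_method, 1)

  # member-id order cannot change the coverage count
  roster2 <- roster
  roster2$member_ids <- list(c("KE2", "KE1"), "KE3")
  net2 <- aop_network(roster2, net$edges)
  expect_equal(attr(build_method_catalogue(net2, sections), "coverage"),
               attr(cat_tbl, "coverage"))
})

test_that("summary report percentages recompute from counts and sum to 100", {
  b <- generate_fixture(fixture_spec(n_aops = 8, ke_share_prob = 0.3, seed = 12))
  h <- harmonise_bundle(b)
  net <- build_network(h$roster, h$kers)
  m <- network_metrics(net)
  rep <- summary_report(net, metrics = m, kc_table = b$kc_table,
                        sections = b$measurement_sections)
  n_e <- nrow(net$edges)
  expect_equal(rep$evidence$pct,
               round_half_up(100 * rep$evidence$counts / n_e, 2))
  expect_lt(abs(sum(rep$evidence$pct) - 100), 0.02 + 1e-9)
  expect_equal(sum(rep$evidence$counts), n_e)
  expect_equal(sum(rep$flow$counts), nrow(net$nodes))
  expect_equal(rep$quant$n_any, sum(has_quant(net$edges$quant)))
  js <- report_json(rep)
  expect_true(jsonlite::validate(js))
})

test_that("empty networks summarise to zero counts and null percentages", {
  net <- build_network(tibble::tibble(title = character(), role = character()),
                       tibble::tibble())
  rep <- summary_report(net)
  expect_equal(sum(rep$evidence$counts), 0)
  expect_true(all(is.na(rep$evidence$pct)))
})

test_that("exports produce the declared formats and GraphML round-trips", {
  b <- cardiotox_composition_fixture()
  h <- harmonise_bundle(b)
  net <- build_network(h$roster, h$kers)

  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, format = "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(net$edges))
  expect_true(all(grepl("\t(adjacent|non-adjacent)\t", lines)))

  ov <- tempfile(fileext = ".tsv")
  export_network(net, ov, format = "overlay", overlay_attribute = "evidence")
  head4 <- readLines(ov, n = 4)
  expect_match(head4[1], "^#VERSION=")
  expect_match(head4[2], "^#NAME=")
  expect_match(head4[3], "^#DESCRIPTION=")
  expect_equal(head4[4], "name\tvalue\tcolor")
  body <- readr::read_tsv(ov, skip = 3, show_col_types = FALSE)
  expect_lte(length(unique(body$color)), 4) # one colour per category at most
  expect_equal(nrow(body), nrow(net$edges))

  ovn <- tempfile(fileext = ".tsv")
  export_network(net, ovn, format = "overlay", overlay_attribute = "role",
                 drop_self_loops = TRUE)
  expect_equal(nrow(readr::read_tsv(ovn, skip = 3, show_col_types = FALSE)),
               nrow(net$nodes))

  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, format = "graphml")
  back <- read_graphml_network(gml)
  expect_equal(back$nodes, net$nodes[, names(back$nodes)])
  expect_equal(back$edges[, c("upstream", "downstream", "adjacency",
                              "evidence", "quant", "source_aops")],
               net$edges[, c("upstream", "downstream", "adjacency",
                             "evidence", "quant", "source_aops")])

  expect_error(export_network(net, tempfile(), format = "dot"))

  one <- toy_network("A", "B")
  sif1 <- tempfile()
  export_network(one, sif1, format = "sif")
  expect_equal(length(readLines(sif1)), 1)
})
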