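test_that("fixture specs validate their fields", {
  expect_error(fixture_spec(n_aops = 0), "positive")
  expect_error(fixture_spec(ke_share_prob = 1.2), "probability")
  expect_error(fixture_spec(events_per_aop = c(2, 5)), "min >= 3")
  expect_error(fixture_spec(evidence = c(0.5, 0.5)), "named")
  expect_s3_class(fixture_spec(), "fixture_spec")
})

test_that("generation is deterministic and respects structural knobs", {
  sp <- fixture_spec(n_aops = 5, events_per_aop = c(4, 6), seed = 7)
  b1 <- generate_fixture(sp)
  b2 <- generate_fixture(sp)
  expect_identical(b1, b2)
  expect_equal(length(unique(b1$ke_dataset$aop_id)), 5)

  # sharing disabled: no event id in more than one AOP
  b0 <- generate_fixture(fixture_spec(n_aops = 6, ke_share_prob = 0, seed = 2))
  memb <- unique(b0$ke_dataset[, c("aop_id", "event_id")])
  expect_true(all(table(memb$event_id) == 1))

  # referential integrity: no dangling ids in the KER table
  expect_true(all(b1$ker_table$upstream_event %in% b1$ke_dataset$event_id))
  expect_true(all(b1$ker_table$downstream_event %in% b1$ke_dataset$event_id))
})

test_that("every generated AOP has an MIE-to-AO path and roles at both ends", {
  b <- generate_fixture(fixture_spec(n_aops = 8, ke_share_prob = 0.35, seed = 4))
  for (aop in unique(b$ke_dataset$aop_id)) {
    rows <- b$ke_dataset[b$ke_dataset$aop_id == aop, ]
    expect_true(any(rows$role == "MIE"))
    expect_true(any(rows$role == "AO"))
    kers <- b$ker_table[b$ker_table$aop_id == aop & b$ker_table$adjacency == "adjacent", ]
    g <- igraph::graph_from_data_frame(
      kers[, c("upstream_event", "downstream_event")], directed = TRUE)
    mie <- intersect(rows$event_id[rows$role == "MIE"], igraph::V(g)$name)
    ao <- intersect(rows$event_id[rows$role == "AO"], igraph::V(g)$name)
    d <- igraph::distances(g, v = mie, to = ao, mode = "out")
    expect_true(any(is.finite(d)))
  }
})

test_that("categorical counts are hit exactly when given as counts", {
  sp <- fixture_spec(n_aops = 3, events_per_aop = c(4, 4),
                     adjacency_fraction = 1, seed = 5)
  n_rows <- nrow(generate_fixture(sp)$ker_table) # 9 chain edges
  counts <- c(High = n_rows - 4, Strong = 2, Moderate = 1,
              Low = 0, "Not Specified" = 1, "NA" = 0)
  sp2 <- fixture_spec(n_aops = 3, events_per_aop = c(4, 4),
                      adjacency_fraction = 1, evidence = counts, seed = 5)
  b <- generate_fixture(sp2)
  tab <- table(b$ker_table$evidence_raw)
  expect_equal(unname(tab[["High"]]), n_rows - 4)
  expect_equal(unname(tab[["Strong"]]), 2)
  bad <- counts
  bad[["High"]] <- bad[["High"]] + 1
  expect_error(
    generate_fixture(fixture_spec(n_aops = 3, events_per_aop = c(4, 4),
                                  adjacency_fraction = 1, evidence = bad,
                                  seed = 5)),
    "must sum"
  )
})

test_that("probability-mode categorical draws land within binomial 99% bounds", {
  sp <- fixture_spec(n_aops = 40, events_per_aop = c(6, 6),
                     adjacency_fraction = 1,
                     evidence = c(High = 0.5, Strong = 0, Moderate = 0.5,
                                  Low = 0, "Not Specified" = 0, "NA" = 0),
                     seed = 31)
  b <- generate_fixture(sp)
  n <- nrow(b$ker_table)
  k <- sum(b$ker_table$evidence_raw == "High")
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("bundles round-trip losslessly through the io dialect", {
  b <- generate_fixture(fixture_spec(n_aops = 4, ke_share_prob = 0.25, seed = 8))
  dir <- withr::local_tempdir()
  write_fixture(b, dir)
  rb <- read_fixture(dir)
  expect_equal(rb$ke_dataset, b$ke_dataset, ignore_attr = TRUE)
  expect_equal(rb$ker_table, b$ker_table, ignore_attr = TRUE)
  expect_equal(rb$measurement_sections, b$measurement_sections)
  expect_equal(rb$kc_table, b$kc_table)
  expect_equal(rb$merge_map, b$merge_map)
  expect_error(write_fixture(b, dir, dialect = "exotic"), "dialect")
})

test_that("an empty bundle writes valid header-only files", {
  b <- generate_fixture(fixture_spec(n_aops = 1, events_per_aop = c(3, 3), seed = 1))
  b$ke_dataset <- b$ke_dataset[0, ]
  b$ker_table <- b$ker_table[0, ]
  b$kc_table <- b$kc_table[0, ]
  b$measurement_sections <- b$measurement_sections[0, ]
  dir <- withr::local_tempdir()
  write_fixture(b, dir)
  expect_equal(nrow(read_ke_dataset(file.path(dir, "ke_dataset.tsv"))), 0)
  expect_equal(nrow(read_ker_table(file.path(dir, "ker_table.tsv"))), 0)
})

test_that("the composition fixture round-trips and matches its documented shape", {
  b <- cardiotox_composition_fixture()
  expect_equal(nrow(b$ke_dataset), 96)
  expect_equal(length(unique(b$ke_dataset$event_id)), 71)
  expect_equal(nrow(b$ker_table), 96)
  dir <- withr::local_tempdir()
  write_fixture(b, dir)
  rb <- read_fixture(dir)
  expect_equal(nrow(rb$ker_table), 96)
  expect_equal(rb$ke_dataset, b$ke_dataset, ignore_attr = TRUE)
  # the 13th AOP is the deliberate exception lacking MIE/AO annotations
  roles_by_aop <- split(b$ke_dataset$role, b$ke_dataset$aop_id)
  no_mie_ao <- names(roles_by_aop)[vapply(roles_by_aop, function(r)
    !any(r == "MIE") && !any(r == "AO"), logical(1))]
  expect_equal(no_mie_ao, "AOP:913")
})
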