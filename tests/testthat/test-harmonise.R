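test_that("title standardisation capitalises, trims and drops NA entries", {
  expect_equal(standardise_title("oxidative stress"), "Oxidative stress")
  expect_equal(standardise_title("  cell injury  "), "Cell injury")
  expect_true(is.na(standardise_title("NA")))
  expect_true(is.na(standardise_title("  ")))
  # gene-symbol-initial titles keep their conventional casing
  expect_equal(standardise_title("hERG channel blockade"), "hERG channel blockade")
  expect_equal(standardise_title("(+)-blocker binding"), "(+)-Blocker binding")
})

test_that("role resolution prefers AO over MIE over KE", {
  expect_equal(resolve_role(c("AO", "KE", "KE")), "AO")
  expect_equal(resolve_role(c("MIE", "KE")), "MIE")
  expect_equal(resolve_role("KE"), "KE")
  expect_error(resolve_role(character()))
})

mk_records <- function(...) {
  rows <- list(...)
  tibble::tibble(
    aop_id = vapply(rows, `[[`, character(1), 1),
    event_id = vapply(rows, `[[`, character(1), 2),
    title = vapply(rows, `[[`, character(1), 3),
    role = vapply(rows, `[[`, character(1), 4)
  )
}

test_that("merge map groups member ids under one canonical node", {
  recs <- mk_records(
    c("AOP:261", "KE1535", "Heart failure", "AO"),
    c("AOP:433", "KE1964", "Sudden cardiac death", "AO"),
    c("AOP:261", "KE1", "Decrease, cardiac contractility", "KE")
  )
  mm <- tibble::tibble(canonical_title = c("Heart failure", "Heart failure"),
                       event_id = c("KE1535", "KE 1964"))
  roster <- apply_merge_map(recs, mm)
  expect_equal(nrow(roster), 2)
  hf <- roster[roster$title == "Heart failure", ]
  expect_equal(hf$member_ids[[1]], c("KE1535", "KE1964"))
  expect_equal(hf$role, "AO")
  expect_setequal(hf$aops[[1]], c("AOP:261", "AOP:433"))
})

test_that("unmapped ids become singleton nodes; NA titles are dropped; unknown map ids warn", {
  recs <- mk_records(
    c("AOP:1", "KE1", "alpha event", "KE"),
    c("AOP:2", "KE2", "Beta event", "KE"),
    c("AOP:2", "KE3", "NA", "KE")
  )
  roster <- apply_merge_map(recs, NULL)
  expect_equal(roster$title, c("Alpha event", "Beta event"))
  expect_equal(nrow(attr(roster, "dropped")), 1)
  expect_warning(
    apply_merge_map(recs, tibble::tibble(canonical_title = "X", event_id = "KE99")),
    "not present"
  )
})

test_that("distinct unmapped ids with colliding standardised titles auto-merge with a warning", {
  recs <- mk_records(
    c("AOP:1", "KE1", "oxidative stress", "KE"),
    c("AOP:2", "KE2", "Oxidative stress", "KE")
  )
  expect_warning(roster <- apply_merge_map(recs, NULL), "merged")
  expect_equal(nrow(roster), 1)
  expect_equal(roster$member_ids[[1]], c("KE1", "KE2"))
})

test_that("merge map injectivity is enforced", {
  recs <- mk_records(c("AOP:1", "KE1", "A", "KE"))
  mm <- tibble::tibble(canonical_title = c("X", "Y"), event_id = c("KE1", "KE1"))
  expect_error(apply_merge_map(recs, mm), "injective")
})

test_that("harmonisation conserves ids and membership grows monotonically", {
  b <- generate_fixture(fixture_spec(n_aops = 8, ke_share_prob = 0.4, seed = 5))
  roster <- apply_merge_map(b$ke_dataset, b$merge_map)
  expect_equal(sum(lengths(roster$member_ids)),
               length(unique(b$ke_dataset$event_id)))
  expect_true(all(lengths(roster$aops) >= 1))
  expect_true(nrow(roster) <= length(unique(b$ke_dataset$event_id)))
})

test_that("harmonisation is idempotent", {
  b <- generate_fixture(fixture_spec(n_aops = 6, ke_share_prob = 0.3, seed = 9))
  roster <- apply_merge_map(b$ke_dataset, b$merge_map)
  # rebuild a record table from the harmonised roster and re-harmonise
  rerecs <- tidyr::unnest(
    tibble::tibble(
      title = roster$title, role = roster$role,
      event_id = roster$member_ids, aop_id = roster$aops
    ),
    cols = c("event_id")
  ) |> tidyr::unnest(cols = c("aop_id"))
  roster2 <- apply_merge_map(rerecs[, c("aop_id", "event_id", "title", "role")],
                             b$merge_map)
  expect_equal(roster2, roster, ignore_attr = TRUE)
})

test_that("relationship remapping produces self-loops for merged endpoints and reports unresolved", {
  recs <- mk_records(
    c("AOP:261", "KE1535", "Heart failure", "AO"),
    c("AOP:433", "KE1964", "Sudden cardiac death", "AO")
  )
  mm <- tibble::tibble(canonical_title = c("Heart failure", "Heart failure"),
                       event_id = c("KE1535", "KE1964"))
  roster <- apply_merge_map(recs, mm)
  kers <- tibble::tibble(
    aop_id = c("AOP:433", "AOP:433"),
    upstream_event = c("KE1535", "KE1535"),
    downstream_event = c("KE1964", "KE404"),
    adjacency = "adjacent",
    evidence_raw = "High", quant_raw = "NA",
    self_loop = FALSE
  )
  out <- remap_kers(kers, roster)
  expect_equal(nrow(out), 1)
  expect_true(out$self_loop)
  expect_equal(out$upstream, "Heart failure")
  expect_equal(nrow(attr(out, "unresolved")), 1)
})
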