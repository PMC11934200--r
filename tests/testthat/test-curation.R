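mk_records <- function(smiles, labels, task = "NR-AR") {
  df <- data.frame(mol_id = sprintf("M%02d", seq_along(smiles)),
                   smiles = smiles, stringsAsFactors = FALSE)
  df[[task]] <- labels
  df
}

test_that("conflicting labels drop the whole identity group", {
  rec <- mk_records(c("CCO", "OCC"), c(0L, 1L))
  out <- suppressWarnings(curate_task(rec, "NR-AR"))
  expect_equal(nrow(out$records), 0)
  expect_equal(out$audit$unmatched_labels, 2)
  expect_equal(out$audit$final, 0)
})

test_that("matching-label duplicates keep only the first occurrence", {
  rec <- mk_records(c("CCO", "OCC", "C(C)O"), c(1L, 1L, 1L))
  out <- curate_task(rec, "NR-AR")
  expect_equal(nrow(out$records), 1)
  expect_identical(out$records$mol_id, "M01")
  expect_equal(out$audit$duplicates_removed, 2)
  expect_equal(out$audit$duplicate_groups, 1)
})

test_that("clean unique input passes through untouched", {
  rec <- mk_records(c("CCO", "CCN", "CCC"), c(1L, 0L, 1L))
  out <- curate_task(rec, "NR-AR")
  expect_identical(out$records[, names(rec)], rec)
  expect_equal(out$audit$no_data, 0)
  expect_equal(out$audit$salts_complexes, 0)
  expect_equal(out$audit$unmatched_labels, 0)
  expect_equal(out$audit$duplicates_removed, 0)
})

test_that("missing labels and salts are removed and counted", {
  rec <- mk_records(c("CCO", "CCN", "CC(=O)[O-].[Na+]", "CCC"),
                    c(1L, NA, 1L, 0L))
  out <- curate_task(rec, "NR-AR")
  expect_equal(out$audit$no_data, 1)
  expect_equal(out$audit$salts_complexes, 1)
  expect_equal(out$audit$final, 2)
  expect_setequal(out$records$mol_id, c("M01", "M04"))
})

test_that("unparseable records are dropped, counted, and reported by id", {
  rec <- mk_records(c("CCO", "not-a-molecule", "CCC"), c(1L, 1L, 0L))
  expect_warning(out <- curate_task(rec, "NR-AR"), "unparseable")
  expect_equal(out$audit$parse_failures, 1)
  expect_identical(out$audit$parse_failure_ids, "M02")
  expect_equal(out$audit$final, 2)
})

test_that("curation is idempotent and conserves the audit identity", {
  inj <- fx_injected()$injected
  once <- curate_task(inj$records, "NR-AR")
  twice <- curate_task(once$records, "NR-AR")
  expect_identical(once$records, twice$records)
  expect_equal(twice$audit$final, twice$audit$initial)
  a <- once$audit
  expect_equal(a$initial - a$no_data - a$parse_failures - a$salts_complexes -
                 a$unmatched_labels - a$duplicates_removed, a$final)
})

test_that("removal counts match the injection audit exactly", {
  fx <- fx_injected()
  out <- curate_task(fx$injected$records, "NR-AR")
  audit <- fx$injected$injection_audit
  expect_equal(out$audit$duplicates_removed, audit$n_dup)
  expect_equal(out$audit$unmatched_labels, 2 * audit$n_conflict)
  expect_equal(out$audit$salts_complexes, audit$n_salt)
  expect_equal(out$audit$final,
               nrow(fx$base) - audit$n_conflict - audit$n_salt)
})

test_that("pairwise fingerprint identity agrees with canonical identity", {
  rec <- mk_records(c("CCO", "OCC", "CCN", "c1ccccc1C", "Cc1ccccc1"),
                    c(1L, 1L, 0L, 1L, 1L))
  fast <- curate_task(rec, "NR-AR", pairwise = FALSE)
  slow <- curate_task(rec, "NR-AR", pairwise = TRUE)
  expect_identical(fast$records, slow$records)
  expect_equal(fast$audit$duplicates_removed, slow$audit$duplicates_removed)
})

test_that("multi-task tables are audited per task", {
  df <- data.frame(mol_id = c("a", "b", "c"), smiles = c("CCO", "CCN", "CCC"),
                   stringsAsFactors = FALSE)
  df[["NR-AR"]] <- c(1L, NA, 0L)
  df[["NR-ER"]] <- c(NA, 1L, 0L)
  out <- curate_all(df)
  expect_setequal(names(out$tasks), c("NR-AR", "NR-ER"))
  expect_equal(out$audit_table$no_data, c(1, 1))
  expect_equal(out$audit_table$final, c(2, 2))
})
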