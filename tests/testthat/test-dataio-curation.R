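test_that("CSV records parse with required columns enforced", {
  df <- data.frame(compound_id = c("a", "b", "c"),
                   smiles = c("CCO", "CCN", "CCC"),
                   activity_type = "Ki",
                   activity_value = c("12", "", "not_a_number"),
                   year = c("2010", "", "2012"))
  path <- write_records_csv(df)
  rec <- parse_input(path, "csv")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$activity_value, c(12, NA, NA))
  expect_equal(rec$year, c(2010L, NA, 2012L))
  bad <- write_records_csv(df[, setdiff(names(df), "smiles")])
  expect_error(parse_input(bad, "csv"), "smiles",
               class = "autoqsar_config_error")
  expect_error(parse_input(tempfile(), "csv"), class = "autoqsar_io_error")
})

test_that("SMILES files parse one structure per line with optional ids", {
  path <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1", "", "CCN\tmol3"), path)
  rec <- parse_input(path)
  expect_equal(rec$compound_id, c("mol1", "MOL_2", "mol3"))
  expect_equal(rec$smiles, c("CCO", "c1ccccc1", "CCN"))
})

test_that("SDF molecules parse with their activity tags", {
  path <- write_tiny_sdf(tempfile(fileext = ".sdf"))
  rec <- parse_input(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$compound_id, c("ethanol", "methane"))
  expect_equal(rec$activity_type, c("Ki", "Ki"))
  expect_equal(rec$activity_value, c(100, 2500))
  expect_equal(rec$year, c(2015L, NA))
})

test_that("canonicalization extracts the parent and reports rejections", {
  out <- canonicalize_and_desalt(c("CCN.Cl", "CCO", "notasmiles", "[Na+].[Cl-]"),
                                 c("salt", "plain", "bad", "inorganic"))
  expect_equal(out$canonical_smiles[out$compound_id == "salt"], "CCN")
  expect_equal(out$status, c("ok", "ok", "rejected", "rejected"))
  expect_equal(out$reason[3:4], c("invalid_structure", "inorganic_only"))
  # idempotence on canonical output
  again <- canonicalize_and_desalt(out$canonical_smiles[1:2])
  expect_equal(again$canonical_smiles, out$canonical_smiles[1:2])
  expect_error(canonicalize_and_desalt(""), class = "autoqsar_config_error")
})

test_that("curation filters, desalts and deduplicates with a reconciling log", {
  recs <- data.frame(
    compound_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    smiles = c("Oc1ccccc1", "c1ccccc1O", "CCO", "CCCN", "CCCCO", "CCO"),
    activity_type = c("Ki", "Ki", "Ki", "IC50", "Ki", "Ki"),
    activity_value = c(100, 200, 50, 10, NA, 80),
    year = c(2010L, 2015L, NA, 2012L, 2014L, NA),
    stringsAsFactors = FALSE)
  cd <- curate(recs, "Ki")
  # most recent year wins among the phenol duplicates
  expect_true("r2" %in% cd$records$compound_id)
  expect_false("r1" %in% cd$records$compound_id)
  # absent years: the median-activity representative survives (even group:
  # lower original index between the two middles)
  expect_true("r3" %in% cd$records$compound_id)
  expect_false("r6" %in% cd$records$compound_id)
  expect_false(any(c("r4", "r5") %in% cd$records$compound_id))
  log <- cd$curation_log
  count_of <- function(rule) log$count[log$rule == rule]
  expect_equal(count_of("input"), 6L)
  expect_equal(count_of("dropped_activity_type") + count_of("dropped_missing_value") +
                 count_of("rejected_structure") + count_of("deduplicated") +
                 count_of("kept"), 6L)
  expect_equal(anyDuplicated(cd$records$canonical_smiles), 0L)
  expect_true(all(cd$records$activity_type == "Ki"))
})

test_that("curation is idempotent and order-independent for dated duplicates", {
  recs <- data.frame(
    compound_id = c("a", "b", "c"),
    smiles = c("Oc1ccccc1", "c1ccccc1O", "CCO"),
    activity_type = "Ki", activity_value = c(5, 7, 9),
    year = c(2011L, 2019L, 2015L), stringsAsFactors = FALSE)
  cd1 <- curate(recs, "Ki")
  cd2 <- curate(cd1$records, "Ki")
  expect_equal(cd2$records[names(cd1$records)], cd1$records)
  rev_cd <- curate(recs[3:1, ], "Ki")
  expect_setequal(rev_cd$records$compound_id, cd1$records$compound_id)
})

test_that("curation halts when nothing survives", {
  recs <- data.frame(compound_id = "x", smiles = "CCO",
                     activity_type = "Ki", activity_value = NA_real_,
                     year = NA_integer_, stringsAsFactors = FALSE)
  expect_error(curate(recs, "Ki"), class = "autoqsar_empty_dataset_error")
  expect_error(curate(recs, ""), class = "autoqsar_config_error")
})

test_that("the embedded fixture curates to exactly the planted counts", {
  cd <- curate(make_smiles_fixture(), "Ki")
  log <- stats::setNames(cd$curation_log$count, cd$curation_log$rule)
  expect_equal(log[["input"]], 41L)
  expect_equal(log[["dropped_activity_type"]], 3L)
  expect_equal(log[["dropped_missing_value"]], 1L)
  expect_equal(log[["rejected_structure"]], 1L)
  expect_equal(log[["desalted"]], 1L)
  expect_equal(log[["deduplicated"]], 4L)
  expect_equal(log[["kept"]], 32L)
  expect_equal(nrow(cd$records), 32L)
  # the dated phenol duplicate resolves to the 2015 record, the undated
  # trio to its median-activity member, the salt to its parent record
  expect_true(all(c("CPD032", "CPD034", "CPD002") %in% cd$records$compound_id))
  expect_false(any(c("CPD031", "CPD033", "CPD035", "CPD036", "CPD037",
                     "CPD038") %in% cd$records$compound_id))
})
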