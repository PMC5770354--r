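test_that("descriptor calculation is deterministic with one row per structure", {
  fm <- compute_descriptors(c(m1 = "C", m2 = "CC", m3 = "C"))
  v <- as.matrix(fm)
  expect_equal(nrow(v), 3L)
  expect_gt(ncol(v), 100L)
  expect_true(all(startsWith(colnames(v), "desc_")))
  # identical structures give identical rows
  expect_equal(unname(v["m1", ]), unname(v["m3", ]))
  expect_false(isTRUE(all.equal(unname(v["m1", ]), unname(v["m2", ]))))
  # unparsable structures are rejected per row, not silently dropped
  fm2 <- compute_descriptors(c(ok = "CCO", bad = "xx$$"))
  expect_equal(rownames(as.matrix(fm2)), "ok")
  expect_equal(attr(fm2, "rejections")$compound_id, "bad")
  expect_error(compute_descriptors(c(a = "xx$$")),
               class = "autoqsar_empty_dataset_error")
})

test_that("every fingerprint kind yields a binary block of the right width", {
  smis <- c(benzene = "c1ccccc1", aspirin = "CC(=O)Oc1ccccc1C(=O)O")
  kinds <- c("morgan", "feat_morgan", "atom_pair", "torsion", "path",
             "avalon", "layered", "maccs", "pattern")
  for (kind in kinds) {
    spec <- if (kind == "maccs") fingerprint_spec(kind) else
      fingerprint_spec(kind, n_bits = 256L)
    fm <- compute_fingerprints(smis, spec)
    v <- as.matrix(fm)
    expect_equal(nrow(v), 2L)
    expect_equal(ncol(v), if (kind == "maccs") 167L else 256L)
    expect_true(all(v %in% c(0, 1)))
    expect_true(all(fm$column_kind == "fingerprint"))
    expect_true(all(startsWith(colnames(v), kind)))
  }
})

test_that("fingerprints are a pure function of structure and spec", {
  spec <- fingerprint_spec("morgan", 1024L, 2L)
  fm1 <- compute_fingerprints(c(a = "CCO", b = "CCO", c = "CCN"), spec)
  v <- as.matrix(fm1)
  expect_equal(ncol(v), 1024L)
  expect_equal(unname(v["a", ]), unname(v["b", ]))
  expect_false(isTRUE(all.equal(unname(v["a", ]), unname(v["c", ]))))
  fm2 <- compute_fingerprints(c(a = "CCO", b = "CCO", c = "CCN"), spec)
  expect_identical(as.matrix(fm1), as.matrix(fm2))
})

test_that("fingerprint specs validate kinds and warn on fixed-width keys", {
  expect_error(fingerprint_spec("ecfp99"))
  expect_error(fingerprint_spec("morgan", n_bits = 0),
               class = "autoqsar_config_error")
  expect_warning(fingerprint_spec("maccs", n_bits = 1024L), "ignored")
  mc <- suppressWarnings(compute_fingerprints(
    c(a = "c1ccccc1O"), suppressWarnings(fingerprint_spec("maccs", 1024L))))
  expect_equal(ncol(as.matrix(mc)), 167L)
})

test_that("merging blocks concatenates columns and prunes constants", {
  ids <- c("a", "b", "c")
  b1 <- feature_matrix(matrix(c(1, 2, 3, 4, 5, 6), 3,
                              dimnames = list(ids, c("d1", "d2"))))
  b2 <- feature_matrix(matrix(c(0, 1, 1, 0, 0, 0), 3,
                              dimnames = list(ids, c("fp_1", "fp_2"))),
                       "fingerprint")
  merged <- merge_feature_blocks(list(b1, b2))
  expect_equal(colnames(as.matrix(merged)), c("d1", "d2", "fp_1"))
  expect_equal(attr(merged, "removed_constant"), "fp_2")
  expect_equal(unname(merged$column_kind),
               c("descriptor", "descriptor", "fingerprint"))
  # row mismatch and column collisions are alignment errors
  b3 <- feature_matrix(matrix(1:6, 3, dimnames = list(rev(ids), c("x", "y"))))
  expect_error(merge_feature_blocks(list(b1, b3)),
               class = "autoqsar_alignment_error")
  b4 <- feature_matrix(matrix(7:12, 3, dimnames = list(ids, c("d1", "z"))))
  expect_error(merge_feature_blocks(list(b1, b4)),
               class = "autoqsar_alignment_error")
})

test_that("merged width is the sum of block widths for curated structures", {
  cd <- curate(utils::head(make_smiles_fixture(), 12), "Ki")
  smis <- stats::setNames(cd$records$canonical_smiles, cd$records$compound_id)
  desc <- compute_descriptors(smis)
  fp <- compute_fingerprints(smis, fingerprint_spec("morgan", 256L))
  merged <- merge_feature_blocks(list(desc, fp))
  total <- ncol(as.matrix(desc)) + ncol(as.matrix(fp))
  removed <- length(attr(merged, "removed_constant"))
  expect_equal(ncol(as.matrix(merged)), total - removed)
  expect_equal(rownames(as.matrix(merged)), names(smis))
})
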