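test_that("SMILES files parse into heavy-atom graphs", {
  path <- tempfile(fileext = ".smi")
  writeLines(c("C methane", "c1ccccc1 benzene"), path)
  mols <- read_structures(path, format = "smiles")
  expect_length(mols, 2L)
  expect_equal(vapply(mols, function(m) m$id, ""), c("methane", "benzene"))
  expect_equal(nrow(mols[[1]]$atoms), 1L)
  expect_equal(nrow(mols[[2]]$atoms), 6L)
  expect_true(all(mols[[2]]$atoms$aromatic))
  expect_length(attr(mols, "failures"), 0L)
})

test_that("a malformed SDF record is reported without dropping the file", {
  path <- write_bad_sdf()
  mols <- read_structures(path, format = "sdf")
  expect_length(mols, 2L)
  expect_equal(vapply(mols, function(m) m$id, ""), c("m1", "m3"))
  expect_length(attr(mols, "failures"), 1L)
  expect_match(attr(mols, "failures"), "broken")
})

test_that("unreadable or empty structure inputs raise errors", {
  expect_error(read_structures(tempfile(), "sdf"), "cannot read")
  empty <- tempfile(fileext = ".smi")
  writeLines("not_a_smiles_string_$$$", empty)
  expect_error(read_structures(empty, "smiles"), "no valid molecules")
})

test_that("activity tables parse IC50s with missing-value and error conventions", {
  path <- write_activity_csv(data.frame(
    id = c("a", "b"),
    `BxPC-3` = c(10.2, 3.3), `NCI-H446` = c(9.13, NA),
    SW1990 = c(NA, 2), `NCI-H157` = c(1, 2), check.names = FALSE))
  act <- read_activity_table(path)
  expect_equal(dim(act), c(2L, 4L))
  expect_identical(act["a", "NCI-H446"], 9.13)
  expect_true(is.na(act["a", "SW1990"]))   # blank is missing, not zero
  expect_true(is.na(act["b", "NCI-H446"]))

  dup <- write_activity_csv(data.frame(id = c("a", "a"), X = c(1, 2)))
  expect_error(read_activity_table(dup), "duplicate")
  bad <- write_activity_csv(data.frame(id = c("a", "b"), X = c("1.0", "oops")))
  expect_error(read_activity_table(bad), "row 2, column 'X'")
})

test_that("join_library preserves order and handles unmatched ids", {
  mols <- list(mol_methane(), mol_ethane(), mol_propane())
  act <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                dimnames = list(c("methane", "ethane", "propane"), c("A", "B")))
  lib <- join_library(mols, act)
  expect_length(lib, 3L)
  expect_identical(library_ids(lib), c("methane", "ethane", "propane"))

  # permissive keeps molecules without activity rows, with a warning entry
  lib2 <- join_library(mols, act[1:2, , drop = FALSE], permissive = TRUE)
  expect_length(lib2, 3L)
  expect_length(lib2$warnings, 1L)
  expect_true(all(is.na(lib2$records[[3]]$activities)))
  expect_error(join_library(mols, act[1:2, , drop = FALSE]), "permissive")

  rownames(act) <- c("x", "y", "z")
  expect_error(join_library(mols, act), "no molecule id matches")
})

test_that("write/read round trip preserves ids, atom counts and IC50s", {
  gen <- generate_library(generator_config(n_compounds = 12L, n_off_scaffold = 2L),
                          seed = 11)
  dir <- tempfile(); export_fixture(gen, dir)
  mols <- read_structures(file.path(dir, "structures.sdf"), "sdf")
  act <- read_activity_table(file.path(dir, "activities.csv"))
  lib2 <- join_library(mols, act)
  expect_identical(library_ids(lib2), library_ids(gen$library))
  expect_equal(vapply(lib2$records, function(r) nrow(r$molecule$atoms), 0L),
               vapply(gen$library$records, function(r) nrow(r$molecule$atoms), 0L))
  expect_equal(activity_matrix(lib2), activity_matrix(gen$library),
               tolerance = 1e-12)
  # graphs survive the round trip up to isomorphism
  keys1 <- vapply(gen$library$records, function(r) mol_key(r$molecule), "")
  keys2 <- vapply(lib2$records, function(r) mol_key(r$molecule), "")
  expect_identical(keys1, keys2)
})
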