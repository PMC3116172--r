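test_that("additive logP reproduces the hand-summed atomic contributions", {
  # methane: one aliphatic carbon (0.1441) + 4 hydrogens on carbon (0.1230)
  d <- compute_general_descriptors(mol_methane())
  expect_equal(unname(d["logp"]), 0.1441 + 4 * 0.1230, tolerance = 1e-12)
  expect_equal(unname(d["mr"]), 2.503 + 4 * 1.057, tolerance = 1e-12)
  # ethane: two such carbons, six hydrogens
  d2 <- compute_general_descriptors(mol_ethane())
  expect_equal(unname(d2["logp"]), 2 * 0.1441 + 6 * 0.1230, tolerance = 1e-12)
})

test_that("benzene is neutral and its charges sum to zero", {
  d <- compute_general_descriptors(mol_benzene())
  expect_equal(unname(d["q_pos"] + d["q_neg"]), 0, tolerance = 1e-9)
  expect_gte(d[["vsa_total"]], 0)
  expect_length(d, 19L)
})

test_that("drug-like-index counts match hand counts on reference graphs", {
  b <- compute_drug_like_index(mol_benzene())
  expect_equal(unname(b[c("n_rings", "n_ring_systems", "n_linker_atoms",
                          "framework_size")]), c(1, 1, 0, 6))
  bp <- compute_drug_like_index(mol_biphenyl())
  expect_equal(unname(bp[c("n_rings", "n_ring_systems", "n_linker_atoms")]),
               c(2, 2, 0))
  e <- compute_drug_like_index(mol_ethane())
  expect_equal(unname(e[c("n_rings", "framework_size", "n_sidechain_atoms")]),
               c(0, 0, 2))
})

test_that("descriptors are deterministic and atom-order invariant", {
  set.seed(42)
  for (k in 1:20) {
    m <- random_molecule(sprintf("r%d", k), n = sample(4:10, 1))
    perm <- sample(nrow(m$atoms))
    mp <- permute_molecule(m, perm)
    expect_equal(compute_general_descriptors(m), compute_general_descriptors(mp),
                 tolerance = 1e-10)
    expect_equal(compute_drug_like_index(m), compute_drug_like_index(mp),
                 tolerance = 1e-12)
  }
  expect_identical(compute_general_descriptors(mol_benzene()),
                   compute_general_descriptors(mol_benzene()))
})

test_that("drug-like-index counts are integers obeying the cyclomatic bound", {
  set.seed(7)
  for (k in 1:20) {
    m <- random_molecule(sprintf("c%d", k), n = sample(3:10, 1))
    d <- compute_drug_like_index(m)
    counts <- d[setdiff(names(d), "dli")]
    expect_true(all(counts >= 0))
    expect_equal(counts, round(counts))
    expect_equal(unname(d["n_rings"]),
                 nrow(m$bonds) - nrow(m$atoms) +
                   igraph::components(getFromNamespace("mol_graph", "bqsar")(m))$no)
  }
})

test_that("build_matrix keeps library order and reports per-compound failures", {
  mols <- list(mol_methane(), mol_ethane(), mol_benzene())
  act <- matrix(1, 3, 1, dimnames = list(c("methane", "ethane", "benzene"), "A"))
  lib <- join_library(mols, act)
  m <- build_matrix(lib, "general")
  expect_identical(m$ids, c("methane", "ethane", "benzene"))
  expect_gte(ncol(m$values), 8L)
  expect_identical(m$values, build_matrix(lib, "general")$values)

  # an empty molecule cannot be described: excluded with a failure record
  broken <- molecule("broken", data.frame(element = character()))
  lib2 <- join_library(list(mol_methane(), broken, mol_ethane()),
                       matrix(1, 3, 1, dimnames = list(c("methane", "broken", "ethane"), "A")))
  m2 <- build_matrix(lib2, "general")
  expect_equal(nrow(m2$values), 2L)
  expect_length(m2$failures, 1L)
  expect_match(m2$failures, "broken")
})

test_that("normalization centers, scales, and drops degenerate columns", {
  expect_equal(normalize_descriptors(cbind(a = c(1, 3), b = c(0, 2)))$matrix[, "a"],
               c(-1, 1), ignore_attr = TRUE)
  set.seed(1)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("x", "y", "z")))
  nz <- normalize_descriptors(X)
  expect_true(all(abs(colMeans(nz$matrix)) < 1e-12))
  expect_true(all(abs(sqrt(colMeans(nz$matrix^2)) - 1) < 1e-12))

  Xc <- cbind(X, const = 5)
  expect_warning(nc <- normalize_descriptors(Xc), "const")
  expect_identical(nc$normalization$dropped, "const")
  expect_error(suppressWarnings(normalize_descriptors(matrix(1, 4, 2))), "zero variance")
})
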