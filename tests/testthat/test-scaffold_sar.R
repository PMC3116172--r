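lib_from_mols <- function(mols, cell = "NCI-H446", ic50 = NULL) {
  ids <- vapply(mols, `[[`, "", "id")
  if (is.null(ic50)) ic50 <- rep(1, length(mols))
  join_library(mols, matrix(ic50, ncol = 1, dimnames = list(ids, cell)))
}

test_that("scaffold matching decomposes substituted cores and skips strangers", {
  sc <- toy_scaffold()
  bare <- toy_compound("bare", sc, list())
  methylated <- toy_compound("me", sc, list("1" = frag_named("methyl")))
  stranger <- mol_propane()  # shares no ring with the scaffold
  lib <- lib_from_mols(list(bare, methylated, stranger))
  ms <- match_scaffolds(lib, list(sc))
  expect_identical(ms$unmatched, "propane")
  expect_true(all(vapply(ms$matches$bare$rgroups, is.null, TRUE)))  # all H
  r <- ms$matches$me$rgroups
  expect_null(r[["4"]])
  expect_identical(r[["1"]]$atoms$element, "C")
})

test_that("matching reassembles every generated compound exactly", {
  gen <- generate_library(generator_config(n_compounds = 20L, n_off_scaffold = 3L),
                          seed = 3)
  ms <- match_scaffolds(gen$library, gen$scaffolds)
  expect_length(ms$unmatched, 3L)
  sc_by_id <- setNames(gen$scaffolds, vapply(gen$scaffolds, `[[`, "", "id"))
  for (m in ms$matches) {
    orig <- Filter(function(r) r$molecule$id == m$id, gen$library$records)[[1]]$molecule
    rebuilt <- reassemble(sc_by_id[[m$scaffold]], m$rgroups, id = m$id)
    expect_identical(mol_key(rebuilt), mol_key(orig))
  }
})

test_that("chimera enumeration mirrors brute-force counting on toy sets", {
  sc <- toy_scaffold()
  groups <- list(H = NULL, methyl = frag_named("methyl"),
                 hydroxyl = frag_named("hydroxyl"))
  build <- function(maps) {
    mols <- lapply(seq_along(maps), function(i)
      toy_compound(sprintf("t%d", i),
                   sc, lapply(maps[[i]], function(g) groups[[g]])))
    match_scaffolds(lib_from_mols(mols), list(sc))
  }
  # identical molecules offer no alternative R-groups
  same <- build(list(c("1" = "methyl", "4" = "H"), c("1" = "methyl", "4" = "H")))
  expect_length(enumerate_chimeras(same, list(sc)), 0L)
  # two molecules differing at one position only regenerate each other
  two <- build(list(c("1" = "methyl", "4" = "H"), c("1" = "hydroxyl", "4" = "H")))
  expect_length(enumerate_chimeras(two, list(sc)), 0L)
  # (A,X), (B,Y), (A,Y) leave exactly the chimera (B,X)
  three <- build(list(c("1" = "methyl", "4" = "H"),
                      c("1" = "hydroxyl", "4" = "methyl"),
                      c("1" = "methyl", "4" = "methyl")))
  ch <- enumerate_chimeras(three, list(sc))
  expect_length(ch, 1L)
  expect_identical(fragment_key_public(ch[[1]]$rgroups[["1"]]),
                   fragment_key_public(frag_named("hydroxyl")))
  expect_identical(fragment_key_public(ch[[1]]$rgroups[["4"]]), "H")

  set.seed(21)
  vocab <- c("H", "methyl", "hydroxyl")
  for (k in 1:15) {
    nmol <- sample(2:5, 1)
    maps <- lapply(seq_len(nmol), function(i)
      setNames(sample(vocab, 2, replace = TRUE), c("1", "4")))
    maps <- unique(maps)
    ms <- build(maps)
    expect_length(enumerate_chimeras(ms, list(sc)),
                  chimera_count_oracle(maps))
  }
})

test_that("scores are centered on the input set and weights measure overlap", {
  set.seed(33)
  sc <- toy_scaffold()
  rgs <- list(list("1" = NULL, "4" = frag_named("methyl")),
              list("1" = frag_named("hydroxyl"), "4" = NULL),
              list("1" = frag_named("methyl"), "4" = frag_named("methyl")),
              list("1" = NULL, "4" = NULL))
  mols <- lapply(seq_along(rgs), function(i) toy_compound(sprintf("p%d", i), sc, rgs[[i]]))
  lib <- lib_from_mols(mols, ic50 = c(1, 1, 50, 50))
  X <- build_matrix(lib, "general")$values
  model <- fit_binary_bayes(X, c(TRUE, TRUE, FALSE, FALSE))
  p <- predict_bayes(model, X)
  scores <- vapply(seq_len(nrow(X)), function(i)
    score_chimera(model, X[i, ], mean(p)), 0)
  expect_equal(mean(scores), 0, tolerance = 1e-9)

  ms <- match_scaffolds(lib, list(sc))
  # chimera equal to p4 except position 1: overlap 1/2 with p4, etc.
  chim <- list(scaffold = "T", rgroups = list("1" = frag_named("methyl"), "4" = NULL))
  w <- weight_chimera(chim, ms)
  manual <- mean(c(1 / 2, 0 / 2, 1 / 2, 1 / 2))
  expect_equal(w, manual)
  full <- list(scaffold = "T", rgroups = rgs[[4]])
  expect_equal(weight_chimera(full, ms), mean(c(1 / 2, 1 / 2, 0 / 2, 2 / 2)))
})

test_that("an uninformative model scores every chimera at zero", {
  sc <- toy_scaffold()
  maps <- list(list("1" = NULL, "4" = frag_named("methyl")),
               list("1" = frag_named("methyl"), "4" = NULL),
               list("1" = frag_named("hydroxyl"), "4" = frag_named("methyl")))
  mols <- lapply(seq_along(maps), function(i) toy_compound(sprintf("u%d", i), sc, maps[[i]]))
  lib <- lib_from_mols(mols)
  # identical class-conditional distributions: train on duplicated rows
  X <- build_matrix(lib, "general")$values
  model <- fit_binary_bayes(rbind(X, X), rep(c(TRUE, FALSE), each = nrow(X)))
  rep <- build_sar_report(model, lib, list(sc), top_n = 100)
  expect_true(all(abs(rep$score) < 1e-9))
})

test_that("the suggestion table ranks by score times weight with tie rules", {
  gen <- generate_library(seed = 2)
  lib <- gen$library
  X <- build_matrix(lib, "general")$values
  lab <- activity_matrix(lib)[, "NCI-H446"] <= 9.13
  model <- fit_binary_bayes(X, lab)
  rep <- build_sar_report(model, lib, gen$scaffolds, top_n = 25)
  expect_s3_class(rep, "bq_sar_report")
  expect_gt(nrow(rep), 0)
  key <- rep$ranking
  expect_true(all(diff(key) <= 1e-12))
  expect_equal(rep$pct_gain, 100 * rep$score)
  expect_true(all(rep$weight >= 0 & rep$weight <= 1))
  expect_identical(build_sar_report(model, lib, gen$scaffolds, top_n = 0) |> nrow(), 0L)
})
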