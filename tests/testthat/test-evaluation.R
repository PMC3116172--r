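toy_grid <- function(values, division = "diverse") {
  cells <- expand.grid(model = c("PLS", "Bayes"), metric = c("R2", "Ap"),
                       cell_line = c("L1", "L2"),
                       descriptor_set = c("general", "drug_like"),
                       stringsAsFactors = FALSE)
  cells$value <- values
  results_grid(cells, division = division)
}

test_that("sigma is the drug-like minus general difference, cell by cell", {
  g <- results_grid(data.frame(
    model = "PLS", metric = "R2", cell_line = c("BxPC-3", "NCI-H446", "X"),
    descriptor_set = rep(c("general", "drug_like"), each = 3),
    value = c(0.552, 0.625, 0.3, 0.494, 0.906, 0.3)), division = "diverse")
  s <- sigma_columns(g)
  expect_equal(s$sigma[s$cell_line == "BxPC-3"], -0.058, tolerance = 1e-12)
  expect_equal(s$sigma[s$cell_line == "NCI-H446"], 0.281, tolerance = 1e-12)
  expect_equal(s$sigma[s$cell_line == "X"], 0)
})

test_that("sigma flags cells whose counterpart is missing", {
  g <- results_grid(data.frame(model = "PLS", metric = "R2", cell_line = "L1",
                               descriptor_set = "general", value = 0.5))
  s <- sigma_columns(g)
  expect_true(is.na(s$sigma))
  expect_true(is.na(s$drug_like))
})

test_that("swapping descriptor-set roles negates every sigma", {
  set.seed(19)
  v <- runif(16)
  g <- toy_grid(v)
  swapped <- as.data.frame(g)
  swapped$descriptor_set <- ifelse(swapped$descriptor_set == "general",
                                   "drug_like", "general")
  s1 <- sigma_columns(g)
  s2 <- sigma_columns(results_grid(swapped))
  key <- function(d) paste(d$model, d$metric, d$cell_line)
  expect_equal(s1$sigma, -s2$sigma[match(key(s1), key(s2))], tolerance = 1e-12)
})

test_that("the division t-test matches the closed-form oracle", {
  set.seed(20)
  for (k in 1:5) {
    a <- runif(16); b <- a + rnorm(16, 0.1, 0.05)
    ga <- toy_grid(a, "diverse"); gb <- toy_grid(b, "cluster_diverse")
    got <- paired_ttest(ga, gb)
    want <- paired_t_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    expect_identical(got$n, 16L)
  }
})

test_that("identical grids make the paired t-test degenerate, not numeric", {
  g <- toy_grid(runif(16))
  out <- paired_ttest(g, g)
  expect_true(out$degenerate)
  expect_true(is.na(out$p))
  expect_error(paired_ttest(g, toy_grid(runif(16))[-1, ]), "axes")
})

test_that("rendering writes 3-decimal CSV that reparses to displayed precision", {
  set.seed(22)
  g <- toy_grid(round(runif(16), 3))
  path <- tempfile(fileext = ".csv")
  out <- render_grid(g, csv_path = path)
  expect_length(out$text, nrow(out$wide) + 1L)
  back <- utils::read.csv(path)
  clean <- as.numeric(sub("\\*$", "", back$general))
  expect_equal(clean, round(out$wide$general, 3))
  # the best per-cell-line Ap is starred
  ap_rows <- which(out$wide$metric == "Ap" & out$wide$cell_line == "L1")
  best <- max(c(out$wide$general[ap_rows], out$wide$drug_like[ap_rows]))
  starred <- grepl("\\*", c(back$general[ap_rows], back$drug_like[ap_rows]))
  vals <- c(out$wide$general[ap_rows], out$wide$drug_like[ap_rows])
  expect_identical(starred, vals == best)
})

test_that("single-cell grids and missing values render without error", {
  g <- results_grid(data.frame(model = "Bayes", metric = "Ap", cell_line = "L1",
                               descriptor_set = "general", value = 0.9))
  out <- render_grid(g)
  expect_length(out$text, 2L)
  expect_match(out$text[2], "NA")
})

test_that("the shipped reference grid is complete and internally consistent", {
  ref <- reference_grid()
  expect_identical(nrow(ref), 96L)
  expect_setequal(unique(ref$model), c("PLS", "SVR", "Bayes", "SVM"))
  expect_setequal(unique(ref$division), c("diverse", "cluster_diverse"))
  # at 3 decimals the printed sigma equals drug_like - general in all but
  # one transcription-error cell, where only the sign disagrees
  dev <- abs(round(ref$drug_like - ref$general, 3) - ref$sigma_printed)
  expect_identical(sum(dev > 5e-4), 1L)
  expect_true(all(abs(abs(round(ref$drug_like - ref$general, 3))
                      - abs(ref$sigma_printed)) <= 5e-4))
})
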