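# Response loading, normalization, splits and the synthetic generator.

test_that("normalize_ic50 implements min-max on the log scale", {
  expect_equal(normalize_ic50(c(1, exp(1), exp(2))), c(0, 0.5, 1))
  expect_warning(v <- normalize_ic50(5), "degenerate")
  expect_equal(v, 0.5)
  expect_warning(vc <- normalize_ic50(rep(2, 4)), "degenerate")
  expect_equal(vc, rep(0.5, 4))
  # min-max on already-normalized input keeps endpoints at 0 and 1
  y <- c(0.1, 0.4, 0.9)
  z <- normalize_ic50(y, method = "minmax")
  expect_equal(range(z), c(0, 1))
  expect_equal(z, (y - 0.1) / 0.8)
  expect_error(normalize_ic50(c(-1, 2)), "positive")
  lg <- normalize_ic50(c(1, 2, 4, 100), method = "logistic")
  expect_true(all(lg > 0 & lg < 1))
})

test_that("load_responses filters and accounts for every row", {
  drugs <- tibble::tibble(drug_id = c("d1", "d2"), smiles = c("CC", "CCO"))
  cells <- tibble::tibble(cell_id = c("c1", "c2"), f1 = c(0, 1))
  tab <- tibble::tibble(
    drug_id = c("d1", "d1", "d2", "d2", "d1"),
    cell_id = c("c1", "c2", "c1", "c9", "c1"),   # c9 unknown; d1/c1 dup
    ic50 = c(1, 2, 4, 8, 16)
  )
  expect_warning(
    expect_message(r <- load_responses(tab, drugs = drugs, cells = cells),
                   "dropped"),
    "duplicate"
  )
  expect_equal(nrow(r), 3)
  expect_equal(attr(r, "n_input"), 5)
  expect_equal(attr(r, "n_kept") + attr(r, "n_dropped_unknown") +
                 attr(r, "n_dropped_duplicate") +
                 attr(r, "n_dropped_bad_ic50"), 5)
  expect_true(all(r$y >= 0 & r$y <= 1))

  # 3 valid rows load as 3 records
  ok <- load_responses(tab[1:3, ], drugs = drugs, cells = cells)
  expect_equal(nrow(ok), 3)

  # a single row with an unknown cell drops to zero records
  expect_message(
    none <- load_responses(tibble::tibble(drug_id = "d1", cell_id = "cX",
                                          ic50 = 1),
                           drugs = drugs, cells = cells),
    "dropped")
  expect_equal(nrow(none), 0)

  # non-numeric ic50 rows are counted
  bad <- tibble::tibble(drug_id = c("d1", "d2", "d1"),
                        cell_id = c("c1", "c2", "c2"),
                        ic50 = c("1.5", "oops", "2.5"))
  expect_warning(rb <- load_responses(bad), "non-numeric")
  expect_equal(attr(rb, "n_dropped_bad_ic50"), 1)
  expect_equal(nrow(rb), 2)
  expect_error(load_responses(tibble::tibble(a = 1)), "drug_id")

  # round-trips from file
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[1:3, ], path, row.names = FALSE)
  rf <- load_responses(path, drugs = drugs, cells = cells)
  expect_equal(nrow(rf), 3)
})

test_that("mixed splits follow the 80/10/10 ratio", {
  recs <- tibble::tibble(drug_id = rep(sprintf("d%d", 1:5), 2),
                         cell_id = rep(sprintf("c%d", 1:2), each = 5),
                         y = runif(10))
  sp <- make_split(recs, "mixed", seed = 3)
  expect_equal(unname(table(sp$part)[c("train", "validation", "test")]),
               c(8L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(nrow(sp), 10)
})

test_that("new-cell-line splits share no cell identity across parts", {
  set.seed(20)
  recs <- tidyr::expand_grid(drug_id = sprintf("d%d", 1:6),
                             cell_id = sprintf("c%d", 1:12))
  recs$y <- runif(nrow(recs))
  sp <- make_split(recs, "new_cell_line", seed = 5)
  parts <- split(sp$cell_id, sp$part)
  expect_length(intersect(parts$train, parts$test), 0)
  expect_length(intersect(parts$train, parts$validation), 0)
  expect_length(intersect(parts$validation, parts$test), 0)
  expect_equal(nrow(sp), nrow(recs))
  expect_error(make_split(recs[recs$cell_id %in% c("c1", "c2"), ],
                          "new_cell_line"), "too few")
})

test_that("splits are seed-deterministic and seed-sensitive", {
  set.seed(21)
  recs <- tidyr::expand_grid(drug_id = sprintf("d%d", 1:10),
                             cell_id = sprintf("c%d", 1:10))
  recs$y <- runif(100)
  a <- make_split(recs, "mixed", seed = 7)
  b <- make_split(recs, "mixed", seed = 7)
  expect_identical(a$part, b$part)
  c_ <- make_split(recs, "mixed", seed = 8)
  expect_false(identical(a$part, c_$part))
})

test_that("split disjointness and coverage hold across random instances", {
  set.seed(22)
  for (rep in 1:500) {
    n_d <- sample(3:6, 1); n_c <- sample(10:15, 1)
    recs <- tidyr::expand_grid(drug_id = sprintf("d%d", seq_len(n_d)),
                               cell_id = sprintf("c%d", seq_len(n_c)))
    kind <- sample(c("mixed", "new_cell_line"), 1)
    sp <- make_split(recs, kind, seed = sample.int(1e6, 1))
    expect_equal(nrow(sp), nrow(recs))          # coverage
    expect_false(anyNA(sp$part))                # every record assigned
    expect_true(all(table(sp$part) >= 1))       # three non-empty parts
    if (kind == "new_cell_line") {
      tab <- table(sp$cell_id, sp$part)
      expect_true(all(rowSums(tab > 0) == 1))   # each cell in one part
    }
  }
})

test_that("double cold-start flag also partitions drugs", {
  set.seed(23)
  recs <- tidyr::expand_grid(drug_id = sprintf("d%d", 1:12),
                             cell_id = sprintf("c%d", 1:12))
  sp <- make_split(recs, "new_cell_line", seed = 2, cold_drugs = TRUE)
  for (col in c("cell_id", "drug_id")) {
    tab <- table(sp[[col]], sp$part)
    expect_true(all(rowSums(tab > 0) == 1))
  }
  expect_equal(nrow(sp) + attr(sp, "n_dropped_cross_part"), nrow(recs))
})

test_that("synthetic data is reproducible with a known noiseless limit", {
  ds0 <- simulate_drug_response(n_drugs = 4, n_cells = 3, cell_dim = 15,
                                noise_sd = 0, seed = 31)
  # noiseless: observed y equals the deterministic ground-truth function
  expect_equal(ds0$responses$y, ds0$truth$y_star)
  ds0b <- simulate_drug_response(n_drugs = 4, n_cells = 3, cell_dim = 15,
                                 noise_sd = 0, seed = 31)
  expect_identical(ds0$responses, ds0b$responses)
  expect_identical(ds0$cells, ds0b$cells)
  ds1 <- simulate_drug_response(n_drugs = 4, n_cells = 3, cell_dim = 15,
                                noise_sd = 0.05, seed = 32)
  expect_false(identical(ds1$responses$y, ds1$truth$y_star))
  expect_true(all(ds1$responses$y >= 0 & ds1$responses$y <= 1))
  expect_gt(stats::var(ds1$responses$y), 0)
})

test_that("the default-size generator yields 2000 in-range pairs", {
  ds <- simulate_drug_response(seed = 41)
  expect_equal(nrow(ds$responses), 2000)           # 50 drugs x 40 cells
  expect_equal(nrow(ds$drugs), 50)
  expect_equal(nrow(ds$cells), 40)
  expect_equal(ncol(ds$cells) - 1L, 735)
  expect_true(all(ds$responses$y >= 0 & ds$responses$y <= 1))
  expect_gt(stats::var(ds$responses$y), 0)
  expect_false(any(duplicated(ds$drugs$smiles)))
  # every generated SMILES parses into a valid one-fragment graph
  feats <- featurize_drugs(ds$drugs[1:8, ], n_bits = 64)
  for (g in feats$graph) {
    expect_true(g$num_atoms >= 5 && g$num_atoms <= 30)
    expect_true(isSymmetric(g$adjacency))
  }
})

test_that("dataset CSV export round-trips through the loaders", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  drugs <- gatfuse:::read_table_auto(file.path(dir, "drugs.csv"))
  cells <- gatfuse:::read_table_auto(file.path(dir, "cells.csv"))
  resp <- load_responses(file.path(dir, "responses.csv"),
                         drugs = drugs, cells = cells)
  expect_equal(nrow(resp), nrow(ds$responses))
  # the stored normalized response survives the round trip unchanged
  expect_equal(resp$y, ds$responses$y, tolerance = 1e-8)
  # normalizing ln(raw_ic50) by min-max recovers the min-max-rescaled y,
  # because raw_ic50 = exp(6 y - 3) is affine in y on the log scale
  raw_only <- dplyr::transmute(ds$responses, drug_id, cell_id,
                               ic50 = raw_ic50)
  resp2 <- load_responses(raw_only, drugs = drugs, cells = cells)
  expect_equal(
    resp2$y,
    (ds$responses$y - min(ds$responses$y)) /
      (max(ds$responses$y) - min(ds$responses$y)),
    tolerance = 1e-8
  )
})
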