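test_that("taper_data validates schema and invariants", {
  td <- one_tree()
  expect_s3_class(td, "taper_data")
  expect_equal(nrow(td), 11)
  expect_equal(n_trees(td), 1)

  # missing column named in the error
  bad <- dplyr::select(tibble::as_tibble(td), -"D_cm")
  expect_error(taper_data(bad), "D_cm", class = "stemtaper_schema_error")

  # section at or above total height identifies the tree
  bad <- tibble::as_tibble(td)
  bad$h_m[5] <- bad$H_m[5]
  expect_error(taper_data(bad), "p1/t1",
               class = "stemtaper_validation_error")

  # conflicting plot covariates
  bad <- tibble::as_tibble(td)
  bad$Sd_trees_ha[3] <- 900
  expect_error(taper_data(bad), "Sd_trees_ha",
               class = "stemtaper_consistency_error")

  # domain checks
  bad <- tibble::as_tibble(td); bad$H_m <- 1.2
  expect_error(taper_data(bad), class = "stemtaper_validation_error")
  bad <- tibble::as_tibble(td); bad$Cd <- 1.4
  expect_error(taper_data(bad), class = "stemtaper_validation_error")
})

test_that("CSV round trip reproduces every numeric field", {
  sim <- simulate_taper_data(n_plots = 4, seed = 21)
  f <- withr::local_tempfile(fileext = ".csv")
  write_stem_csv(sim$data, f)
  back <- read_stem_csv(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(sim$data),
               tolerance = 1e-12)
  # a second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_stem_csv(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("read_stem_csv rejects malformed files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_id,tree_id,D_cm", "p1,t1,21"), f)
  expect_error(read_stem_csv(f), "H_m", class = "stemtaper_schema_error")
  expect_error(read_stem_csv(file.path(tempdir(), "absent.csv")),
               class = "stemtaper_io_error")
})

test_that("fitting/validation split is by whole tree with round() sizing", {
  sim <- simulate_taper_data(seed = 31)  # 396 trees
  sp <- split_fit_validation(sim$data, fraction = 0.25, seed = 7)
  expect_equal(n_trees(sp$validation), 99)   # round(0.25 * 396)
  expect_equal(n_trees(sp$fitting), 297)

  small <- simulate_taper_data(n_plots = 2, trees_per_plot = 2, seed = 3)
  sp4 <- split_fit_validation(small$data, 0.25, seed = 1)
  expect_equal(n_trees(sp4$validation), 1)
  expect_equal(n_trees(sp4$fitting), 3)

  # determinism
  sp2 <- split_fit_validation(sim$data, fraction = 0.25, seed = 7)
  expect_identical(sp$validation$tree_id, sp2$validation$tree_id)
  expect_identical(sp$validation$plot_id, sp2$validation$plot_id)

  expect_error(split_fit_validation(small$data, 0.01, seed = 1),
               class = "stemtaper_validation_error")
})

test_that("split partition property holds across fractions and seeds", {
  sim <- simulate_taper_data(n_plots = 9, seed = 13)
  key <- function(d) paste(d$plot_id, d$tree_id)
  all_keys <- sort(unique(key(sim$data)))
  for (fr in c(0.1, 0.25, 0.5, 0.8)) {
    for (sd_ in 1:3) {
      sp <- split_fit_validation(sim$data, fr, seed = sd_)
      kf <- unique(key(sp$fitting)); kv <- unique(key(sp$validation))
      expect_length(intersect(kf, kv), 0)
      expect_identical(sort(c(kf, kv)), all_keys)
      expect_equal(length(kv), round(fr * length(all_keys)))
      # all 11 sections of each tree travel together
      expect_true(all(table(key(sp$validation)) == 11))
    }
  }
})
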