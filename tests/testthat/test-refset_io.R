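test_that("reference-set write/read round trip is lossless", {
  refset <- make_reference_set(5, seed = 3, noise_sd = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_set(refset, path)
  back <- read_reference_set(path)

  expect_equal(length(back), 5)
  for (i in 1:5) {
    expect_identical(back$entries[[i]]$name, refset$entries[[i]]$name)
    expect_identical(back$entries[[i]]$index, refset$entries[[i]]$index)
    expect_lt(max(abs(back$entries[[i]]$spectrum$values -
                        refset$entries[[i]]$spectrum$values)), 1e-12)
    expect_lt(max(abs(as.numeric(back$entries[[i]]$structure) -
                        as.numeric(refset$entries[[i]]$structure))), 1e-12)
  }
  expect_equal(back$grid$wavelengths, refset$grid$wavelengths)
})

test_that("beta-II flags come from the (configurable) name list", {
  refset <- make_reference_set(3, seed = 1)
  refset$entries[[2]]$name <- "alpha-chymotrypsin"
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_set(refset, path)
  back <- read_reference_set(path)
  expect_equal(vapply(back$entries, `[[`, logical(1), "beta2"),
               c(FALSE, TRUE, FALSE))
  custom <- read_reference_set(path, beta2_names = c("REF01"))
  expect_equal(vapply(custom$entries, `[[`, logical(1), "beta2"),
               c(TRUE, FALSE, FALSE))
})

test_that("malformed reference files are rejected with informative errors", {
  g <- wavelength_grid()
  # 50 spectral rows where the grid demands 51
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength,a",
               paste(240:191, rnorm(50), sep = ","),
               paste(c("helix", "sheet", "turn", "bend", "loop"), 0.1, sep = ",")),
             path)
  expect_error(read_reference_set(path, grid = g), "ragged")

  # non-numeric cell
  path2 <- withr::local_tempfile(fileext = ".csv")
  lines <- c("wavelength,a", paste(240:190, 1, sep = ","),
             "helix,0.5", "sheet,oops", "turn,0", "bend,0", "loop,0")
  writeLines(lines, path2)
  expect_error(read_reference_set(path2), "non-numeric.*'a'")

  # structure fraction out of [0, 1]
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength,a", paste(240:190, 1, sep = ","),
               "helix,0.5", "sheet,1.5", "turn,0", "bend,0", "loop,0"),
             path3)
  expect_error(read_reference_set(path3), "outside \\[0, 1\\].*'a'")
})

test_that("test-spectrum files parse labels and trailing temperatures", {
  series <- make_melting_series(structure_fractions3(0.6, 0.1, 0.3),
                                f_schedule = seq(0, 0.9, length.out = 10),
                                temperatures_C = seq(20, 110, by = 10),
                                seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_test_spectra(series$spectra, path)
  back <- read_test_spectra(path, wavelength_grid())
  expect_length(back, 10)
  expect_equal(vapply(back, `[[`, numeric(1), "temperature_C"),
               seq(20, 110, by = 10))

  # header without a temperature stays temperature-free
  s <- list(cd_spectrum(rnorm(51), wavelength_grid(), label = "plain"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_test_spectra(s, path2)
  expect_null(read_test_spectra(path2)[[1]]$temperature_C)

  # declared grid must match the file: wrong span or wrong row count
  expect_error(read_test_spectra(path, wavelength_grid(250, 200, 1)),
               "do not match")
  expect_error(read_test_spectra(path, wavelength_grid(240, 196, 1)), "ragged")
})

test_that("results tables leave derandomized columns empty at 0% RC", {
  rows <- data.frame(
    temperature_C = c(20, 60), best_nrmsd = c(0.009, 0.017),
    rc_added = c(0, 0.2),
    derand_helix = c(0.76, 0.77), derand_sheet = c(0, 0),
    derand_other = c(0.24, 0.23),
    regen_helix = c(0.76, 0.62), regen_sheet = c(0, 0),
    regen_other = c(0.24, 0.38), note = c("", ""))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(rows, path)
  out <- read.csv(path, check.names = FALSE, colClasses = "character")
  expect_equal(nrow(out), 2)
  expect_equal(out$derand_helix, c("", "0.77"))
  expect_equal(out$RC_added, c("0%", "20%"))
  expect_equal(out$regen_helix, c("0.76", "0.62"))

  # empty row list -> header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_results_table(rows[0, ], path2)
  expect_length(readLines(path2), 1)
})
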