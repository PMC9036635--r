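# Column-oriented CSV dialect shared by reference sets and test sets:
#   - one spectrum per column; first row holds column names;
#   - first column holds the descending wavelengths for the spectral rows
#     and the annotation labels (helix, sheet, turn, bend, loop) for the
#     structure rows that follow;
#   - decimal separator ".", field separator ",".
# Reference files carry n_structures extra rows per column; test files
# carry none. The writer emits exactly this layout so read/write
# round-trips are lossless.

STRUCTURE_ROW_LABELS <- c("helix", "sheet", "turn", "bend", "loop")

num_or_na <- function(x) suppressWarnings(as.numeric(x))

# returns list(values = P x n matrix, structures = n_structures x n matrix,
#              names, wavelengths)
parse_column_file <- function(path, n_structures, grid) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (ncol(raw) < 2) stop(sprintf("%s: expected a wavelength column plus at least one spectrum column", path))
  n_rows <- nrow(raw)
  n_spec <- n_rows - n_structures
  if (!is.null(grid) && n_spec != length(grid))
    stop(sprintf(
      "%s: ragged columns: %d spectral rows per column where the %g-%g nm grid demands %d",
      path, n_spec, grid$start_nm, grid$end_nm, length(grid)))
  if (n_spec < 2) stop(sprintf("%s: too few spectral rows (%d)", path, n_spec))

  first <- raw[[1]]
  wl <- num_or_na(first[seq_len(n_spec)])
  if (anyNA(wl))
    stop(sprintf("%s: non-numeric wavelength cell in column '%s' (row %d)",
                 path, names(raw)[1], which(is.na(wl))[1] + 1L))
  steps <- diff(wl)
  if (any(steps >= 0) || max(abs(steps - steps[1])) > 1e-6)
    stop(sprintf("%s: wavelength column must be strictly descending and uniformly spaced", path))
  if (is.null(grid)) {
    grid <- wavelength_grid(wl[1], wl[n_spec], -steps[1])
  } else if (max(abs(wl - grid$wavelengths)) > 1e-6) {
    stop(sprintf("%s: wavelengths do not match the expected %g-%g nm grid",
                 path, grid$start_nm, grid$end_nm))
  }

  cols <- names(raw)[-1]
  vals <- matrix(NA_real_, n_spec, length(cols))
  strs <- if (n_structures > 0) matrix(NA_real_, n_structures, length(cols)) else NULL
  for (j in seq_along(cols)) {
    v <- num_or_na(raw[[j + 1]])
    if (anyNA(v))
      stop(sprintf("%s: non-numeric cell in column '%s' (row %d)",
                   path, cols[j], which(is.na(v))[1] + 1L))
    vals[, j] <- v[seq_len(n_spec)]
    if (n_structures > 0) {
      s <- v[n_spec + seq_len(n_structures)]
      bad <- which(s < -1e-9 | s > 1 + 1e-9)
      if (length(bad))
        stop(sprintf(
          "%s: structure fraction %.4g outside [0, 1] in column '%s' (row %d)",
          path, s[bad[1]], cols[j], n_spec + bad[1] + 1L))
      strs[, j] <- s
    }
  }
  list(values = vals, structures = strs, names = cols,
       grid = grid)
}

#' Read a structure-annotated reference set
#'
#' Reads the column CSV/TXT dialect described in the package: one spectrum
#' per column, wavelengths descending in the first column, and
#' `n_structures` annotation rows (helix, sheet, turn, bend, loop) appended
#' below the spectral rows of every column.
#'
#' @param path file path (`.csv` or `.txt`; the content is CSV either way).
#' @param n_structures number of annotation rows per column (default 5).
#' @param grid optional [wavelength_grid()]; when `NULL` the grid is
#'   inferred from the wavelength column.
#' @param beta2_names names (matched case-insensitively) to flag as beta-II
#'   members; defaults to [default_beta2_names()].
#' @return A [reference_set()] whose entry indices follow file column order.
#' @export
read_reference_set <- function(path, n_structures = 5, grid = NULL,
                               beta2_names = default_beta2_names()) {
  if (n_structures != 5)
    stop("reference sets are annotated with 5 structure classes")
  p <- parse_column_file(path, n_structures, grid)
  entries <- lapply(seq_along(p$names), function(j) {
    s <- p$structures[, j]
    reference_entry(
      spectrum = cd_spectrum(p$values[, j], p$grid, label = p$names[j]),
      structure = structure_fractions5(s[1], s[2], s[3], s[4], s[5]),
      name = p$names[j], index = j,
      beta2 = tolower(p$names[j]) %in% tolower(beta2_names))
  })
  reference_set(entries)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a reference set in the column CSV dialect
#'
#' Inverse of [read_reference_set()]; the round trip preserves values to
#' better than 1e-12 and names/order exactly. Entry names must not contain
#' commas.
#'
#' @param refset a [reference_set()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_reference_set <- function(refset, path) {
  stopifnot(inherits(refset, "reference_set"))
  nm <- refset_names(refset)
  if (any(grepl(",", nm))) stop("entry names must not contain commas")
  V <- t(refset_matrix(refset))            # P x n
  S <- t(refset_structures(refset))        # 5 x n
  body <- rbind(
    cbind(fmt_num(refset$grid$wavelengths),
          matrix(fmt_num(V), nrow = nrow(V))),
    cbind(STRUCTURE_ROW_LABELS, matrix(fmt_num(S), nrow = 5)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("wavelength", nm), collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

# "BSA 70C", "lysozyme_90 C", "70C" -> temperature 70; NULL when absent
parse_label_temperature <- function(label) {
  m <- regmatches(label,
                  regexpr("([0-9]+(\\.[0-9]+)?)\\s*(°\\s*)?C$", label))
  if (length(m) == 0) return(NULL)
  as.numeric(sub("\\s*(°\\s*)?C$", "", m))
}

#' Read test spectra (optionally a temperature series)
#'
#' Same column dialect as [read_reference_set()] but with no structure
#' rows. Column headers become spectrum labels; a trailing temperature in a
#' header (e.g. `"BSA 70C"`) is parsed into `temperature_C`.
#'
#' @param path file path.
#' @param grid expected [wavelength_grid()]; the file's wavelength column
#'   must match it (`NULL` to infer from the file).
#' @return A list of [cd_spectrum()] objects in column order.
#' @export
read_test_spectra <- function(path, grid = NULL) {
  p <- parse_column_file(path, 0L, grid)
  lapply(seq_along(p$names), function(j)
    cd_spectrum(p$values[, j], p$grid, label = p$names[j],
                temperature_C = parse_label_temperature(p$names[j])))
}

#' Write test spectra in the column CSV dialect
#'
#' @param spectra list of [cd_spectrum()] on one grid; labels become column
#'   headers (a known temperature is appended as e.g. `" 70C"` when not
#'   already part of the label).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_test_spectra <- function(spectra, path) {
  if (length(spectra) == 0) stop("no spectra to write")
  grid <- spectra[[1]]$grid
  labs <- vapply(spectra, function(s) {
    lab <- s$label
    if (!is.null(s$temperature_C) && is.null(parse_label_temperature(lab)))
      lab <- sprintf("%s %gC", lab, s$temperature_C)
    lab
  }, character(1))
  V <- vapply(spectra, function(s) {
    if (!same_grid(s$grid, grid)) stop("all spectra must share one grid")
    s$values
  }, numeric(length(grid)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("wavelength", labs), collapse = ","), con)
  body <- cbind(fmt_num(grid$wavelengths), matrix(fmt_num(V), nrow = nrow(V)))
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Write a melting-series results table
#'
#' One row per temperature with the best fit's NRMSD, the random-coil
#' percentage added, the derandomized 3-class fractions and the regenerated
#' 3-class fractions of the original protein. Following the reporting
#' convention for such tables, the derandomized columns are left empty when
#' the best fit needed 0% RC (the derandomized and regenerated fractions
#' coincide there).
#'
#' @param rows data frame as produced by [analyze_series()] (`$table`),
#'   with columns `temperature_C`, `best_nrmsd`, `rc_added`,
#'   `derand_helix/sheet/other`, `regen_helix/sheet/other`, `note`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(rows, path) {
  hdr <- c("temperature_C", "best_NRMSD", "RC_added",
           "derand_helix", "derand_sheet", "derand_other",
           "regen_helix", "regen_sheet", "regen_other", "note")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  if (!is.null(rows) && nrow(rows) > 0) {
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      derand <- if (isTRUE(r$rc_added == 0)) c("", "", "") else
        sprintf("%.2f", c(r$derand_helix, r$derand_sheet, r$derand_other))
      line <- c(sprintf("%g", r$temperature_C),
                sprintf("%.3f", r$best_nrmsd),
                sprintf("%d%%", round(100 * r$rc_added)),
                derand,
                sprintf("%.2f", c(r$regen_helix, r$regen_sheet, r$regen_other)),
                if (is.null(r$note) || is.na(r$note)) "" else r$note)
      writeLines(paste(line, collapse = ","), con)
    }
  }
  invisible(path)
}
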