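#' A reference-set entry
#'
#' One structure-annotated reference spectrum. `index` is the 1-based
#' position of the spectrum's column in the input file; map layouts label
#' reference proteins by this number. `beta2` marks membership of the
#' Sreerama--Woody beta-II class, whose CD spectra resemble unfolded/
#' polyproline-II spectra.
#'
#' @param spectrum a [cd_spectrum()].
#' @param structure a [structure_fractions5()].
#' @param name entry name.
#' @param index 1-based ordinal within the set.
#' @param beta2 logical beta-II flag.
#' @return An object of class `reference_entry`.
#' @export
reference_entry <- function(spectrum, structure, name, index, beta2 = FALSE) {
  stopifnot(inherits(spectrum, "cd_spectrum"),
            inherits(structure, "structure_fractions5"),
            is.character(name), length(name) == 1,
            is.numeric(index), index >= 1, index == round(index))
  structure(
    list(spectrum = spectrum, structure = structure, name = name,
         index = as.integer(index), beta2 = isTRUE(beta2)),
    class = "reference_entry")
}

#' A set of annotated reference spectra
#'
#' @param entries list of [reference_entry()] objects sharing one
#'   wavelength grid, with unique indices.
#' @return An object of class `reference_set` with elements `entries`,
#'   `grid` and `n_structures` (always 5).
#' @export
reference_set <- function(entries) {
  if (length(entries) == 0) stop("reference set must contain at least one entry")
  stopifnot(all(vapply(entries, inherits, logical(1), "reference_entry")))
  grid <- entries[[1]]$spectrum$grid
  for (e in entries)
    if (!same_grid(e$spectrum$grid, grid))
      stop(sprintf("entry '%s' is not on the shared wavelength grid", e$name))
  idx <- vapply(entries, `[[`, integer(1), "index")
  if (anyDuplicated(idx)) stop("entry indices must be unique")
  structure(list(entries = entries, grid = grid, n_structures = 5L),
            class = "reference_set")
}

#' @export
length.reference_set <- function(x) length(x$entries)

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d entries on %g-%g nm (%d points), %d beta-II flagged\n",
              length(x), x$grid$start_nm, x$grid$end_nm, length(x$grid),
              sum(vapply(x$entries, `[[`, logical(1), "beta2"))))
  invisible(x)
}

# n x P matrix of reference spectra (rows follow entry order)
refset_matrix <- function(refset) {
  do.call(rbind, lapply(refset$entries, function(e) e$spectrum$values))
}

# n x 5 matrix of structure annotations
refset_structures <- function(refset) {
  do.call(rbind, lapply(refset$entries, function(e) as.numeric(e$structure)))
}

refset_names <- function(refset) {
  vapply(refset$entries, `[[`, character(1), "name")
}

#' Default beta-II reference-protein names
#'
#' The beta-II proteins of the Sreerama--Woody classification that commonly
#' occur as best matching units when partially unfolded spectra are fitted:
#' alpha-chymotrypsin, chymotrypsinogen and elastase. Matching is
#' case-insensitive on these names.
#'
#' @return Character vector of names.
#' @export
default_beta2_names <- function() {
  c("alpha-chymotrypsin", "chymotrypsinogen", "elastase")
}

#' Read a beta-II membership sidecar file
#'
#' Plain text, one reference-entry name per line; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return Character vector of names.
#' @export
read_beta2_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
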