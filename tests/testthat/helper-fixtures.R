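# Shared fixtures, built in code at test time.

# Hand-built map with full control over weights/structures/occupancy,
# for oracle tests of BMU search and prediction arithmetic.
toy_map <- function(weights, structures = NULL, rows, cols,
                    grid = NULL, occupancy = NULL, k_bmu = 5) {
  if (is.null(grid)) {
    # tiny grid with as many points as weight columns
    p <- ncol(weights)
    grid <- wavelength_grid(240, 240 - (p - 1), 1)
  }
  coords <- cbind(row = rep(seq_len(rows), each = cols),
                  col = rep(seq_len(cols), times = rows))
  if (is.null(occupancy))
    occupancy <- data.frame(index = integer(0), name = character(0),
                            node = integer(0), row = integer(0),
                            col = integer(0))
  structure(
    list(config = som_config(rows = rows, cols = cols,
                             k_bmu = min(k_bmu, rows * cols)),
         grid = grid, coords = coords, weights = weights,
         node_structures = structures, occupancy = occupancy,
         quant_error = NA_real_),
    class = "trained_map")
}

toy_spectrum <- function(values, grid = NULL, ...) {
  if (is.null(grid)) grid <- wavelength_grid(240, 240 - (length(values) - 1), 1)
  cd_spectrum(values, grid, ...)
}

fake_candidate <- function(nrmsd, f_rc = 0, neighbour_names = character(0),
                           derand_spectrum = NULL, predicted_spectrum = NULL) {
  structure(
    list(f_rc = f_rc, nrmsd = nrmsd,
         derand_spectrum = derand_spectrum,
         fit = list(nrmsd = nrmsd,
                    neighbour_references = if (length(neighbour_names))
                      data.frame(bmu_rank = 1, index = seq_along(neighbour_names),
                                 name = neighbour_names, map_distance = 0)
                    else NULL,
                    predicted_spectrum = predicted_spectrum),
         derand_structure = structure_fractions3(0.5, 0.2, 0.3),
         regenerated_structure = structure_fractions3(0.5, 0.2, 0.3),
         co_optimal = NA),
    class = "derand_candidate")
}

# One modest trained map shared across test files (built on first use).
.fixtures <- new.env(parent = emptyenv())

demo_refset <- function() {
  if (is.null(.fixtures$refset))
    .fixtures$refset <- make_reference_set(50, seed = 5, noise_sd = 0)
  .fixtures$refset
}

demo_map <- function() {
  if (is.null(.fixtures$map))
    .fixtures$map <- train_som(
      demo_refset(),
      som_config(rows = 15, cols = 15, epochs = 300, radius_final = 0.25,
                 lr_final = 0.002, seed = 9))
  .fixtures$map
}
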