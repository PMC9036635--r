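#' Persist a trained map to a portable file
#'
#' Writes the whole map (config, wavelength grid, node prototype spectra,
#' node structures, reference occupancy) as a single JSON document at full
#' numeric precision, so training and prediction can be separate
#' invocations and round trips are exact.
#'
#' @param map a [train_som()] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_som_map <- function(map, path) {
  stopifnot(inherits(map, "trained_map"))
  obj <- list(
    format = "cdsom-map",
    version = 1L,
    config = unclass(map$config),
    grid = list(start_nm = map$grid$start_nm, end_nm = map$grid$end_nm,
                step_nm = map$grid$step_nm),
    weights = map$weights,
    node_structures = map$node_structures,
    occupancy = map$occupancy,
    quant_error = map$quant_error)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a trained map written by [write_som_map()]
#'
#' @param path file path.
#' @return A `trained_map` object.
#' @export
read_som_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cdsom-map"))
    stop(sprintf("%s is not a cdsom map file", path))
  cfg <- do.call(som_config, obj$config[c(
    "rows", "cols", "k_bmu", "epochs", "lr_initial", "lr_final",
    "radius_initial", "radius_final", "n_neighbours", "seed")])
  grid <- wavelength_grid(obj$grid$start_nm, obj$grid$end_nm, obj$grid$step_nm)
  ns <- obj$node_structures
  if (!is.null(ns)) {
    ns <- as.matrix(ns)
    colnames(ns) <- c("helix", "sheet", "turn", "bend", "loop")
  }
  structure(
    list(config = cfg, grid = grid,
         coords = node_coords(cfg$rows, cfg$cols),
         weights = as.matrix(obj$weights),
         node_structures = ns,
         occupancy = as.data.frame(obj$occupancy),
         quant_error = obj$quant_error),
    class = "trained_map")
}
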