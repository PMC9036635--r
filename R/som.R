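#' Self-organising map configuration
#'
#' Settings for training and prediction. The defaults follow common
#' practice for spectral SOMs: a 50 x 50 map, 5 best matching units (BMUs)
#' for prediction, online Kohonen updates with a Gaussian neighbourhood,
#' and learning rate / neighbourhood radius decaying exponentially from
#' their initial to final values over the training run.
#'
#' @param rows,cols map dimensions (nodes).
#' @param k_bmu number of best matching units used for prediction.
#' @param epochs passes over the reference set.
#' @param lr_initial,lr_final learning-rate schedule; `lr_initial >=
#'   lr_final > 0`.
#' @param radius_initial,radius_final Gaussian neighbourhood radius in map
#'   units; defaults `max(rows, cols)/2` down to 1.
#' @param n_neighbours reference entries averaged into each node's
#'   structure (see [assign_node_structures()]).
#' @param seed integer random seed; training is deterministic given the
#'   seed.
#' @return An object of class `som_config`.
#' @export
som_config <- function(rows = 50, cols = 50, k_bmu = 5, epochs = 100,
                       lr_initial = 0.5, lr_final = 0.01,
                       radius_initial = NULL, radius_final = 1,
                       n_neighbours = 5, seed = 1L) {
  if (is.null(radius_initial)) radius_initial <- max(rows, cols) / 2
  stopifnot(rows >= 1, cols >= 1, k_bmu >= 1, epochs >= 1, n_neighbours >= 1,
            lr_initial >= lr_final, lr_final > 0,
            radius_initial >= radius_final, radius_final >= 0)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         k_bmu = as.integer(k_bmu), epochs = as.integer(epochs),
         lr_initial = lr_initial, lr_final = lr_final,
         radius_initial = radius_initial, radius_final = radius_final,
         n_neighbours = as.integer(n_neighbours), seed = as.integer(seed)),
    class = "som_config")
}

# node coordinates in (row, col) lexicographic order; node index i maps to
# coords[i, ]. which.min() on distances therefore breaks ties
# lexicographically, which is the tie rule used everywhere.
node_coords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

#' Train a self-organising map on a reference set
#'
#' Classical online Kohonen training: spectra are presented in random order
#' each epoch; the winning node (smallest Euclidean distance over the
#' wavelength grid) and its Gaussian neighbourhood
#' `h = exp(-d_map^2 / (2 sigma^2))` are pulled toward the sample, with the
#' learning rate and `sigma` decaying exponentially across the run. Node
#' weights are initialised uniformly within the per-wavelength min/max
#' envelope of the reference spectra. Training is fully deterministic given
#' `config$seed`.
#'
#' After training each reference entry is assigned its winning node
#' ("occupancy"), which drives both node-structure assignment and the
#' numbered map layouts.
#'
#' @param refset a [reference_set()].
#' @param config a [som_config()].
#' @param assign_structures if `TRUE` (default) node structures are
#'   attached immediately via [assign_node_structures()] with
#'   `config$n_neighbours`.
#' @return An object of class `trained_map` with node `weights` (one
#'   prototype spectrum per row), `coords`, `node_structures`, `occupancy`
#'   (one winning node per reference entry) and the mean quantisation error
#'   `quant_error`.
#' @export
train_som <- function(refset, config = som_config(), assign_structures = TRUE) {
  stopifnot(inherits(refset, "reference_set"), inherits(config, "som_config"))
  X <- refset_matrix(refset)
  if (!all(is.finite(X))) stop("reference spectra contain non-finite values")
  n <- nrow(X)
  P <- ncol(X)
  N <- config$rows * config$cols
  coords <- node_coords(config$rows, config$cols)

  set.seed(config$seed)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  # P x N working copy; columns are nodes so colSums gives node distances
  Wt <- matrix(stats::runif(P * N), nrow = P) * (hi - lo) + lo

  total <- config$epochs * n
  lr0 <- config$lr_initial
  lr_ratio <- config$lr_final / lr0
  r0 <- config$radius_initial
  rf <- max(config$radius_final, 1e-3)
  step <- 0L
  denom <- max(total - 1L, 1L)
  for (ep in seq_len(config$epochs)) {
    for (i in sample.int(n)) {
      x <- X[i, ]
      d2 <- colSums((Wt - x)^2)
      b <- which.min(d2)
      frac <- step / denom
      lr <- lr0 * lr_ratio^frac
      sig <- max(r0 * (rf / r0)^frac, 1e-3)
      dmap2 <- (coords[, 1] - coords[b, 1])^2 + (coords[, 2] - coords[b, 2])^2
      h <- lr * exp(-dmap2 / (2 * sig^2))
      idx <- which(h > 1e-6)
      Wt[, idx] <- Wt[, idx] + (x - Wt[, idx]) * rep(h[idx], each = P)
      step <- step + 1L
    }
  }

  occ_node <- integer(n)
  qerr <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((Wt - X[i, ])^2)
    occ_node[i] <- which.min(d2)
    qerr[i] <- sqrt(d2[occ_node[i]])
  }
  occupancy <- data.frame(
    index = vapply(refset$entries, `[[`, integer(1), "index"),
    name = refset_names(refset),
    node = occ_node,
    row = coords[occ_node, 1],
    col = coords[occ_node, 2],
    stringsAsFactors = FALSE)

  map <- structure(
    list(config = config, grid = refset$grid, coords = coords,
         weights = t(Wt), node_structures = NULL, occupancy = occupancy,
         quant_error = mean(qerr)),
    class = "trained_map")
  if (assign_structures)
    map <- assign_node_structures(map, refset, config$n_neighbours)
  map
}

#' @export
print.trained_map <- function(x, ...) {
  cat(sprintf("<trained_map> %d x %d nodes on %g-%g nm, %d references, quantisation error %.4g%s\n",
              x$config$rows, x$config$cols, x$grid$start_nm, x$grid$end_nm,
              nrow(x$occupancy), x$quant_error,
              if (is.null(x$node_structures)) " (no node structures)" else ""))
  invisible(x)
}

#' Attach secondary-structure fractions to map nodes
#'
#' Each node's structure is the inverse-distance-weighted mean of the
#' annotations of the `n_neighbours` reference entries whose occupancy
#' nodes are nearest in map (grid) space; ties in map distance are broken
#' by spectral distance between the node prototype and the reference
#' spectrum. A node hosting a reference at map distance 0 takes that
#' reference's structure exactly (equal shares if several references share
#' the node).
#'
#' @param map a [train_som()] result.
#' @param refset the [reference_set()] the map was trained on.
#' @param n_neighbours number of reference entries per node; at most the
#'   reference-set size.
#' @return `map` with `node_structures` filled in (one row per node).
#' @export
assign_node_structures <- function(map, refset,
                                   n_neighbours = map$config$n_neighbours) {
  stopifnot(inherits(map, "trained_map"), inherits(refset, "reference_set"))
  n <- length(refset)
  if (n_neighbours > n)
    stop(sprintf("n_neighbours (%d) exceeds reference-set size (%d)",
                 n_neighbours, n))
  X <- refset_matrix(refset)
  S5 <- refset_structures(refset)
  W <- map$weights
  N <- nrow(W)
  # spectral node-to-reference distances, used only to break map-space ties
  Dspec <- outer(rowSums(W^2), rowSums(X^2), "+") - 2 * (W %*% t(X))
  occ_r <- map$occupancy$row
  occ_c <- map$occupancy$col
  NS <- matrix(0, N, 5)
  for (v in seq_len(N)) {
    dmap <- sqrt((map$coords[v, 1] - occ_r)^2 + (map$coords[v, 2] - occ_c)^2)
    sel <- order(dmap, Dspec[v, ])[seq_len(n_neighbours)]
    d <- dmap[sel]
    w <- if (any(d == 0)) {
      as.numeric(d == 0) / sum(d == 0)
    } else {
      (1 / d) / sum(1 / d)
    }
    NS[v, ] <- as.numeric(w %*% S5[sel, , drop = FALSE])
  }
  colnames(NS) <- c("helix", "sheet", "turn", "bend", "loop")
  map$node_structures <- NS
  map
}

check_query <- function(map, query) {
  stopifnot(inherits(map, "trained_map"), inherits(query, "cd_spectrum"))
  if (!same_grid(query$grid, map$grid))
    stop("query spectrum is not on the map's wavelength grid")
}

#' Find the best matching units for a query spectrum
#'
#' The `k` nodes whose prototype spectra are closest (Euclidean) to the
#' query, ranked by distance with ties broken by (row, col).
#'
#' @param map a [trained_map()].
#' @param query a [cd_spectrum()] on the map grid.
#' @param k number of BMUs (default the map's `k_bmu`).
#' @return Data frame with columns `rank`, `node`, `row`, `col`,
#'   `distance` (non-decreasing with rank).
#' @export
find_bmus <- function(map, query, k = map$config$k_bmu) {
  check_query(map, query)
  N <- nrow(map$weights)
  if (k > N) stop(sprintf("k (%d) exceeds the node count (%d)", k, N))
  d <- sqrt(colSums((t(map$weights) - query$values)^2))
  ord <- order(d, map$coords[, 1], map$coords[, 2])[seq_len(k)]
  data.frame(rank = seq_len(k), node = ord,
             row = map$coords[ord, 1], col = map$coords[ord, 2],
             distance = d[ord])
}

#' Fit a query spectrum against a trained map
#'
#' Predicts secondary structure and a reconstructed spectrum from the
#' query's `k_bmu` best matching units. BMU `i` receives weight
#' `(1/d_i) / sum_j (1/d_j)`; a BMU at distance 0 takes all the weight
#' (shared equally if several are at 0). The predicted spectrum and the
#' 5-class structure are the weighted averages of the BMU prototypes and
#' node structures; the 3-class structure is their [collapse_structure()];
#' `nrmsd` measures the reconstruction against the query.
#' `neighbour_references` lists the reference entries whose occupancy nodes
#' lie within `neighbour_radius` map units of each BMU — inspecting them
#' (e.g. for beta-II members) is how ambiguous fits are understood.
#'
#' @param map a [trained_map()] with node structures assigned.
#' @param query a [cd_spectrum()] on the map grid.
#' @param k number of BMUs (default the map's `k_bmu`).
#' @param neighbour_radius map-distance radius for `neighbour_references`.
#' @return An object of class `som_fit` with elements `predicted_spectrum`,
#'   `structure5`, `structure3`, `nrmsd`, `bmus`, `bmu_weights`,
#'   `neighbour_references`.
#' @export
som_predict <- function(map, query, k = map$config$k_bmu,
                        neighbour_radius = 3) {
  check_query(map, query)
  if (is.null(map$node_structures))
    stop("map has no node structures; call assign_node_structures() first")
  bm <- find_bmus(map, query, k)
  d <- bm$distance
  w <- if (any(d == 0)) as.numeric(d == 0) / sum(d == 0) else (1 / d) / sum(1 / d)
  pred <- as.numeric(w %*% map$weights[bm$node, , drop = FALSE])
  s5v <- as.numeric(w %*% map$node_structures[bm$node, , drop = FALSE])
  s5 <- structure_fractions5(s5v[1], s5v[2], s5v[3], s5v[4], s5v[5])
  pred_spec <- cd_spectrum(pred, map$grid,
                           label = paste0("fit:", query$label),
                           temperature_C = query$temperature_C)
  neigh <- do.call(rbind, lapply(seq_len(nrow(bm)), function(i) {
    dm <- sqrt((bm$row[i] - map$occupancy$row)^2 +
                 (bm$col[i] - map$occupancy$col)^2)
    keep <- which(dm <= neighbour_radius)
    if (!length(keep)) return(NULL)
    data.frame(bmu_rank = bm$rank[i],
               index = map$occupancy$index[keep],
               name = map$occupancy$name[keep],
               map_distance = dm[keep], stringsAsFactors = FALSE)
  }))
  structure(
    list(predicted_spectrum = pred_spec, structure5 = s5,
         structure3 = collapse_structure(s5),
         nrmsd = nrmsd(query, pred_spec), bmus = bm, bmu_weights = w,
         neighbour_references = neigh, query_label = query$label),
    class = "som_fit")
}

#' @export
predict.trained_map <- function(object, query, ...) {
  som_predict(object, query, ...)
}

#' @export
print.som_fit <- function(x, ...) {
  s <- x$structure3
  cat(sprintf("<som_fit> '%s': helix %.2f sheet %.2f other %.2f, NRMSD %.4f\n",
              x$query_label, s["helix"], s["sheet"], s["other"], x$nrmsd))
  cat(sprintf("  BMUs: %s\n",
              paste(sprintf("(%d,%d)", x$bmus$row, x$bmus$col), collapse = " ")))
  invisible(x)
}

#' Map-layout records for plotting
#'
#' Returns the plottable content of the numbered map figures: the
#' occupancy coordinate of every reference entry (labelled by its file
#' ordinal) and, when a fit is supplied, the coordinates of its BMUs (the
#' "red dots").
#'
#' @param map a [trained_map()].
#' @param fit optional [som_predict()] result.
#' @return List with `references` (index, name, row, col), `bmus` (row,
#'   col, rank; `NULL` without a fit) and `extent` (rows, cols).
#' @export
map_layout <- function(map, fit = NULL) {
  stopifnot(inherits(map, "trained_map"))
  refs <- map$occupancy[, c("index", "name", "row", "col")]
  bm <- if (is.null(fit)) NULL else fit$bmus[, c("row", "col", "rank")]
  list(references = refs, bmus = bm,
       extent = c(rows = map$config$rows, cols = map$config$cols))
}

#' @export
plot.trained_map <- function(x, fit = NULL, ...) {
  lay <- map_layout(x, fit)
  plot(NA, xlim = c(0.5, lay$extent["cols"] + 0.5),
       ylim = c(0.5, lay$extent["rows"] + 0.5),
       xlab = "map column", ylab = "map row", ...)
  text(lay$references$col, lay$references$row,
       labels = lay$references$index, cex = 0.7)
  if (!is.null(lay$bmus))
    points(lay$bmus$col, lay$bmus$row, pch = 19, col = "red")
  invisible(lay)
}
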