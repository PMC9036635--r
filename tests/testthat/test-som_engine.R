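test_that("training is deterministic given seed and config", {
  refset <- make_reference_set(8, seed = 2)
  cfg <- som_config(rows = 6, cols = 6, epochs = 30, seed = 13)
  m1 <- train_som(refset, cfg)
  m2 <- train_som(refset, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$occupancy, m2$occupancy)
  expect_identical(m1$node_structures, m2$node_structures)
})

test_that("a 1x1 map converges toward the reference mean", {
  refset <- make_reference_set(6, seed = 4)
  cfg <- som_config(rows = 1, cols = 1, epochs = 400, lr_final = 0.001,
                    radius_final = 0, seed = 1)
  map <- train_som(refset, cfg)
  X <- t(vapply(refset$entries, function(e) e$spectrum$values, numeric(51)))
  target <- colMeans(X)
  expect_lt(max(abs(map$weights[1, ] - target)), 0.05 * max(abs(target)))
  expect_true(all(map$occupancy$node == 1))
})

test_that("a single reference spectrum becomes an attractor", {
  refset <- make_reference_set(1, seed = 6)
  map <- train_som(refset, som_config(rows = 4, cols = 4, epochs = 300,
                                      lr_final = 0.001, radius_final = 0.2,
                                      seed = 3),
                   assign_structures = FALSE)
  bm <- find_bmus(map, refset$entries[[1]]$spectrum, k = 1)
  expect_lt(bm$distance, 1e-2)
})

test_that("BMU search equals an exhaustive distance sort", {
  set.seed(99)
  for (dims in list(c(3, 3), c(4, 5))) {
    W <- matrix(rnorm(prod(dims) * 10), nrow = prod(dims))
    map <- toy_map(W, rows = dims[1], cols = dims[2])
    for (rep in 1:10) {
      q <- toy_spectrum(rnorm(10))
      got <- find_bmus(map, q, k = nrow(W))
      d <- sqrt(colSums((t(W) - q$values)^2))
      ord <- order(d, map$coords[, 1], map$coords[, 2])
      expect_equal(got$node, ord)
      expect_equal(got$distance, d[ord])
      expect_true(all(diff(got$distance) >= 0))
    }
  }
})

test_that("BMU edge cases: exact match, k = node count, grid mismatch", {
  set.seed(1)
  W <- matrix(rnorm(9 * 5), nrow = 9)
  map <- toy_map(W, rows = 3, cols = 3)
  q <- toy_spectrum(W[7, ])
  bm <- find_bmus(map, q, k = 1)
  expect_equal(bm$node, 7)
  expect_equal(bm$distance, 0)
  expect_equal(nrow(find_bmus(map, q, k = 9)), 9)
  expect_error(find_bmus(map, q, k = 10), "node count")
  expect_error(find_bmus(map, toy_spectrum(rnorm(4)), k = 1), "grid")
})

test_that("node structures: zero-distance host and symmetric average", {
  # 1x3 map; refs occupy the end nodes; the centre node is map-equidistant
  g <- wavelength_grid(240, 237, 1)
  a <- c(1, 0, 0, 0)
  b <- c(0, 0, 0, 1)
  W <- rbind(a, (a + b) / 2, b)
  refset <- reference_set(list(
    reference_entry(cd_spectrum(a, g), structure_fractions5(1, 0, 0, 0, 0), "A", 1),
    reference_entry(cd_spectrum(b, g), structure_fractions5(0, 1, 0, 0, 0), "B", 2)))
  occ <- data.frame(index = 1:2, name = c("A", "B"), node = c(1L, 3L),
                    row = c(1L, 1L), col = c(1L, 3L))
  map <- toy_map(W, rows = 1, cols = 3, grid = g, occupancy = occ)

  m1 <- assign_node_structures(map, refset, n_neighbours = 1)
  expect_equal(unname(m1$node_structures[1, ]), c(1, 0, 0, 0, 0))
  expect_equal(unname(m1$node_structures[3, ]), c(0, 1, 0, 0, 0))

  m2 <- assign_node_structures(map, refset, n_neighbours = 2)
  expect_equal(unname(m2$node_structures[2, ]), c(0.5, 0.5, 0, 0, 0))
  # hosts still take their reference verbatim (zero map distance dominates)
  expect_equal(unname(m2$node_structures[1, ]), c(1, 0, 0, 0, 0))

  expect_error(assign_node_structures(map, refset, n_neighbours = 3),
               "exceeds")
})

test_that("node structures match a brute-force inverse-distance oracle", {
  g <- wavelength_grid(240, 236, 1)
  set.seed(21)
  W <- matrix(rnorm(4 * 5), nrow = 4)  # 2x2 map
  S <- rbind(c(0.6, 0.2, 0.1, 0.05, 0.05),
             c(0.1, 0.7, 0.1, 0.05, 0.05),
             c(0.2, 0.2, 0.2, 0.2, 0.2))
  specs <- lapply(1:3, function(i) cd_spectrum(rnorm(5), g))
  refset <- reference_set(lapply(1:3, function(i)
    reference_entry(specs[[i]],
                    structure_fractions5(S[i, 1], S[i, 2], S[i, 3], S[i, 4], S[i, 5]),
                    LETTERS[i], i)))
  occ <- data.frame(index = 1:3, name = LETTERS[1:3], node = c(1L, 2L, 4L),
                    row = c(1L, 1L, 2L), col = c(1L, 2L, 2L))
  map <- toy_map(W, rows = 2, cols = 2, grid = g, occupancy = occ)
  got <- assign_node_structures(map, refset, n_neighbours = 2)$node_structures

  coords <- map$coords
  for (v in 1:4) {
    dmap <- sqrt((coords[v, 1] - occ$row)^2 + (coords[v, 2] - occ$col)^2)
    dspec <- vapply(specs, function(s) sum((W[v, ] - s$values)^2), numeric(1))
    sel <- order(dmap, dspec)[1:2]
    d <- dmap[sel]
    w <- if (any(d == 0)) as.numeric(d == 0) / sum(d == 0) else (1 / d) / sum(1 / d)
    expect_equal(unname(got[v, ]), as.numeric(w %*% S[sel, ]), tolerance = 1e-12)
  }
})

test_that("prediction arithmetic follows the inverse-distance BMU weighting", {
  g <- wavelength_grid(240, 237, 1)
  W <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  S <- rbind(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1),
             c(0, 1, 0, 0, 0), c(0, 0, 1, 0, 0))
  map <- toy_map(W, structures = S, rows = 2, cols = 2, grid = g, k_bmu = 2)

  # query equal to a node weight: that node dominates entirely
  fit <- som_predict(map, cd_spectrum(W[3, ], g))
  expect_equal(fit$nrmsd, 0)
  expect_equal(fit$predicted_spectrum$values, W[3, ])
  expect_equal(as.numeric(fit$structure5), S[3, ])

  # two BMUs at equal distance with structures e_helix / e_loop -> midpoint
  q <- cd_spectrum(c(0.5, 0.5, -1, -1), g)  # equidistant from nodes 1 and 2
  fit2 <- som_predict(map, q, k = 2)
  expect_equal(sort(fit2$bmus$node[1:2]), c(1, 2))
  expect_equal(as.numeric(fit2$structure5), c(0.5, 0, 0, 0, 0.5))

  # general query: hand-computed inverse-distance average over k = 2 BMUs
  q3 <- cd_spectrum(c(0.9, 0.2, 0.1, 0), g)
  d <- sqrt(rowSums(sweep(W, 2, q3$values)^2))
  sel <- order(d)[1:2]
  w <- (1 / d[sel]) / sum(1 / d[sel])
  fit3 <- som_predict(map, q3, k = 2)
  expect_equal(fit3$predicted_spectrum$values, as.numeric(w %*% W[sel, ]),
               tolerance = 1e-12)
  expect_equal(as.numeric(fit3$structure5), as.numeric(w %*% S[sel, ]),
               tolerance = 1e-12)
  expect_equal(sum(fit3$bmu_weights), 1)
  expect_equal(fit3$nrmsd, nrmsd(q3, fit3$predicted_spectrum))
})

test_that("prediction requires node structures", {
  refset <- make_reference_set(4, seed = 8)
  map <- train_som(refset, som_config(rows = 3, cols = 3, epochs = 10, seed = 1),
                   assign_structures = FALSE)
  expect_error(som_predict(map, refset$entries[[1]]$spectrum),
               "node structures")
})

test_that("map layout lists numbered references and BMU markers", {
  map <- demo_map()
  refset <- demo_refset()
  lay <- map_layout(map)
  expect_equal(nrow(lay$references), length(refset))
  expect_equal(lay$references$index, seq_len(length(refset)))
  expect_null(lay$bmus)

  fit <- som_predict(map, refset$entries[[1]]$spectrum)
  lay2 <- map_layout(map, fit)
  expect_equal(nrow(lay2$bmus), 5)
  expect_equal(unname(lay2$extent), c(15, 15))
})

test_that("map persistence round-trips exactly", {
  map <- demo_map()
  path <- withr::local_tempfile(fileext = ".json")
  write_som_map(map, path)
  back <- read_som_map(path)
  expect_equal(back$weights, map$weights, tolerance = 1e-12)
  expect_equal(unname(back$node_structures), unname(map$node_structures),
               tolerance = 1e-12)
  expect_equal(back$occupancy$node, map$occupancy$node)
  q <- demo_refset()$entries[[3]]$spectrum
  f1 <- som_predict(map, q)
  f2 <- som_predict(back, q)
  expect_equal(f1$nrmsd, f2$nrmsd)
  expect_equal(f1$bmus, f2$bmus)
})
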