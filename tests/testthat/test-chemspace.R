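test_that("descriptor matrices have the documented shape and scaling", {
  mols <- mols_from_smiles(c("CCO", "CCO", "c1ccccc1", "CCCCCC", "c1ccncc1"))
  X <- compute_descriptors(mols)
  expect_equal(ncol(X), 4 + 2048)
  expect_identical(X[1, ], X[2, ])  # identical molecules, identical rows
  props <- X[, 1:4]
  expect_equal(unname(colMeans(props)), rep(0, 4), tolerance = 1e-10)
  nz <- apply(props, 2, sd) > 0
  expect_equal(unname(apply(props, 2, sd)[nz]),
               rep(1, sum(nz)), tolerance = 1e-10)
  # fingerprint block stays binary
  expect_true(all(X[, 5:ncol(X)] %in% c(0, 1)))
})

test_that("embedding is seeded-deterministic and stays in the unit square", {
  set.seed(1)
  X <- matrix(rnorm(40 * 8), 40)
  m1 <- embed_2d(X, labels = rep(c("A", "B"), 20), seed = 7, n_iter = 150)
  m2 <- embed_2d(X, labels = rep(c("A", "B"), 20), seed = 7, n_iter = 150)
  expect_identical(m1$points, m2$points)
  expect_equal(nrow(m1$points), 40)
  expect_true(all(m1$points$x >= 0 & m1$points$x <= 1))
  expect_true(all(m1$points$y >= 0 & m1$points$y <= 1))
})

test_that("well-separated descriptor blobs stay separated in the map", {
  set.seed(2)
  X <- rbind(matrix(rnorm(30 * 10, 0), ncol = 10),
             matrix(rnorm(30 * 10, 12), ncol = 10))
  map <- embed_2d(X, labels = rep(c("A", "B"), each = 30), seed = 3,
                  n_iter = 300)
  pts <- map$points
  a <- as.matrix(pts[pts$label == "A", c("x", "y")])
  b <- as.matrix(pts[pts$label == "B", c("x", "y")])
  within <- mean(c(dist(a), dist(b)))
  between <- mean(sqrt(outer(a[, 1], b[, 1], "-")^2 +
                         outer(a[, 2], b[, 2], "-")^2))
  expect_lt(within, between)
})

test_that("a single disc recovers pi r^2 within rasterization tolerance", {
  map <- structure(list(
    points = tibble::tibble(record_id = c("p", "q"), x = 0.5, y = 0.5,
                            label = c("A", "B")),
    radius = 0.02, seed = 1), class = "embedding_map")
  ov <- buffered_overlap(map, resolution = 1024)
  expect_equal(ov$area_a, pi * 0.02^2, tolerance = 0.01)
  expect_equal(ov$area_overlap, pi * 0.02^2, tolerance = 0.01)
  expect_equal(ov$overlap_fraction_a, 1, tolerance = 0.01)
})

test_that("two-disc intersection matches the closed-form lens area", {
  r <- 0.02; d <- 0.025
  map <- structure(list(
    points = tibble::tibble(record_id = c("p", "q"),
                            x = c(0.5, 0.5 + d), y = 0.5,
                            label = c("A", "B")),
    radius = r, seed = 1), class = "embedding_map")
  ov <- buffered_overlap(map, resolution = 1024)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  expect_equal(ov$area_overlap, lens, tolerance = 0.01)
})

test_that("identical collections overlap completely and A/B swap is symmetric", {
  set.seed(4)
  pts <- tibble::tibble(x = runif(15), y = runif(15))
  map <- structure(list(
    points = dplyr::bind_rows(
      dplyr::mutate(pts, record_id = sprintf("a%02d", 1:15), label = "A"),
      dplyr::mutate(pts, record_id = sprintf("b%02d", 1:15), label = "B")),
    radius = 0.02, seed = 1), class = "embedding_map")
  ov <- buffered_overlap(map, resolution = 512)
  expect_equal(ov$overlap_fraction_a, 1, tolerance = 1e-6)
  expect_equal(ov$overlap_fraction_b, 1, tolerance = 1e-6)
  # swap labels
  map2 <- map
  map2$points$label <- ifelse(map2$points$label == "A", "B", "A")
  ov2 <- buffered_overlap(map2, resolution = 512)
  expect_equal(ov2$area_a, ov$area_a)
  expect_equal(ov2$area_b, ov$area_b)
  expect_equal(ov2$area_overlap, ov$area_overlap)
})

test_that("doubling the raster resolution changes areas by under 0.5%", {
  set.seed(6)
  map <- structure(list(
    points = tibble::tibble(record_id = sprintf("p%02d", 1:20),
                            x = runif(20), y = runif(20),
                            label = rep(c("A", "B"), 10)),
    radius = 0.03, seed = 1), class = "embedding_map")
  o1 <- buffered_overlap(map, resolution = 1024)
  o2 <- buffered_overlap(map, resolution = 2048)
  expect_lt(abs(o1$area_a - o2$area_a) / o2$area_a, 0.005)
  expect_lt(abs(o1$area_b - o2$area_b) / o2$area_b, 0.005)
})

test_that("invalid radii are rejected", {
  map <- structure(list(points = tibble::tibble(
    record_id = "p", x = 0.5, y = 0.5, label = "A"),
    radius = -1, seed = 1), class = "embedding_map")
  expect_error(buffered_overlap(map), "radius")
  expect_error(embed_2d(matrix(rnorm(50), 10), labels = rep("A", 10),
                        radius = 0), "radius")
})
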