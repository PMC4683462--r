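# Chromatic-locus rasterization and occupancy summaries

test_that("points map to half-open cells exactly as brute-force binning", {
  # grid arithmetic at the cell boundary (default origin)
  two <- rbind(c(0.001, 0.005, 0.005), c(0.031, 0.005, 0.005))
  m <- rasterize_loci(two)
  expect_equal(nrow(m), 2)
  expect_equal(sort(m$ix), c(0L, 1L))
  # single point, repeated points
  one <- rasterize_loci(matrix(c(0.01, 0.01, 0.01), 1))
  expect_equal(one$count, 1L)
  ten <- rasterize_loci(matrix(rep(c(0.01, 0.01, 0.01), 10), ncol = 3,
                               byrow = TRUE))
  expect_equal(nrow(ten), 1)
  expect_equal(ten$count, 10L)
  # oracle equivalence on random points, including negative coordinates
  set.seed(9)
  p <- cbind(runif(300, -0.7, 0.7), runif(300, -0.7, 0.7),
             runif(300, -0.7, 0.7))
  map <- rasterize_loci(p, cell_size = 0.022)
  oracle <- brute_bin(p, 0.022)
  colnames(oracle) <- c("ix", "iy", "iz")
  got <- tibble::as_tibble(oracle) |>
    dplyr::count(ix, iy, iz, name = "count") |>
    dplyr::arrange(ix, iy, iz)
  expect_equal(as.data.frame(map)[, c("ix", "iy", "iz", "count")],
               as.data.frame(got))
  expect_equal(sum(map$count), 300)
})

test_that("direct 3D flooring equals the intersection of yz and yx 2D grids", {
  set.seed(12)
  p <- random_tetra_points(400)
  map3 <- rasterize_loci(p, 0.022)
  gyz <- project_2d(p, "yz", 0.022)
  gyx <- project_2d(p, "yx", 0.022)
  # combining the two 2D cell identities (sharing the y axis) must give the
  # same 3D cell count
  idx <- floor(cbind(p[, 1], p[, 2], p[, 3]) / 0.022)
  key_2d <- paste(idx[, 2], idx[, 3], "|", idx[, 2], idx[, 1])
  expect_equal(nrow(map3), length(unique(key_2d)))
  # marginalization: summing the 3D map over x reproduces the yz grid
  marg <- dplyr::count(as.data.frame(map3), iy, iz, wt = count, name = "count")
  expect_equal(dplyr::arrange(marg, iy, iz)$count,
               dplyr::arrange(as.data.frame(gyz), i1, i2)$count)
})

test_that("locus summaries measure occupancy and mass concentration", {
  p100 <- matrix(rep(c(0.001, 0.001, 0.001), 100), ncol = 3, byrow = TRUE)
  s1 <- locus_summary(rasterize_loci(p100))
  expect_equal(s1$n_occupied, 1)
  expect_equal(s1$mass_fraction, 1)
  # 99 points in one cell, 1 in another: half the mass sits in 1 of 2 loci
  p2 <- rbind(p100[1:99, ], c(0.5, 0.5, 0.1))
  s2 <- locus_summary(rasterize_loci(p2))
  expect_equal(s2$n_occupied, 2)
  expect_equal(s2$mass_fraction, 0.5)
  # pigeonhole: loci never exceed distinct points
  set.seed(2)
  p <- random_tetra_points(200)
  expect_lte(locus_summary(rasterize_loci(p))$n_occupied, 200)
  # empty input
  s0 <- locus_summary(rasterize_loci(p[0, , drop = FALSE]))
  expect_equal(s0$n_occupied, 0)
})

test_that("shared and unique loci partition the union", {
  set.seed(14)
  a <- rasterize_loci(random_tetra_points(150))
  expect_equal(shared_unique_loci(a, a)$frac_shared, 1)
  b <- rasterize_loci(sweep(random_tetra_points(150), 2, c(5, 5, 5), "+"))
  disj <- shared_unique_loci(a, b)
  expect_equal(disj$n_shared, 0)
  expect_equal(disj$frac_only_a + disj$frac_only_b, 1)
  # subset: a's loci within (a union b) are never unique to a smaller set
  p <- random_tetra_points(200)
  sub <- rasterize_loci(p[1:50, ])
  full <- rasterize_loci(p)
  part <- shared_unique_loci(sub, full)
  expect_equal(part$n_only_a, 0)
  expect_equal(part$n_shared, nrow(sub))
  # mismatched grids are an error
  c1 <- rasterize_loci(p, cell_size = 0.05)
  expect_error(shared_unique_loci(full, c1), "grid")
})
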