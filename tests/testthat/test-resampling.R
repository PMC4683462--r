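# Bootstrap machinery: sex ratios, order nulls, p-values

make_points <- function(n_species, seed = 1, sexes = c("male", "female")) {
  withr::with_seed(seed, {
    sp <- sprintf("sp%02d", seq_len(n_species))
    do.call(rbind, lapply(sexes, function(sx) {
      p <- as.data.frame(random_tetra_points(n_species * 17))
      p$species <- rep(sp, each = 17)
      p$order <- rep(rep(c("A", "B"), length.out = n_species), each = 17)
      p$sex <- sx
      p
    }))
  })
}

test_that("two-tailed bootstrap p follows the doubled-smaller-tail formula", {
  expect_equal(two_tailed_p(rep(5, 100), 5), 1)
  # observed below all 9999 replicates
  expect_equal(two_tailed_p(seq_len(9999), 0), 2e-4)
  # observed at the median is maximally unsurprising
  expect_equal(two_tailed_p(1:101, 51), 1)
  # raw (uncorrected) variant recovers the plain proportion
  expect_equal(two_tailed_p(1:100, 0, correction = FALSE), 0)
  expect_equal(two_tailed_p(1:100, 3, correction = FALSE), 2 * 3 / 100)
})

test_that("sex-ratio bootstrap: identical sexes give ratio exactly 1", {
  pts <- make_points(12, seed = 5, sexes = "male")
  both <- rbind(pts, transform(pts, sex = "female"))
  for (met in c("n_loci", "hull_volume")) {
    bs <- bootstrap_sex_ratio(both, met, B = 50, seed = 3)
    expect_equal(bs$replicates, rep(1, 50))
    expect_equal(bs$median, 1)
  }
})

test_that("sex-ratio bootstrap respects monotonicity and seeding", {
  pts <- make_points(15, seed = 6, sexes = "male")
  # female points are a strict per-species subset of male points
  fem <- do.call(rbind, lapply(split(pts, pts$species),
                               function(d) d[1:8, ]))
  fem$sex <- "female"
  both <- rbind(pts, fem)
  bs <- bootstrap_sex_ratio(both, "n_loci", B = 60, seed = 9)
  expect_true(all(bs$replicates <= 1 + 1e-12))
  expect_lte(bs$q025, bs$median)
  expect_lte(bs$median, bs$q975)
  expect_equal(length(bs$replicates), 60)
  bs2 <- bootstrap_sex_ratio(both, "n_loci", B = 60, seed = 9)
  expect_identical(bs$replicates, bs2$replicates)
  # species missing one sex are excluded rather than crashing
  extra <- pts[pts$species == "sp01", ]
  extra$species <- "maleonly"
  bs3 <- bootstrap_sex_ratio(rbind(both, extra), "n_loci", B = 10, seed = 2)
  expect_equal(length(bs3$replicates), 10)
})

test_that("order-null bootstrap covers degenerate and singleton draws", {
  pts <- make_points(10, seed = 7, sexes = "male")
  pts$order <- "A" # the 'order' is the entire avifauna
  whole <- bootstrap_order_null(pts, order = "A", metric = "n_loci", B = 40,
                                seed = 4, replace = FALSE)
  expect_equal(whole$observed, 100)
  expect_equal(whole$replicates, rep(100, 40))
  expect_equal(whole$p_two_tailed, 1)
  # n = 1 replicates span singleton-species gamuts
  single <- bootstrap_order_null(pts, n_species = 1, metric = "n_loci",
                                 B = 50, seed = 5)
  per_species <- vapply(split(pts, pts$species),
                        function(d) nrow(rasterize_loci(d)), 1L)
  full <- nrow(rasterize_loci(pts))
  expect_true(all(single$replicates %in% (100 * per_species / full)))
  expect_error(bootstrap_order_null(pts, n_species = 0), "n_species")
  expect_error(bootstrap_order_null(pts, order = "Nope"), "no species")
  # seeded determinism
  a <- bootstrap_order_null(pts, n_species = 4, metric = "n_loci", B = 30,
                            seed = 11)
  b <- bootstrap_order_null(pts, n_species = 4, metric = "n_loci", B = 30,
                            seed = 11)
  expect_identical(a$replicates, b$replicates)
})

test_that("larger B shrinks the Monte-Carlo spread of the bootstrap median", {
  pts <- make_points(12, seed = 8)
  meds <- function(B, seeds) vapply(seeds, function(s)
    bootstrap_sex_ratio(pts, "n_loci", B = B, seed = s)$median, numeric(1))
  sd_small <- sd(meds(40, 1:12))
  sd_large <- sd(meds(400, 1:12))
  expect_lt(sd_large, sd_small)
})
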