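# Cone templates, quantum catches and the tetrahedral embedding

test_that("cone template peaks where asked and stays in [0, 1]", {
  for (lm in c(372, 419, 500, 609)) {
    cv <- cone_template(lm)
    nearest <- std_grid()[which.min(abs(std_grid() - lm))]
    expect_equal(std_grid()[which.max(cv)], nearest)
    expect_gte(min(cv), 0)
    expect_equal(max(cv), 1)
  }
  # a UV-shifted cone is more sensitive at 340 nm than a violet-shifted one
  u372 <- cone_template(372); u419 <- cone_template(419)
  expect_gt(u372[std_grid() == 340], u419[std_grid() == 340])
  expect_error(cone_template(250), "outside")
})

test_that("sensitivity sets are deterministic and round-trip through CSV", {
  a <- build_sensitivity_set("U")
  b <- build_sensitivity_set("U")
  expect_identical(a$curves, b$curves)
  # V-type u-cone peaks at longer wavelength than U-type
  v <- build_sensitivity_set("V")
  expect_gt(std_grid()[which.max(v$curves[, "u"])],
            std_grid()[which.max(a$curves[, "u"])])
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_set(a, f)
  back <- build_sensitivity_set(file = f)
  expect_equal(back$curves, a$curves, tolerance = 1e-12)
  # missing cone column is a format error
  tab <- readr::read_csv(f, show_col_types = FALSE)
  readr::write_csv(tab[, c("wavelength_nm", "u", "s", "m")], f)
  expect_error(build_sensitivity_set(file = f), "columns")
})

test_that("quantum catches follow the rectangle-rule definition", {
  sens <- build_sensitivity_set("U")
  curves <- list(zero = rep(0, 81), full = rep(100, 81), half = rep(50, 81))
  q <- quantum_catches(resample_spectra(make_set(curves)), sens)
  qz <- q[q$species == "zero", c("qu", "qs", "qm", "ql")]
  expect_equal(unlist(qz), c(qu = 0, qs = 0, qm = 0, ql = 0))
  # R = 100% with flat irradiance: catch equals each cone's curve sum
  qf <- q[q$species == "full", ]
  expect_equal(c(qf$qu, qf$qs, qf$qm, qf$ql), unname(colSums(sens$curves)),
               tolerance = 1e-12)
  # homogeneity: halving reflectance halves every catch
  qh <- q[q$species == "half", ]
  expect_equal(c(qh$qu, qh$qs, qh$qm, qh$ql),
               0.5 * c(qf$qu, qf$qs, qf$qm, qf$ql), tolerance = 1e-12)
  # grid mismatch is an error
  expect_error(quantum_catches(make_set(list(a = rep(1, 81)))[1:50, ], sens),
               "grid")
})

test_that("relative catches normalize to the simplex and reject all-zero", {
  q <- tibble::tibble(spectrum_id = c("a", "b", "c"),
                      qu = c(1, 2, 1), qs = c(1, 0, 2), qm = c(1, 0, 3),
                      ql = c(1, 0, 4))
  f <- relative_catches(q)
  expect_equal(unlist(f[1, c("u", "s", "m", "l")]),
               c(u = .25, s = .25, m = .25, l = .25))
  expect_equal(unlist(f[2, c("u", "s", "m", "l")]), c(u = 1, s = 0, m = 0, l = 0))
  expect_equal(unlist(f[3, c("u", "s", "m", "l")]),
               c(u = .1, s = .2, m = .3, l = .4))
  q$qu[1] <- -1 # makes row sum zero
  q[1, c("qs", "qm", "ql")] <- list(1, 0, 0)
  q[1, c("qu")] <- 0; q[1, c("qs")] <- 0; q[1, c("qm")] <- 0; q[1, "ql"] <- 0
  expect_error(relative_catches(q), "degenerate")
})

test_that("the tetrahedral embedding is regular, oriented and bounded", {
  # achromatic point at the origin
  expect_equal(unname(tetra_coords(matrix(rep(0.25, 4), 1))[1, ]),
               c(0, 0, 0))
  v <- tetra_vertices()
  # L vertex at the apex, U vertex at the derived position
  expect_equal(unname(v[4, ]), c(0, 0, 0.75))
  expect_equal(unname(v[1, ]), c(sqrt(3 / 8), -1 / (2 * sqrt(2)), -0.25),
               tolerance = 1e-12)
  # circumradius 0.75 and pairwise equidistant edges sqrt(3/2)
  expect_equal(unname(sqrt(rowSums(v^2))), rep(0.75, 4))
  d <- as.matrix(dist(v))
  expect_equal(unname(d[upper.tri(d)]), rep(sqrt(3 / 2), 6))
  # every simplex point maps within the distance bound
  set.seed(11)
  p <- random_tetra_points(500)
  expect_lte(max(sqrt(rowSums(p^2))), 0.75 + 1e-9)
  # affinity of the map
  f1 <- c(0.1, 0.2, 0.3, 0.4); f2 <- c(0.7, 0.1, 0.1, 0.1)
  for (al in c(0, 0.3, 0.8, 1)) {
    lhs <- tetra_coords(matrix(al * f1 + (1 - al) * f2, 1))
    rhs <- al * tetra_coords(matrix(f1, 1)) + (1 - al) * tetra_coords(matrix(f2, 1))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_error(tetra_coords(matrix(c(0.5, 0.5, 0.5, 0.5), 1)), "simplex")
})

test_that("species-sex aggregation averages coordinates and keeps means inside", {
  pts <- tibble::tibble(
    species = c("a", "a", "b"), order = "o", sex = "male",
    patch = "breast", x = c(0, 0, 0.1), y = c(0, 0, 0.1),
    z = c(0.2, 0.4, 0.3))
  agg <- aggregate_species_sex(pts)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$z[agg$species == "a"], 0.3)
  expect_equal(agg$n_specimens[agg$species == "a"], 2)
  # convexity: means of simplex images stay inside the tetrahedron
  set.seed(3)
  p <- as.data.frame(random_tetra_points(60))
  p$species <- rep(c("s1", "s2", "s3"), each = 20)
  p$order <- "o"; p$sex <- "female"; p$patch <- "crown"
  m <- aggregate_species_sex(p)
  expect_lte(max(sqrt(m$x^2 + m$y^2 + m$z^2)), 0.75)
})
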