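# The synthetic avifauna generator: shapes, truth labels, determinism

test_that("family curves carry their defining features", {
  wl <- std_grid()
  # amplitude 0 melanin is exactly flat at baseline
  g <- gen_spectrum(list(family = "melanin", baseline = 12, amplitude = 0,
                         saturating = FALSE, tau = 200, noise_sd = 0))
  expect_equal(g$reflectance_pct, rep(12, 81))
  # all families stay within [0, 100] even with noise
  set.seed(17)
  for (fm in c("melanin", "white", "carotenoid", "structural",
               "carotenoid_structural")) {
    for (i in 1:10) {
      y <- gen_spectrum(sample_family_params(fm, noise_sd = 3))$reflectance_pct
      expect_true(all(y >= 0 & y <= 100))
    }
  }
  # pathological parameters are clipped with a warning
  expect_warning(gen_spectrum(list(family = "white", baseline = 120,
                                   noise_sd = 0)), "clipping")
})

test_that("noise-free spectra are recovered by the classifier (round-trip)", {
  set.seed(23)
  for (fm in c("structural", "carotenoid", "carotenoid_structural")) {
    for (i in 1:10) {
      g <- gen_spectrum(sample_family_params(fm, noise_sd = 0))
      lab <- classify_mechanism(spectral_features(g$reflectance_pct),
                                order = "Passeriformes")
      expect_equal(lab, fm)
    }
  }
  # a parrot-like order flips carotenoid shapes to psittacofulvin end to end
  g <- withr::with_seed(3, gen_spectrum(sample_family_params("psittacofulvin",
                                                             noise_sd = 0)))
  expect_equal(classify_mechanism(spectral_features(g$reflectance_pct),
                                  order = "Psittaciformes"),
               "psittacofulvin")
})

test_that("gen_avifauna is seeded, structured and truthful", {
  cf <- avifauna_config(n_species = 12,
    orders = tibble::tibble(
      name = c("A", "Psittaciformes"), size = c(8, 4),
      is_parrot_like = c(FALSE, TRUE),
      freq = list(c(melanin = .5, white = .1, carotenoid = .2,
                    structural = .2),
                  c(melanin = .4, psittacofulvin = .3, structural = .3))),
    n_specimens_per_sex = 2, n_patches = 5, seed = 42)
  sim <- gen_avifauna(cf)
  expect_length(unique(sim$spectra$spectrum_id), 12 * 2 * 2 * 5)
  expect_equal(nrow(sim$truth), 12 * 5 * 2)
  expect_true(all(sim$spectra$wavelength_nm %in% std_grid()))
  # byte-identical regeneration under the same config
  sim2 <- gen_avifauna(cf)
  expect_identical(sim$spectra, sim2$spectra)
  expect_identical(sim$truth, sim2$truth)
  # parrot-like species never carry carotenoid truth labels
  parrot_truth <- sim$truth$family[sim$truth$order == "Psittaciformes"]
  expect_false(any(parrot_truth %in% c("carotenoid", "carotenoid_structural")))
})

test_that("truth shares track the configured mechanism frequencies", {
  fq <- c(melanin = 0.55, white = 0.1, carotenoid = 0.15, structural = 0.2)
  cf <- avifauna_config(n_species = 40,
    orders = tibble::tibble(name = "A", size = 40, is_parrot_like = FALSE,
                            freq = list(fq)),
    n_specimens_per_sex = 1, dichromatism = 0, seed = 77)
  sim <- gen_avifauna(cf)
  male_truth <- sim$truth[sim$truth$sex == "male", ]
  obs <- table(factor(male_truth$family, levels = names(fq))) / nrow(male_truth)
  # multinomial sampling error at n = 680 draws: 4 sd margin
  for (fm in names(fq)) {
    se <- sqrt(fq[[fm]] * (1 - fq[[fm]]) / nrow(male_truth))
    expect_lt(abs(obs[[fm]] - fq[[fm]]), 4 * se + 1e-9)
  }
})

test_that("melanin colours sit nearer the achromatic point than structural", {
  cf <- avifauna_config(n_species = 30,
    orders = tibble::tibble(name = "A", size = 30, is_parrot_like = FALSE,
                            freq = list(c(melanin = 0.5, structural = 0.5))),
    n_specimens_per_sex = 1, dichromatism = 0, seed = 19)
  sim <- gen_avifauna(cf)
  pts <- model_colours(sim$spectra, build_sensitivity_set("U"))
  truth <- sim$truth
  key <- paste(pts$species, pts$sex, pts$patch)
  fam <- truth$family[match(key, paste(truth$species, truth$sex, truth$patch))]
  d <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  expect_lt(mean(d[fam == "melanin"]), mean(d[fam == "structural"]))
})
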