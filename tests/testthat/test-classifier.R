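# Spectral-shape features and mechanism classification

test_that("Savitzky-Golay smoothing preserves polynomials and damps noise", {
  expect_equal(smooth_spectrum(rep(30, 81)), rep(30, 81))
  wl <- std_grid()
  cubic <- 20 + 1e-6 * (wl - 500)^3 / 10 + 1e-4 * (wl - 500)^2 / 10
  expect_equal(smooth_spectrum(cubic, window = 11, order = 3), cubic,
               tolerance = 1e-9)
  withr::with_seed(8, {
    clean <- 30 + 20 * (wl - 300) / 400
    noisy <- clean + runif(81, -1, 1)
    expect_lt(max(abs(smooth_spectrum(noisy, 11, 3) -
                        smooth_spectrum(clean, 11, 3))), 1)
  })
  expect_error(smooth_spectrum(rep(1, 81), window = 10), "odd")
  expect_error(smooth_spectrum(rep(1, 5), window = 81), "shorter")
})

test_that("shape features pick out the diagnostic signatures", {
  flat <- spectral_features(fixture_curve("flat15"))
  expect_lt(flat$flatness, 0.1)
  expect_equal(nrow(flat$peaks), 0)
  expect_false(flat$trough_present)

  bell <- spectral_features(fixture_curve("bell450"))
  expect_equal(nrow(bell$peaks), 1)
  expect_lt(abs(bell$peaks$wl - 450), 15)
  expect_false(bell$shoulder)

  sig <- spectral_features(fixture_curve("sigmoid"))
  expect_gt(sig$monotonicity, 0.95)
  expect_true(sig$shoulder)

  caro <- spectral_features(fixture_curve("caro_trough"))
  expect_true(caro$trough_present)
  expect_equal(caro$fine_structure450, 1L)

  combo <- spectral_features(fixture_curve("combo"))
  expect_true(combo$trough_present)
  expect_true(combo$long_trough)
  expect_equal(combo$fine_structure450, 1L)
})

test_that("classification follows the rule precedence with taxonomic context", {
  cls <- function(shape, ord) {
    classify_mechanism(spectral_features(fixture_curve(shape)), order = ord)
  }
  expect_equal(cls("flat15", "Passeriformes"), "melanin")
  expect_equal(cls("rising", "Passeriformes"), "melanin")
  expect_equal(cls("white", "Passeriformes"), "melanin")
  expect_equal(cls("bell450", "Passeriformes"), "structural")
  # identical carotenoid-type shape flips to psittacofulvin in parrots
  expect_equal(cls("caro_trough", "Passeriformes"), "carotenoid")
  expect_equal(cls("caro_trough", "Psittaciformes"), "psittacofulvin")
  expect_equal(cls("sigmoid", "Passeriformes"), "carotenoid")
  # trough + mid peak + long trough: pigment + structure
  expect_equal(cls("combo", "Passeriformes"), "carotenoid_structural")
  expect_equal(cls("combo", "Psittaciformes"), "psittacofulvin_structural")
  # unknown order cannot test parrot membership: carotenoid with a warning
  expect_warning(lab <- cls("caro_trough", "unknown"), "unknown order")
  expect_equal(lab, "carotenoid")
})

test_that("classification is deterministic, exclusive and order-invariant", {
  set.seed(31)
  fams <- c("melanin", "white", "carotenoid", "structural",
            "carotenoid_structural")
  curves <- list()
  for (i in 1:20) {
    p <- sample_family_params(sample(fams, 1), noise_sd = 1)
    curves[[sprintf("s%02d", i)]] <- gen_spectrum(p)$reflectance_pct
  }
  set <- make_set(curves)
  r1 <- classify_set(set)
  r2 <- classify_set(set)
  expect_identical(r1$labels$mechanism, r2$labels$mechanism)
  expect_true(all(r1$labels$mechanism %in% mechanism_labels()))
  expect_equal(sum(r1$shares$share_pct), 100)
  # permuting the spectra changes no label
  perm <- spectrum_set(set[sample(nrow(set)), ])
  r3 <- classify_set(perm)
  expect_equal(
    r3$labels$mechanism[match(r1$labels$spectrum_id, r3$labels$spectrum_id)],
    r1$labels$mechanism)
})

test_that("an all-flat set is all melanin and balanced sets give equal shares", {
  flat_set <- make_set(lapply(stats::setNames(nm = paste0("f", 1:5)),
                              function(nm) rep(runif(1, 5, 60), 81)))
  rf <- classify_set(flat_set)
  expect_equal(unique(rf$labels$mechanism), "melanin")
  expect_equal(rf$shares$share_pct[rf$shares$mechanism == "melanin"], 100)
  # one clean exemplar of each of the six labels: shares 1/6 each
  shapes <- c(melanin = "flat15", carotenoid = "caro_trough",
              structural = "bell450", carotenoid_structural = "combo")
  curves <- lapply(shapes, fixture_curve)
  names(curves) <- paste0("sp_", names(shapes))
  set6 <- dplyr::bind_rows(
    make_set(curves, order = "Passeriformes"),
    make_set(stats::setNames(curves[c("sp_carotenoid",
                                      "sp_carotenoid_structural")],
                             c("pp_psitta", "pp_psitta_struct")),
             order = "Psittaciformes"))
  r6 <- classify_set(spectrum_set(set6))
  expect_equal(sort(unique(r6$labels$mechanism)), sort(mechanism_labels()))
  expect_equal(r6$shares$share_pct, rep(100 / 6, 6), tolerance = 1e-12)
})
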