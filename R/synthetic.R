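# Parametric generator of labelled synthetic avifaunas. Each
# colour-production mechanism is a spectral family with a functional form
# whose noise-free curve carries the family-defining shape features; noise is
# spectrally correlated (smooth), as instrument/specimen noise is, so that
# shape classification remains a fair task.

.families <- c("melanin", "white", "carotenoid", "psittacofulvin",
               "structural", "carotenoid_structural",
               "psittacofulvin_structural")

.logistic <- function(x) 1 / (1 + exp(-x))
.bell <- function(wl, center, width) exp(-((wl - center) / width)^2)

# carotenoid/psittacofulvin absorption fine structure: twin dips at 430 and
# 460 nm flanking a small local reflectance maximum at ~445 nm
.add_fine_structure <- function(wl, y) {
  y + 4 * .bell(wl, 445, 9) -
    pmin(3, 0.5 * y) * (.bell(wl, 430, 10) + .bell(wl, 460, 10))
}

#' Draw random family parameters
#'
#' Samples one parameter set from the family's calibrated ranges (uses the
#' current RNG state; seed outside).
#'
#' @param family One of melanin, white, carotenoid, psittacofulvin,
#'   structural, carotenoid_structural, psittacofulvin_structural.
#' @param noise_sd Spectrally correlated noise standard deviation, percent.
#' @return Named list of parameters for [gen_spectrum()].
#' @export
sample_family_params <- function(family, noise_sd = 1.5) {
  family <- match.arg(family, .families)
  p <- switch(family,
    melanin = list(baseline = runif(1, 2, 18),
                   amplitude = runif(1, 0, 32),
                   saturating = runif(1) < 0.5,
                   tau = runif(1, 170, 260)),
    white = list(baseline = runif(1, 55, 80)),
    carotenoid = ,
    psittacofulvin = list(plateau = runif(1, 35, 65),
                          center = runif(1, 480, 530),
                          width = runif(1, 15, 25),
                          uv_bump = if (runif(1) < 0.5) runif(1, 8, 18) else 0,
                          uv_center = runif(1, 330, 360),
                          fine_structure = NA), # set below
    structural = list(baseline = runif(1, 2, 8),
                      amplitude = runif(1, 22, 60),
                      center = runif(1, 310, 630),
                      width = runif(1, 30, 55),
                      second_peak = if (runif(1) < 0.3) runif(1, 120, 200)
                                    else 0),
    carotenoid_structural = ,
    psittacofulvin_structural = list(baseline = runif(1, 3, 6),
                                     amplitude = runif(1, 28, 50),
                                     center = runif(1, 515, 585),
                                     width = runif(1, 35, 50),
                                     uv_bump = runif(1, 6, 14),
                                     uv_center = runif(1, 330, 355)))
  if (family %in% c("carotenoid", "psittacofulvin"))
    p$fine_structure <- p$uv_bump > 0 # trough subtype carries fine structure
  p$family <- family
  p$noise_sd <- noise_sd
  p
}

#' Generate one reflectance spectrum from a spectral family
#'
#' Functional forms (percent reflectance on the standard grid):
#' melanin, flat-to-monotone baseline + linear or saturating rise; white,
#' flat high baseline; carotenoid/psittacofulvin, logistic rise to a plateau
#' (sigmoid subtype) optionally with a UV bump and twin absorption dips at
#' 430/460 nm (trough subtype); structural, Gaussian bell (optional second
#' bell: iridescence); pigment + structure, mid-wavelength bell with a UV
#' bump and carotenoid fine structure in the 450-nm trough, reflectance
#' suppressed again beyond 620 nm by the bell's fall. Noise is white noise
#' smoothed to ~25 nm correlation length, rescaled to `noise_sd`, added, and
#' clamped to \[0, 100\].
#'
#' @param params From [sample_family_params()], or a hand-built list with the
#'   same fields.
#' @return List: `wavelength_nm`, `reflectance_pct`, `family` (truth label:
#'   white collapses to melanin for classification purposes only in
#'   downstream accuracy checks; the generating family is reported as-is).
#' @export
gen_spectrum <- function(params) {
  wl <- std_grid()
  p <- params
  base <- switch(p$family,
    melanin = {
      rise <- if (isTRUE(p$saturating)) 1 - exp(-(wl - 300) / p$tau)
              else (wl - 300) / 400
      p$baseline + p$amplitude * rise
    },
    white = rep(p$baseline, length(wl)),
    carotenoid = ,
    psittacofulvin = {
      y <- 2 + (p$plateau - 2) * .logistic((wl - p$center) / p$width)
      if (p$uv_bump > 0) y <- y + p$uv_bump * .bell(wl, p$uv_center, 30)
      if (isTRUE(p$fine_structure)) y <- .add_fine_structure(wl, y)
      y
    },
    structural = {
      y <- p$baseline + p$amplitude * .bell(wl, p$center, p$width)
      if (p$second_peak > 0) {
        c2 <- min(p$center + p$second_peak, 670)
        y <- y + 0.7 * p$amplitude * .bell(wl, c2, p$width)
      }
      y
    },
    carotenoid_structural = ,
    psittacofulvin_structural = {
      y <- p$baseline + p$amplitude * .bell(wl, p$center, p$width) +
        p$uv_bump * .bell(wl, p$uv_center, 30)
      .add_fine_structure(wl, y)
    },
    stop("unknown family: ", p$family, call. = FALSE))
  if (any(base > 100 + 1e-9) || any(base < -1e-9))
    warning("parameters push the noise-free curve outside [0, 100]; ",
            "clipping (family ", p$family, ")", call. = FALSE)
  if (p$noise_sd > 0) {
    w <- rnorm(length(wl) + 20)
    k <- .bell(seq(-25, 25, by = 5), 0, 25 / sqrt(2)) # ~25 nm correlation
    sm <- stats::filter(w, k / sum(k), sides = 2)
    sm <- sm[11:(10 + length(wl))]
    base <- base + p$noise_sd * (sm - mean(sm)) / sd(sm)
  }
  out <- pmin(100, pmax(0, base))
  list(wavelength_nm = wl, reflectance_pct = out, family = p$family)
}

#' Synthetic avifauna configuration
#'
#' Defaults describe a desk-scale avifauna with the structure of a real
#' regional sample: a few orders of very different sizes, one parrot-like
#' order with disproportionate psittacofulvin/structural colour, mechanism
#' frequencies dominated by melanin, three specimens per species and sex,
#' 17 patches, and male-biased ornamental colour (dichromatism: an
#' ornamental male patch is replaced in females by a melanin/white patch
#' with the given probability).
#'
#' @param n_species Total species (default 60).
#' @param orders Data frame with columns `name`, `size`, `is_parrot_like`,
#'   and a `freq` list-column of named mechanism frequency vectors.
#'   Default: 4 orders of sizes 30/15/10/5, the 15 parrot-like.
#' @param n_specimens_per_sex Specimens per species and sex (default 3).
#' @param n_patches Patches per specimen (default 17).
#' @param dichromatism Probability a non-melanin male patch is melanin/white
#'   in females (default 0.5).
#' @param noise_sd Correlated noise sd, percent (default 1.5).
#' @param seed Integer seed.
#' @return List of class `avifauna_config`.
#' @export
avifauna_config <- function(n_species = 60, orders = NULL,
                            n_specimens_per_sex = 3, n_patches = 17,
                            dichromatism = 0.5, noise_sd = 1.5, seed = 1) {
  if (is.null(orders)) {
    land_freq <- c(melanin = 0.62, white = 0.13, carotenoid = 0.12,
                   structural = 0.10, carotenoid_structural = 0.03)
    parrot_freq <- c(melanin = 0.30, white = 0.10, psittacofulvin = 0.22,
                     structural = 0.15, psittacofulvin_structural = 0.23)
    orders <- tibble(
      name = c("Passeriformes", "Psittaciformes", "Columbiformes",
               "Charadriiformes"),
      size = c(30, 15, 10, 5),
      is_parrot_like = c(FALSE, TRUE, FALSE, FALSE),
      freq = list(land_freq, parrot_freq, land_freq, land_freq))
  }
  if (sum(orders$size) != n_species)
    stop("order sizes must sum to n_species", call. = FALSE)
  for (fq in orders$freq)
    if (abs(sum(fq) - 1) > 1e-9)
      stop("mechanism frequency vectors must sum to 1", call. = FALSE)
  structure(list(n_species = n_species, orders = orders,
                 n_specimens_per_sex = n_specimens_per_sex,
                 n_patches = n_patches, dichromatism = dichromatism,
                 noise_sd = noise_sd, seed = seed),
            class = "avifauna_config")
}

#' Generate a labelled synthetic avifauna
#'
#' Draws, for every species x patch, a mechanism family from the order's
#' frequency vector and a parameter set (the species' phenotype); females
#' share the male phenotype except that ornamental (non-melanin/white)
#' patches are swapped to melanin or white with probability `dichromatism`.
#' Each specimen then gets an independent correlated-noise realization of
#' its sex's base curve. Deterministic for a given config (seeded).
#'
#' @param config An [avifauna_config()].
#' @return List: `spectra` (a [spectrum_set()]) and `truth` (tibble: species,
#'   order, sex, patch, family -- the generating family of every patch).
#' @export
gen_avifauna <- function(config) {
  cf <- config
  withr::with_seed(cf$seed, {
    wl <- std_grid()
    nw <- length(wl)
    patches <- if (cf$n_patches == 17) default_patches()
               else sprintf("patch%02d", seq_len(cf$n_patches))
    species_tab <- tibble(
      species = sprintf("sp%03d", seq_len(cf$n_species)),
      order = rep(cf$orders$name, cf$orders$size),
      freq_i = rep(seq_len(nrow(cf$orders)), cf$orders$size))
    n_spectra <- cf$n_species * cf$n_patches * 2 * cf$n_specimens_per_sex
    curves <- vector("list", n_spectra)
    meta <- list(species = character(n_spectra), order = character(n_spectra),
                 sex = character(n_spectra), specimen_id = character(n_spectra),
                 patch = character(n_spectra))
    truth <- vector("list", cf$n_species * cf$n_patches)
    k <- 0L; kt <- 0L
    for (i in seq_len(cf$n_species)) {
      fq <- cf$orders$freq[[species_tab$freq_i[i]]]
      for (pa in patches) {
        fam_m <- sample(names(fq), 1, prob = fq)
        par_m <- sample_family_params(fam_m, noise_sd = cf$noise_sd)
        ornamental <- !fam_m %in% c("melanin", "white")
        if (ornamental && runif(1) < cf$dichromatism) {
          fam_f <- sample(c("melanin", "white"), 1, prob = c(0.8, 0.2))
          par_f <- sample_family_params(fam_f, noise_sd = cf$noise_sd)
        } else {
          fam_f <- fam_m
          par_f <- par_m
        }
        per_sex <- list(male = par_m, female = par_f)
        for (sx in c("male", "female")) {
          for (sp_i in seq_len(cf$n_specimens_per_sex)) {
            k <- k + 1L
            curves[[k]] <- gen_spectrum(per_sex[[sx]])$reflectance_pct
            meta$species[k] <- species_tab$species[i]
            meta$order[k] <- species_tab$order[i]
            meta$sex[k] <- sx
            meta$specimen_id[k] <- sprintf("%s_%s_%d", species_tab$species[i],
                                           substr(sx, 1, 1), sp_i)
            meta$patch[k] <- pa
          }
        }
        kt <- kt + 1L
        truth[[kt]] <- tibble(species = species_tab$species[i],
                              order = species_tab$order[i],
                              sex = c("male", "female"), patch = pa,
                              family = c(fam_m, fam_f))
      }
    }
    long <- tibble(
      spectrum_id = rep(meta$specimen_id, each = nw) |>
        paste(rep(meta$patch, each = nw), sep = "|"),
      species = rep(meta$species, each = nw),
      order = rep(meta$order, each = nw),
      sex = rep(meta$sex, each = nw),
      specimen_id = rep(meta$specimen_id, each = nw),
      patch = rep(meta$patch, each = nw),
      wavelength_nm = rep(wl, n_spectra),
      reflectance_pct = unlist(curves, use.names = FALSE))
    spectra <- spectrum_set(long,
                            provenance = sprintf(
                              "gen_avifauna(n_species=%d, seed=%d)",
                              cf$n_species, cf$seed))
    list(spectra = spectra, truth = bind_rows(truth))
  })
}
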