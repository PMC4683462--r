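# Independent oracles and small fixture builders shared across tests.

# brute-force binning oracle: per point and per axis, step cell by cell until
# the half-open interval [lo, hi) containing the coordinate is found
brute_bin <- function(points, cell_size, origin = c(0, 0, 0)) {
  idx1 <- function(v, o) {
    i <- 0L
    repeat {
      lo <- o + i * cell_size
      hi <- o + (i + 1L) * cell_size
      if (lo <= v && v < hi) return(i)
      i <- i + if (v >= hi) 1L else -1L
    }
  }
  out <- matrix(0L, nrow(points), 3)
  for (r in seq_len(nrow(points)))
    for (a in 1:3)
      out[r, a] <- idx1(points[r, a], origin[a])
  out
}

# long-format spectrum set from a named list of reflectance vectors on the
# standard grid (names become species; other metadata fixed)
make_set <- function(curves, order = "Passeriformes", sex = "male",
                     patch = "breast") {
  wl <- avigamut::std_grid()
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    data.frame(species = nm, order = order, sex = sex,
               specimen_id = paste0(nm, "_1"), patch = patch,
               wavelength_nm = wl, reflectance_pct = curves[[nm]])
  }))
  avigamut::spectrum_set(df)
}

# random points uniformly inside the reference tetrahedron, via rejection
# from random simplex weights
random_tetra_points <- function(n) {
  f <- matrix(stats::rexp(4 * n), ncol = 4)
  f <- f / rowSums(f)
  avigamut::tetra_coords(f)
}

# deterministic noise-free family spectrum for classifier fixtures
fixture_curve <- function(shape) {
  wl <- avigamut::std_grid()
  switch(shape,
    flat15 = rep(15, length(wl)),
    rising = 5 + 25 * (wl - 300) / 400,
    white = rep(70, length(wl)),
    bell450 = 5 + 40 * exp(-((wl - 450) / 40)^2),
    sigmoid = {
      y <- 2 + 48 * plogis((wl - 520) / 20)
      y
    },
    caro_trough = {
      y <- 2 + 48 * plogis((wl - 510) / 20) + 12 * exp(-((wl - 345) / 30)^2)
      y + 4 * exp(-((wl - 445) / 9)^2) -
        pmin(3, 0.5 * y) * (exp(-((wl - 430) / 10)^2) +
                              exp(-((wl - 460) / 10)^2))
    },
    combo = {
      y <- 4 + 38 * exp(-((wl - 555) / 42)^2) + 10 * exp(-((wl - 340) / 30)^2)
      y + 4 * exp(-((wl - 445) / 9)^2) -
        pmin(3, 0.5 * y) * (exp(-((wl - 430) / 10)^2) +
                              exp(-((wl - 460) / 10)^2))
    },
    stop("unknown fixture shape: ", shape))
}
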