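# Tetrachromatic visual modelling: cone sensitivity templates, quantum
# catches under a flat (or user) irradiance, and the embedding of relative
# catches in the tetrahedral colour space with the L vertex at the apex.

#' Visual-pigment sensitivity template
#'
#' Govardovskii A1 alpha-band template evaluated on a wavelength grid and
#' normalized to unit peak at the grid point nearest `lambda_max`. The
#' beta-band is available but off by default; oil-droplet and ocular-media
#' filtering are not modelled (user-supplied curves may incorporate them).
#'
#' @param lambda_max Peak sensitivity, nm (must lie within the grid span).
#' @param grid Wavelength grid, nm (default [std_grid()]).
#' @param beta Add the beta absorption band.
#' @return Non-negative numeric vector on `grid`, max = 1.
#' @export
cone_template <- function(lambda_max, grid = std_grid(), beta = FALSE) {
  if (lambda_max < min(grid) || lambda_max > max(grid))
    stop("lambda_max ", lambda_max, " outside grid [", min(grid), ", ",
         max(grid), "]", call. = FALSE)
  x <- lambda_max / grid
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  b <- 0.922; cc <- 1.104
  S <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  if (beta) {
    lmb <- 189 + 0.315 * lambda_max
    bb <- -40.5 + 0.195 * lambda_max
    S <- S + 0.26 * exp(-((grid - lmb) / bb)^2)
  }
  # unit peak at the grid point nearest lambda_max
  S / S[which.min(abs(grid - lambda_max))]
}

#' Default cone peak wavelengths
#'
#' Widely used average lambda-max values for ultraviolet-sensitive (U-type)
#' and violet-sensitive (V-type) avian visual systems. These are
#' configuration, not measurements: replace them, or supply measured curves
#' via `file`, to match a particular species set.
#'
#' @param type `"U"` or `"V"`.
#' @return Named numeric vector (u, s, m, l), nm.
#' @export
default_lambda_max <- function(type = c("U", "V")) {
  type <- match.arg(type)
  if (type == "U") c(u = 372, s = 456, m = 544, l = 609)
  else             c(u = 419, s = 478, m = 542, l = 607)
}

#' Build a four-cone sensitivity set
#'
#' @param type `"U"` or `"V"` (template curves at [default_lambda_max()]);
#'   ignored when `lambda_max` or `file` is given.
#' @param lambda_max Optional custom 4-vector of peak wavelengths (u, s, m, l).
#' @param file Optional CSV with columns `wavelength_nm, u, s, m, l` on the
#'   standard grid; curves are used bit-for-bit (no renormalization).
#' @param grid Wavelength grid.
#' @param beta Passed to [cone_template()] (template case only).
#' @return A `sensitivity_set`: list with `grid`, `curves` (81 x 4 matrix,
#'   columns u, s, m, l), `type`, `lambda_max`.
#' @export
build_sensitivity_set <- function(type = c("U", "V"), lambda_max = NULL,
                                  file = NULL, grid = std_grid(),
                                  beta = FALSE) {
  if (!is.null(file)) {
    tab <- readr::read_csv(file, col_types = readr::cols(.default = "d"),
                           progress = FALSE)
    need <- c("wavelength_nm", "u", "s", "m", "l")
    if (!all(need %in% names(tab)))
      stop("sensitivity file must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    tab <- arrange(tab, .data$wavelength_nm)
    if (!isTRUE(all.equal(tab$wavelength_nm, grid)))
      stop("sensitivity file is not on the standard grid", call. = FALSE)
    curves <- as.matrix(tab[, c("u", "s", "m", "l")])
    return(structure(list(grid = grid, curves = curves, type = "custom",
                          lambda_max = grid[apply(curves, 2, which.max)]),
                     class = "sensitivity_set"))
  }
  if (is.null(lambda_max)) {
    type <- match.arg(type)
    lambda_max <- default_lambda_max(type)
  } else {
    stopifnot(length(lambda_max) == 4)
    lambda_max <- setNames(as.numeric(lambda_max), c("u", "s", "m", "l"))
    type <- "custom"
  }
  curves <- vapply(lambda_max, cone_template, numeric(length(grid)),
                   grid = grid, beta = beta)
  colnames(curves) <- c("u", "s", "m", "l")
  structure(list(grid = grid, curves = curves, type = type,
                 lambda_max = lambda_max),
            class = "sensitivity_set")
}

#' @export
print.sensitivity_set <- function(x, ...) {
  cat(sprintf("<sensitivity_set %s: lambda_max %s nm on %d-point grid>\n",
              x$type, paste(round(x$lambda_max), collapse = "/"),
              length(x$grid)))
  invisible(x)
}

#' Write a sensitivity set to CSV (round-trips through `file =` of
#' [build_sensitivity_set()])
#' @param sens A sensitivity set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_set <- function(sens, path) {
  readr::write_csv(tibble(wavelength_nm = sens$grid,
                          u = sens$curves[, "u"], s = sens$curves[, "s"],
                          m = sens$curves[, "m"], l = sens$curves[, "l"]),
                   path, progress = FALSE)
  invisible(path)
}

#' Cone quantum catches
#'
#' Q_i = sum over the 5-nm grid of R(lambda) I(lambda) C_i(lambda), with
#' reflectance as a proportion (input percent / 100) and plain rectangular
#' summation. The default irradiance is ideal flat, I(lambda) = 1, so the
#' analysis measures reflectance colour only.
#'
#' @param set A resampled [spectrum_set()].
#' @param sens A sensitivity set from [build_sensitivity_set()].
#' @param irradiance `"flat"` or a numeric vector on the grid.
#' @return Tibble: spectrum metadata plus `qu, qs, qm, ql`.
#' @export
quantum_catches <- function(set, sens, irradiance = "flat") {
  sm <- spectra_matrix(set)
  if (!isTRUE(all.equal(sm$wl, sens$grid)))
    stop("spectrum grid does not match sensitivity grid", call. = FALSE)
  I <- if (identical(irradiance, "flat")) rep(1, length(sm$wl))
       else as.numeric(irradiance)
  if (length(I) != length(sm$wl))
    stop("irradiance must be 'flat' or a vector on the grid", call. = FALSE)
  Q <- t(sens$curves * I) %*% (sm$R / 100) # 4 x n
  out <- sm$meta
  out$qu <- Q[1, ]; out$qs <- Q[2, ]; out$qm <- Q[3, ]; out$ql <- Q[4, ]
  out
}

#' Relative quantum catches (usml simplex)
#'
#' f_i = Q_i / sum(Q). An all-zero catch (all-zero reflectance) is a
#' degenerate spectrum and raises an error naming the offenders; no silent
#' achromatic-black convention is applied.
#'
#' @param q Tibble from [quantum_catches()].
#' @return Same tibble with `qu..ql` replaced by `u, s, m, l` summing to 1.
#' @export
relative_catches <- function(q) {
  tot <- q$qu + q$qs + q$qm + q$ql
  if (any(tot <= 0)) {
    bad <- q$spectrum_id[tot <= 0]
    stop("degenerate all-zero quantum catch for spectrum(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  out <- q[, setdiff(names(q), c("qu", "qs", "qm", "ql"))]
  out$u <- q$qu / tot; out$s <- q$qs / tot
  out$m <- q$qm / tot; out$l <- q$ql / tot
  out
}

#' Map relative catches to tetrahedral coordinates
#'
#' The usml simplex is embedded as a regular tetrahedron of circumradius 0.75
#' centred on the achromatic point (origin), oriented with the L-cone vertex
#' at the apex (0, 0, 0.75):
#' \deqn{x = ((1 - 2s - m - l)/2)\sqrt{3/2},\quad
#'       y = (-1 + 3m + l)/(2\sqrt 2),\quad z = l - 1/4.}
#'
#' @param f Tibble with columns `u, s, m, l` (rows on the simplex), or a
#'   4-column matrix.
#' @param tol Tolerance for the simplex-sum check.
#' @return Input metadata with columns `x, y, z` (matrix input: n x 3 matrix).
#' @export
tetra_coords <- function(f, tol = 1e-9) {
  if (is.matrix(f)) {
    u <- f[, 1]; s <- f[, 2]; m <- f[, 3]; l <- f[, 4]
    meta <- NULL
  } else {
    u <- f$u; s <- f$s; m <- f$m; l <- f$l
    meta <- f[, setdiff(names(f), c("u", "s", "m", "l"))]
  }
  if (any(abs(u + s + m + l - 1) > tol) || any(pmin(u, s, m, l) < -tol))
    stop("relative catches are off the simplex beyond tolerance", call. = FALSE)
  x <- ((1 - 2 * s - m - l) / 2) * sqrt(3 / 2)
  y <- (-1 + 3 * m + l) / (2 * sqrt(2))
  z <- l - 1 / 4
  if (is.null(meta)) return(cbind(x = x, y = y, z = z))
  meta$x <- x; meta$y <- y; meta$z <- z
  meta
}

#' Vertices of the reference tetrahedron
#'
#' Coordinates of the four single-cone stimulation points (rows u, s, m, l).
#' Edge length sqrt(3/2), circumradius 0.75, centroid at the origin, L at the
#' apex.
#'
#' @return 4 x 3 matrix.
#' @export
tetra_vertices <- function() {
  tetra_coords(diag(4))
}

#' Volume of the reference tetrahedron
#'
#' Closed form a^3/(6 sqrt(2)) with edge a = sqrt(3/2): the total theoretical
#' avian colour space, the denominator of "percent of colour space" figures.
#'
#' @return Scalar, about 0.2165064.
#' @export
tetra_volume <- function() sqrt(3 / 2)^3 / (6 * sqrt(2))

#' Spectrum set to colour-space points, in one step
#'
#' Convenience chain: [quantum_catches()] -> [relative_catches()] ->
#' [tetra_coords()].
#'
#' @inheritParams quantum_catches
#' @return Tibble of points with metadata and `x, y, z`.
#' @export
model_colours <- function(set, sens, irradiance = "flat") {
  tetra_coords(relative_catches(quantum_catches(set, sens, irradiance)))
}

#' Average colour-space points across specimens
#'
#' Arithmetic mean of (x, y, z) within each (species, sex, patch) group --
#' specimen averaging happens in colour space, after visual modelling. If a
#' `mechanism` column is present the modal label per group is kept (ties
#' resolved alphabetically, deterministic).
#'
#' @param points Tibble with `species`, `order`, `sex`, `patch`, `x, y, z`.
#' @return One row per (species, sex, patch).
#' @export
aggregate_species_sex <- function(points) {
  has_mech <- "mechanism" %in% names(points)
  out <- points |>
    group_by(.data$species, .data$order, .data$sex, .data$patch) |>
    summarise(
      n_specimens = n(),
      mechanism = if (has_mech) {
        tt <- sort(table(.data$mechanism), decreasing = TRUE)
        names(tt)[order(-tt, names(tt))][1]
      } else NA_character_,
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      .groups = "drop")
  if (!has_mech) out$mechanism <- NULL
  out
}
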