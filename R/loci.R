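# Discrete morphospace occupancy: chromatic loci on a 0.022 grid.
#
# The 3D grid is anchored at the achromatic point (origin) and cells are
# half-open [lo, hi), so every point maps to exactly one cell. Direct 3D
# flooring is mathematically identical to intersecting two 2D grids on the
# yz and yx planes (they share the y axis and cell size); the equivalence is
# kept as a property test rather than as the implementation.

#' Rasterize colour-space points into chromatic loci
#'
#' Each point is assigned to cell
#' `(floor((x-ox)/cell), floor((y-oy)/cell), floor((z-oz)/cell))`.
#'
#' @param points n x 3 matrix or data frame with `x, y, z`.
#' @param cell_size Cell edge length (default 0.022, the standard chromatic
#'   locus size in tetrahedral units).
#' @param origin Grid anchor, default the achromatic point `c(0, 0, 0)`.
#' @return A `locus_map`: tibble of occupied cells `(ix, iy, iz, count)` with
#'   attributes `cell_size`, `origin`, `n_points`.
#' @export
rasterize_loci <- function(points, cell_size = 0.022, origin = c(0, 0, 0)) {
  stopifnot(cell_size > 0, length(origin) == 3)
  m <- as_xyz_matrix(points)
  idx <- floor(sweep(m, 2, origin) / cell_size)
  cells <- tibble(ix = idx[, 1], iy = idx[, 2], iz = idx[, 3]) |>
    count(.data$ix, .data$iy, .data$iz, name = "count") |>
    arrange(.data$ix, .data$iy, .data$iz)
  structure(cells, class = c("locus_map", class(cells)),
            cell_size = cell_size, origin = origin, n_points = nrow(m))
}

#' @export
print.locus_map <- function(x, ...) {
  cat(sprintf("<locus_map: %d occupied loci, %d points, cell %g>\n",
              nrow(x), attr(x, "n_points"), attr(x, "cell_size")))
  NextMethod()
}

.locus_keys <- function(map) {
  paste(map$ix, map$iy, map$iz, sep = ",")
}

#' Summarise a locus map
#'
#' Occupancy, the abundance histogram, and a mass-concentration measure: the
#' smallest fraction of occupied loci that together hold at least a fraction
#' `p` of all points (loci sorted by abundance). A strongly uneven gamut
#' (most patches in few loci) gives a small value.
#'
#' @param map A [rasterize_loci()] result.
#' @param p Mass fraction for the concentration curve (default 0.5).
#' @return List: `n_occupied`, `n_points`, `abundance` (named table of
#'   count frequencies), `mass_fraction`, `n_loci_for_mass`.
#' @export
locus_summary <- function(map, p = 0.5) {
  if (nrow(map) == 0)
    return(list(n_occupied = 0L, n_points = 0L,
                abundance = table(integer(0)),
                mass_fraction = 0, n_loci_for_mass = 0L))
  cnt <- sort(map$count, decreasing = TRUE)
  k <- which(cumsum(cnt) >= p * sum(cnt))[1]
  list(n_occupied = nrow(map), n_points = attr(map, "n_points"),
       abundance = table(map$count),
       mass_fraction = k / nrow(map), n_loci_for_mass = k)
}

#' Loci shared between and unique to two samples
#'
#' Partition of the union of occupied loci into shared / only-a / only-b,
#' with fractions relative to the union ("x% of occupied loci are shared by
#' the sexes, y% restricted to ...").
#'
#' @param a,b Two [rasterize_loci()] maps on the same grid.
#' @return List: counts `n_shared`, `n_only_a`, `n_only_b`, `n_union`, and
#'   fractions `frac_shared`, `frac_only_a`, `frac_only_b`.
#' @export
shared_unique_loci <- function(a, b) {
  if (!isTRUE(all.equal(attr(a, "cell_size"), attr(b, "cell_size"))) ||
      !isTRUE(all.equal(attr(a, "origin"), attr(b, "origin"))))
    stop("locus maps use different grids (cell_size/origin mismatch)",
         call. = FALSE)
  ka <- .locus_keys(a); kb <- .locus_keys(b)
  ns <- length(intersect(ka, kb))
  nu <- length(union(ka, kb))
  list(n_shared = ns, n_only_a = length(ka) - ns, n_only_b = length(kb) - ns,
       n_union = nu,
       frac_shared = if (nu) ns / nu else 0,
       frac_only_a = if (nu) (length(ka) - ns) / nu else 0,
       frac_only_b = if (nu) (length(kb) - ns) / nu else 0)
}

#' 2D shadow grids (side and bottom projections)
#'
#' Occupancy counts on the yz ("side shadow") or yx ("bottom shadow") plane,
#' for rendering the classic projection plots of the tetrahedron.
#'
#' @inheritParams rasterize_loci
#' @param plane `"yz"` or `"yx"`.
#' @return Tibble `(i1, i2, count)` where i1, i2 index the two retained axes;
#'   attributes `plane`, `cell_size`, `origin`.
#' @export
project_2d <- function(points, plane = c("yz", "yx"), cell_size = 0.022,
                       origin = c(0, 0, 0)) {
  plane <- match.arg(plane)
  m <- as_xyz_matrix(points)
  if (nrow(m) == 0) {
    out <- tibble(i1 = integer(), i2 = integer(), count = integer())
  } else {
    idx <- floor(sweep(m, 2, origin) / cell_size)
    keep <- if (plane == "yz") c(2, 3) else c(2, 1)
    out <- tibble(i1 = idx[, keep[1]], i2 = idx[, keep[2]]) |>
      count(.data$i1, .data$i2, name = "count") |>
      arrange(.data$i1, .data$i2)
  }
  structure(out, plane = plane, cell_size = cell_size, origin = origin)
}
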