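# Convex-hull gamut metrics. The hull itself (volume, facet half-spaces) is
# computed by the package's compiled incremental hull (src/chull3d.cpp);
# overlap is exact via half-space duality about an interior point, with a
# Monte-Carlo rejection-sampling route kept as an independent fallback.

as_xyz_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    m <- points
  } else {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    m <- cbind(points$x, points$y, points$z)
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Convex hull of colour-space points
#'
#' @param points n x 3 matrix or data frame with columns `x, y, z`.
#' @return List: `volume`, `degenerate`, `vertices` (row indices), `faces`,
#'   `normals` (unit outward), `offsets`, `center` (an interior point),
#'   plus `points` (the input matrix). Fewer than 4 points, or affinely
#'   degenerate input, gives `volume = 0` with `degenerate = TRUE`.
#' @export
convex_hull3d <- function(points) {
  m <- as_xyz_matrix(points)
  h <- chull3d_cpp(m)
  h$points <- m
  h
}

#' Convex-hull gamut volume
#'
#' Volume of the 3D convex hull enclosing all points: the classical colour
#' gamut measure. Degeneracy (affine dimension < 3) is a result, not an
#' error: `volume = 0`, `degenerate = TRUE`.
#'
#' @inheritParams convex_hull3d
#' @return List of class `hull_result`: `volume`, `n_vertices`, `degenerate`.
#' @export
hull_volume <- function(points) {
  h <- convex_hull3d(points)
  structure(list(volume = h$volume, n_vertices = length(h$vertices),
                 degenerate = h$degenerate), class = "hull_result")
}

#' @export
print.hull_result <- function(x, ...) {
  cat(sprintf("<hull_result: volume %.6g, %d vertices%s>\n", x$volume,
              x$n_vertices, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Are points inside a convex hull?
#'
#' @param points n x 3 matrix or data frame with `x, y, z`.
#' @param hull Result of [convex_hull3d()].
#' @param tol Slack on the facet inequalities.
#' @return Logical vector.
#' @export
in_hull <- function(points, hull, tol = 1e-9) {
  if (hull$degenerate) return(rep(FALSE, nrow(as_xyz_matrix(points))))
  in_hull_cpp(as_xyz_matrix(points), hull$normals, hull$offsets, tol)
}

# interior point of the intersection of two hulls, or NULL.
# Convexity: the mean of feasible points is feasible, and deeper.
.intersection_interior <- function(ha, hb, n_try = 4000L) {
  cand <- rbind(ha$center, hb$center, (ha$center + hb$center) / 2)
  lo <- pmax(apply(ha$points, 2, min), apply(hb$points, 2, min))
  hi <- pmin(apply(ha$points, 2, max), apply(hb$points, 2, max))
  if (any(lo >= hi)) {
    smp <- NULL
  } else {
    smp <- cbind(runif(n_try, lo[1], hi[1]), runif(n_try, lo[2], hi[2]),
                 runif(n_try, lo[3], hi[3]))
  }
  cand <- rbind(cand, smp)
  ok <- in_hull_cpp(cand, ha$normals, ha$offsets, -1e-10) &
    in_hull_cpp(cand, hb$normals, hb$offsets, -1e-10)
  if (!any(ok)) return(NULL)
  colMeans(cand[ok, , drop = FALSE])
}

# vertices of the intersection polytope of two hulls, by duality about c0:
# halfspaces n.x <= o with c0 strictly feasible; dual points n/(o - n.c0);
# facets of the dual hull map back to primal vertices.
.halfspace_intersection_vertices <- function(ha, hb, c0) {
  N <- rbind(ha$normals, hb$normals)
  o <- c(ha$offsets, hb$offsets)
  b <- o - as.numeric(N %*% c0)
  if (any(b <= 1e-12)) return(NULL) # c0 not strictly interior
  D <- N / b
  hd <- chull3d_cpp(D)
  if (hd$degenerate) return(NULL)
  od <- hd$offsets
  if (any(od <= 1e-12)) return(NULL)
  V <- hd$normals / od
  sweep(V, 2, c0, "+")
}

#' Convex-hull overlap between two point sets
#'
#' Volume of the intersection of the two hulls, as an absolute volume and as
#' a fraction of each hull ("the overlap comprises x% of A-occupied and y% of
#' B-occupied volume"). The exact method intersects the two hulls' facet
#' half-spaces about a feasible interior point (polar duality); the
#' Monte-Carlo method rejection-samples inside the smaller hull and reports a
#' standard error. If either hull is degenerate, or the hulls do not
#' intersect with interior, the overlap is 0.
#'
#' @param a,b Point sets (n x 3 matrix or data frame with `x, y, z`).
#' @param method `"exact"` or `"monte_carlo"`.
#' @param n_mc Monte-Carlo sample size.
#' @param seed Optional seed for the Monte-Carlo draws (also used by the
#'   interior-point search of the exact method).
#' @return List of class `overlap_result`: `intersection_volume`, `frac_of_a`,
#'   `frac_of_b`, `vol_a`, `vol_b`, `method`, `mc_se` (NA for exact).
#' @export
hull_overlap <- function(a, b, method = c("exact", "monte_carlo"),
                         n_mc = 1e5, seed = NULL) {
  method <- match.arg(method)
  ha <- convex_hull3d(a)
  hb <- convex_hull3d(b)
  res <- function(vol, se = NA_real_, used = method) {
    structure(list(intersection_volume = vol,
                   frac_of_a = if (ha$volume > 0) vol / ha$volume else 0,
                   frac_of_b = if (hb$volume > 0) vol / hb$volume else 0,
                   vol_a = ha$volume, vol_b = hb$volume,
                   method = used, mc_se = se), class = "overlap_result")
  }
  if (ha$degenerate || hb$degenerate) return(res(0))
  run <- function() {
    if (method == "exact") {
      c0 <- .intersection_interior(ha, hb)
      if (is.null(c0)) return(res(0))
      V <- .halfspace_intersection_vertices(ha, hb, c0)
      if (is.null(V)) return(res(0))
      res(chull3d_cpp(V)$volume)
    } else {
      sm <- if (ha$volume <= hb$volume) ha else hb
      ot <- if (ha$volume <= hb$volume) hb else ha
      lo <- apply(sm$points, 2, min); hi <- apply(sm$points, 2, max)
      p <- cbind(runif(n_mc, lo[1], hi[1]), runif(n_mc, lo[2], hi[2]),
                 runif(n_mc, lo[3], hi[3]))
      ins <- in_hull_cpp(p, sm$normals, sm$offsets, 1e-12)
      n_in <- sum(ins)
      if (n_in == 0) return(res(0, se = NA_real_))
      both <- in_hull_cpp(p[ins, , drop = FALSE], ot$normals, ot$offsets, 1e-12)
      fr <- mean(both)
      res(sm$volume * fr,
          se = sm$volume * sqrt(fr * (1 - fr) / n_in))
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result (%s): volume %.6g = %.1f%% of A, %.1f%% of B%s>\n",
    x$method, x$intersection_volume, 100 * x$frac_of_a, 100 * x$frac_of_b,
    if (is.finite(x$mc_se)) sprintf(", mc_se %.2g", x$mc_se) else ""))
  invisible(x)
}
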