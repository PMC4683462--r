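# Bootstrap inference on gamut metrics: female/male ratio confidence
# intervals and per-order observed-vs-expected colour diversity.
#
# The species is the exchangeable unit: a replicate draws whole species (with
# their full per-sex patch point sets) with replacement; patches are never
# resampled independently. Quantiles use the inclusive linear-interpolation
# convention (R type 7). All randomness is driven by one integer seed of the
# default Mersenne-Twister generator.

.metric_choices <- c("n_loci", "hull_volume")

# per-species precomputation for fast replicate evaluation
.species_units <- function(points, cell_size, origin) {
  m <- as_xyz_matrix(points)
  keys <- paste(floor((m[, 1] - origin[1]) / cell_size),
                floor((m[, 2] - origin[2]) / cell_size),
                floor((m[, 3] - origin[3]) / cell_size), sep = ",")
  split_idx <- split(seq_len(nrow(m)), points$species)
  list(
    species = names(split_idx),
    keys = lapply(split_idx, function(i) unique(keys[i])),
    xyz = lapply(split_idx, function(i) m[i, , drop = FALSE]))
}

.unit_metric <- function(units, take, metric) {
  if (metric == "n_loci") {
    length(unique(unlist(units$keys[take], use.names = FALSE)))
  } else {
    chull3d_cpp(do.call(rbind, units$xyz[take]))$volume
  }
}

.boot_result <- function(metric, reps, B, seed, observed = NULL, p = NULL,
                         n_redrawn = 0L) {
  structure(list(metric = metric, replicates = reps, B = B,
                 median = median(reps),
                 q025 = quantile(reps, 0.025, names = FALSE, type = 7),
                 q975 = quantile(reps, 0.975, names = FALSE, type = 7),
                 observed = observed, p_two_tailed = p, seed = seed,
                 n_redrawn = n_redrawn),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result %s: B=%d, median %.4g [%.4g, %.4g]%s%s>\n",
              x$metric, x$B, x$median, x$q025, x$q975,
              if (!is.null(x$observed)) sprintf(", observed %.4g", x$observed)
              else "",
              if (!is.null(x$p_two_tailed)) sprintf(", p=%.4g", x$p_two_tailed)
              else ""))
  invisible(x)
}

#' Bootstrap the female/male gamut ratio
#'
#' Restricted to species with both sexes present. Each of the `B` replicates
#' draws that many species with replacement, evaluates the gamut metric on
#' the males and on the females of the same drawn species, and records the
#' female/male ratio. The null hypothesis of equal colour diversity is
#' ratio = 1; read it off against the 2.5%/97.5% quantiles. Replicates whose
#' male metric is zero are redrawn and counted in `n_redrawn`.
#'
#' @param points Aggregated colour-space points: tibble with `species`,
#'   `sex` (`"male"`/`"female"`), `x, y, z`.
#' @param metric `"n_loci"` (occupied chromatic loci) or `"hull_volume"`.
#' @param B Number of replicates (default 10000).
#' @param seed Integer seed (identical seed, identical result).
#' @param cell_size,origin Locus grid (used by the `"n_loci"` metric).
#' @return A `bootstrap_result` with the ratio replicates.
#' @export
bootstrap_sex_ratio <- function(points, metric = c("n_loci", "hull_volume"),
                                B = 10000, seed = 1, cell_size = 0.022,
                                origin = c(0, 0, 0)) {
  metric <- match.arg(metric)
  stopifnot(B >= 1)
  by_sex <- split(points$species, points$sex)
  eligible <- sort(intersect(unique(by_sex$male), unique(by_sex$female)))
  if (length(eligible) < 1)
    stop("no species with both sexes present", call. = FALSE)
  mu <- .species_units(points[points$sex == "male" &
                                points$species %in% eligible, ],
                       cell_size, origin)
  fu <- .species_units(points[points$sex == "female" &
                                points$species %in% eligible, ],
                       cell_size, origin)
  N <- length(eligible)
  withr::with_seed(seed, {
    reps <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        take <- unique(sample(eligible, N, replace = TRUE))
        mv <- .unit_metric(mu, take, metric)
        if (mv > 0) break
        redrawn <- redrawn + 1L
        if (redrawn > 100L * B)
          stop("male metric persistently zero; cannot form ratios",
               call. = FALSE)
      }
      reps[b] <- .unit_metric(fu, take, metric) / mv
    }
    .boot_result(metric, reps, B, seed, n_redrawn = redrawn)
  })
}

#' Observed vs expected colour diversity of one order
#'
#' Compares an order's gamut (as percent of the full-sample gamut) with a
#' null distribution obtained by bootstrapping the same number of species
#' from the entire sample, and attaches a two-tailed bootstrap p-value.
#'
#' @param points Aggregated points of one sex: tibble with `species`,
#'   `order`, `x, y, z`.
#' @param order Order name whose species form the observed set. Alternatively
#'   pass `n_species` directly and `observed` will be `NULL`.
#' @param n_species Number of species to draw per replicate (defaults to the
#'   order's species count).
#' @param metric `"n_loci"` or `"hull_volume"`.
#' @param B Number of replicates.
#' @param seed Integer seed.
#' @param replace Draw species with replacement (default TRUE, mirroring the
#'   sex-ratio procedure); FALSE gives the without-replacement variant.
#' @param cell_size,origin Locus grid.
#' @param correction Add-one p-value correction (see [two_tailed_p()]).
#' @return A `bootstrap_result`: replicates and observed are percent of the
#'   full-sample metric.
#' @export
bootstrap_order_null <- function(points, order = NULL, n_species = NULL,
                                 metric = c("n_loci", "hull_volume"),
                                 B = 10000, seed = 1, replace = TRUE,
                                 cell_size = 0.022, origin = c(0, 0, 0),
                                 correction = TRUE) {
  metric <- match.arg(metric)
  units <- .species_units(points, cell_size, origin)
  all_sp <- units$species
  if (!is.null(order)) {
    ord_sp <- unique(points$species[points$order == order])
    if (!length(ord_sp)) stop("no species in order '", order, "'", call. = FALSE)
    if (is.null(n_species)) n_species <- length(ord_sp)
  } else {
    ord_sp <- NULL
    if (is.null(n_species) || n_species < 1)
      stop("give an order name or n_species >= 1", call. = FALSE)
  }
  if (n_species > length(all_sp))
    stop("n_species exceeds the number of species in the sample", call. = FALSE)
  full <- .unit_metric(units, all_sp, metric)
  observed <- if (!is.null(ord_sp))
    100 * .unit_metric(units, ord_sp, metric) / full else NULL
  withr::with_seed(seed, {
    reps <- vapply(seq_len(B), function(b) {
      take <- sample(all_sp, n_species, replace = replace)
      100 * .unit_metric(units, unique(take), metric) / full
    }, numeric(1))
    p <- if (!is.null(observed)) two_tailed_p(reps, observed, correction)
         else NULL
    .boot_result(metric, reps, B, seed, observed = observed, p = p)
  })
}

#' Two-tailed bootstrap p-value
#'
#' Doubled smaller tail of the null replicates relative to the observed
#' value, with an add-one correction so that p > 0 from finite resampling:
#' `p = min(1, 2 * min((1 + #{rep <= obs})/(B + 1), (1 + #{rep >= obs})/(B + 1)))`.
#' With `correction = FALSE` the raw proportion of more-extreme replicates is
#' doubled instead.
#'
#' @param replicates Non-empty numeric vector of null replicates.
#' @param observed Observed statistic.
#' @param correction Apply the add-one correction (default TRUE).
#' @return p-value in (0, 1].
#' @export
two_tailed_p <- function(replicates, observed, correction = TRUE) {
  stopifnot(length(replicates) >= 1)
  B <- length(replicates)
  lo <- sum(replicates <= observed)
  hi <- sum(replicates >= observed)
  if (correction)
    min(1, 2 * min((1 + lo) / (B + 1), (1 + hi) / (B + 1)))
  else
    min(1, 2 * min(lo / B, hi / B))
}
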