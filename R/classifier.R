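# Rule-based assignment of reflectance spectra to colour-production
# mechanisms, from spectral shape plus taxonomic context (parrot orders
# replace carotenoids with psittacofulvins).
#
# The field's practice is expert inspection of spectral shape; here the
# shapes are operationalized as named numeric features with configurable
# thresholds. Defaults are calibrated to separate the synthetic generator's
# spectral families cleanly; they are not claimed to reproduce any particular
# per-species expert assignment.

#' Classifier thresholds
#'
#' All numeric constants of the shape rules, overridable individually.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of thresholds:
#' \describe{
#'   \item{peak_prominence_frac}{interior peak prominence, as fraction of the
#'     spectrum's range (0.05)}
#'   \item{peak_prominence_abs}{absolute minimum prominence, percent
#'     reflectance (7; generous so that smooth correlated noise never
#'     fabricates a structural peak)}
#'   \item{trough_window}{wavelength window searched for the carotenoid
#'     absorption trough (400--510 nm)}
#'   \item{trough_depth_frac}{required trough depth as a fraction of the
#'     post-trough maximum (0.10)}
#'   \item{trough_depth_abs}{absolute minimum trough depth, percent (3)}
#'   \item{shortside_rise_abs}{minimum rise from trough towards short
#'     wavelengths for a true trough, percent (1.5)}
#'   \item{mid_peak_window}{window for the pigment+structure mid peak
#'     (500--600 nm)}
#'   \item{long_tail_window}{window whose mean defines long-wavelength
#'     reflectance (650--700 nm)}
#'   \item{long_trough_frac}{drop from mid peak to long tail marking the
#'     second trough of pigment+structure spectra (0.2)}
#'   \item{fine_left_window, fine_top_window, fine_right_window}{the three
#'     wavelength windows of the carotenoid fine-structure signature: twin
#'     absorption dips near 430 and 460 nm flanking a local reflectance
#'     maximum near 445 nm}
#'   \item{fine_prominence}{required height of that maximum above both
#'     flanking dips, percent (2.5)}
#'   \item{steep_slope}{minimum maximal derivative of a sigmoid rise,
#'     percent/nm (0.25)}
#'   \item{plateau_slope}{maximum mean |derivative| beyond the rise for a
#'     'shoulder' plateau, percent/nm (0.05)}
#'   \item{shoulder_reach_nm}{the 90%-of-maximum point must be reached by
#'     this wavelength for a shoulder (620 nm)}
#'   \item{min_monotonicity}{minimum rank correlation with wavelength for the
#'     sigmoid route (0.8)}
#'   \item{uv_ratio_min}{short/long reflectance ratio marking a UV-truncated
#'     structural peak (2)}
#'   \item{uv_excess_abs}{absolute short-over-long excess for the UV route,
#'     percent (3)}
#'   \item{smooth_window, smooth_order}{Savitzky-Golay parameters for the
#'     main smoothed curve (11 points, order 3)}
#'   \item{fine_smooth_window, fine_smooth_order}{lighter smoothing used for
#'     fine-structure detection (7 points, order 2)}
#'   \item{parrot_orders}{orders whose carotenoid-like spectra are
#'     psittacofulvin-based ("Psittaciformes")}
#' }
#' @export
classifier_thresholds <- function(...) {
  defaults <- list(
    peak_prominence_frac = 0.05, peak_prominence_abs = 7,
    trough_window = c(400, 510), trough_depth_frac = 0.10,
    trough_depth_abs = 3, shortside_rise_abs = 1.5,
    mid_peak_window = c(500, 600), long_tail_window = c(650, 700),
    long_trough_frac = 0.2,
    fine_left_window = c(423, 437), fine_top_window = c(438, 452),
    fine_right_window = c(453, 472), fine_prominence = 2.5,
    steep_slope = 0.25, plateau_slope = 0.05, shoulder_reach_nm = 620,
    min_monotonicity = 0.8,
    uv_ratio_min = 2, uv_excess_abs = 3,
    smooth_window = 19, smooth_order = 2,
    fine_smooth_window = 7, fine_smooth_order = 2,
    parrot_orders = .parrot_orders)
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  modifyList(defaults, ov)
}

#' Savitzky-Golay smoothing of a reflectance spectrum
#'
#' Local-polynomial smoothing on the common grid, clamped to \[0, 100\].
#' Constants and polynomials up to `order` are reproduced exactly.
#'
#' @param reflectance Numeric vector on the standard grid.
#' @param window Odd window length in grid points (> `order`).
#' @param order Polynomial order.
#' @return Smoothed vector, same length.
#' @export
smooth_spectrum <- function(reflectance, window = 11, order = 3) {
  if (window %% 2 == 0 || window <= order)
    stop("window must be odd and greater than order", call. = FALSE)
  if (window >= length(reflectance))
    stop("window must be shorter than the spectrum", call. = FALSE)
  pmin(100, pmax(0, signal::sgolayfilt(reflectance, p = order, n = window)))
}

# interior local maxima with prominence: walk from each local maximum to the
# nearest higher ground on each side; prominence = height - max(valley floors)
.find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(tibble(i = integer(), height = numeric(),
                           prominence = numeric()))
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(is_max)) return(tibble(i = integer(), height = numeric(),
                                     prominence = numeric()))
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    lmin <- h
    j <- i
    while (j > 1) { j <- j - 1; lmin <- min(lmin, y[j]); if (y[j] > h) break }
    left <- lmin
    rmin <- h
    j <- i
    while (j < n) { j <- j + 1; rmin <- min(rmin, y[j]); if (y[j] > h) break }
    h - max(left, rmin)
  }, numeric(1))
  tibble(i = is_max, height = y[is_max], prominence = prom)
}

#' Extract shape features from one resampled spectrum
#'
#' Deterministic feature vector computed on the Savitzky-Golay smoothed
#' curve (fine structure on a lightly smoothed version): overall flatness
#' and monotonicity, interior peaks with prominences, the 400--510 nm
#' absorption trough, fine structure within it, the long-wavelength
#' 'shoulder' plateau, the pigment+structure mid-peak/long-trough signature,
#' and the UV-peak ratio.
#'
#' @param reflectance Numeric vector on [std_grid()].
#' @param thresholds From [classifier_thresholds()].
#' @return Named list of features.
#' @export
spectral_features <- function(reflectance, thresholds = classifier_thresholds()) {
  th <- thresholds
  wl <- std_grid()
  S <- smooth_spectrum(reflectance, th$smooth_window, th$smooth_order)
  Sf <- smooth_spectrum(reflectance, th$fine_smooth_window, th$fine_smooth_order)
  rng <- max(S) - min(S)
  mn <- mean(S)
  step <- wl[2] - wl[1]
  deriv <- diff(S) / step

  in_win <- function(w) wl >= w[1] & wl <= w[2]
  long_tail <- mean(S[in_win(th$long_tail_window)])
  short_max <- max(S[wl <= 400])

  # interior prominent peaks
  pk <- .find_peaks(S)
  pk$wl <- wl[pk$i]
  prom_min <- max(th$peak_prominence_frac * rng, th$peak_prominence_abs)
  peaks <- pk[pk$prominence >= prom_min, , drop = FALSE]

  # carotenoid absorption trough in 400-510 nm
  tw <- which(in_win(th$trough_window))
  i_min <- tw[which.min(S[tw])]
  trough_wl <- wl[i_min]
  trough_val <- S[i_min]
  post_max <- max(S[wl >= th$trough_window[2] + 5])
  depth <- post_max - trough_val
  shortside_max <- max(S[wl <= trough_wl])
  trough_present <- depth >= max(th$trough_depth_frac * post_max,
                                 th$trough_depth_abs) &&
    (shortside_max - trough_val) >= max(th$shortside_rise_abs,
                                        0.05 * post_max)

  # carotenoid fine structure: W-shaped signature of the twin absorption
  # dips at ~430/460 nm with a local reflectance maximum in between.
  # Detected on the residual of light minus heavy smoothing, so that the
  # large-scale flank of a bell or sigmoid cannot mask the dips.
  Sr <- Sf - S
  f_left <- min(Sr[in_win(th$fine_left_window)])
  f_top <- max(Sr[in_win(th$fine_top_window)])
  f_right <- min(Sr[in_win(th$fine_right_window)])
  fine_n <- as.integer(f_top - f_left >= th$fine_prominence &&
                         f_top - f_right >= th$fine_prominence)

  # mid peak + long trough (pigment + structure signature)
  mid_pk <- peaks[peaks$wl >= th$mid_peak_window[1] &
                    peaks$wl <= th$mid_peak_window[2], , drop = FALSE]
  mid_peak_val <- if (nrow(mid_pk)) max(mid_pk$height) else NA_real_
  long_trough <- nrow(mid_pk) > 0 &&
    (mid_peak_val - long_tail) >= th$long_trough_frac * mid_peak_val

  # sigmoid shoulder: steep rise reaching 90% of max early, then a plateau
  reach90 <- wl[which(S >= min(S) + 0.9 * rng)[1]]
  after <- wl[-length(wl)] >= reach90 + 20
  plateau_ok <- if (any(after)) abs(mean(deriv[after])) <= th$plateau_slope
                else TRUE
  mono <- if (rng < 1e-9) 0 else
    suppressWarnings(cor(S, wl, method = "spearman"))
  if (is.na(mono)) mono <- 0
  shoulder <- max(deriv) >= th$steep_slope && reach90 <= th$shoulder_reach_nm &&
    plateau_ok && mono >= th$min_monotonicity

  uv_peak_ratio <- if (long_tail > 0) short_max / long_tail else Inf
  list(flatness = if (mn > 0) rng / mn else 0,
       monotonicity = mono,
       range = rng, mean = mn,
       peaks = peaks[, c("wl", "height", "prominence")],
       trough_wl = trough_wl, trough_val = trough_val,
       trough_depth = depth, trough_present = trough_present,
       fine_structure450 = fine_n,
       mid_peak_val = mid_peak_val, long_trough = long_trough,
       shoulder = shoulder,
       long_tail = long_tail, short_max = short_max,
       uv_peak_ratio = uv_peak_ratio)
}

#' Classify one spectrum into a colour-production mechanism
#'
#' Decision rules, in precedence order (combination rules before
#' single-mechanism rules; melanin is the fall-through):
#' \enumerate{
#'   \item pigment + structure: 450-nm trough with fine structure, a peak
#'     between 500 and 600 nm, and another trough at longer wavelengths ->
#'     `carotenoid_structural` (or `psittacofulvin_structural` in parrot
#'     orders);
#'   \item carotenoid-type: a 450-nm trough with characteristic fine
#'     structure and higher long-wavelength reflectance, or a sigmoid rise
#'     with a long-wavelength shoulder -> `carotenoid` (or `psittacofulvin`
#'     in parrot orders; unknown order -> `carotenoid` with a warning);
#'   \item structural: bell-shaped curves with discrete interior maxima
#'     (including multi-peaked iridescence), or a UV-truncated peak
#'     (short-wavelength reflectance well above long-wavelength);
#'   \item melanin: flat or monotonically rising without a clear maximum --
#'     the unmarked category, which by convention includes white.
#' }
#'
#' @param features From [spectral_features()].
#' @param order Taxonomic order of the species (string; may be "unknown").
#' @param thresholds From [classifier_thresholds()].
#' @return One of [mechanism_labels()].
#' @export
classify_mechanism <- function(features, order = "unknown",
                               thresholds = classifier_thresholds()) {
  th <- thresholds
  f <- features
  parrot <- order %in% th$parrot_orders
  pigment <- if (parrot) "psittacofulvin" else "carotenoid"

  combo <- f$trough_present && f$long_trough && f$fine_structure450 >= 1
  if (combo) return(paste0(pigment, "_structural"))

  caro_trough <- f$trough_present && f$fine_structure450 >= 1 &&
    f$long_tail >= f$trough_val + th$trough_depth_abs &&
    f$long_tail >= f$short_max
  caro_sigmoid <- f$shoulder
  if (caro_trough || caro_sigmoid) {
    if (order == "unknown")
      warning("carotenoid-type spectrum with unknown order: cannot test ",
              "parrot membership; labelled carotenoid", call. = FALSE)
    return(pigment)
  }

  structural <- nrow(f$peaks) >= 1 ||
    (f$uv_peak_ratio >= th$uv_ratio_min &&
       f$short_max - f$long_tail >= th$uv_excess_abs)
  if (structural) return("structural")

  "melanin"
}

#' Classify every spectrum in a set
#'
#' @param set A resampled [spectrum_set()].
#' @param thresholds From [classifier_thresholds()].
#' @return List: `labels` (tibble of spectrum metadata + `mechanism`) and
#'   `shares` (tibble mechanism / n / share_pct; shares sum to 100 over the
#'   six labels).
#' @export
classify_set <- function(set, thresholds = classifier_thresholds()) {
  sm <- spectra_matrix(set)
  lab <- vapply(seq_len(ncol(sm$R)), function(j) {
    classify_mechanism(spectral_features(sm$R[, j], thresholds),
                       order = sm$meta$order[j], thresholds = thresholds)
  }, character(1))
  labels <- sm$meta
  labels$mechanism <- lab
  shares <- tibble(mechanism = mechanism_labels()) |>
    left_join(count(labels, .data$mechanism), by = "mechanism") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           share_pct = 100 * .data$n / sum(.data$n))
  list(labels = labels, shares = shares)
}
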