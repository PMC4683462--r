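# Reading, validating and resampling reflectance spectra.
#
# A SpectrumSet is a long tibble with one row per (spectrum, wavelength):
#   spectrum_id, species, order, sex, specimen_id, patch,
#   wavelength_nm, reflectance_pct
# plus attributes "provenance" and (after read) "read_report".

.meta_cols <- c("species", "order", "sex", "specimen_id", "patch")

#' Construct a spectrum set
#'
#' @param df Long data frame with columns `spectrum_id`, `species`, `order`,
#'   `sex`, `specimen_id`, `patch`, `wavelength_nm`, `reflectance_pct`.
#'   Missing metadata columns are filled with `"unknown"`; a missing
#'   `spectrum_id` is derived from the metadata tuple.
#' @param provenance Free-text provenance note.
#' @return A `spectrum_set` (long tibble).
#' @export
spectrum_set <- function(df, provenance = "") {
  df <- as_tibble(df)
  if (!all(c("wavelength_nm", "reflectance_pct") %in% names(df)))
    stop("spectrum_set needs wavelength_nm and reflectance_pct columns",
         call. = FALSE)
  for (mc in .meta_cols)
    if (!mc %in% names(df)) df[[mc]] <- "unknown"
  df$sex <- normalize_sex(df$sex)
  if (!"spectrum_id" %in% names(df))
    df$spectrum_id <- paste(df$species, df$sex, df$specimen_id, df$patch,
                            sep = "|")
  df <- df[, c("spectrum_id", .meta_cols, "wavelength_nm", "reflectance_pct")]
  df$wavelength_nm <- as.numeric(df$wavelength_nm)
  df$reflectance_pct <- as.numeric(df$reflectance_pct)
  structure(df, class = c("spectrum_set", class(df)),
            provenance = provenance)
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("m", "male")] <- "male"
  x[x %in% c("f", "female")] <- "female"
  x[is.na(x)] <- "unknown"
  x
}

#' @export
print.spectrum_set <- function(x, ...) {
  n <- length(unique(x$spectrum_id))
  cat(sprintf("<spectrum_set: %d spectra, %d species, grid %g-%g nm>\n",
              n, length(unique(x$species)), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  NextMethod()
}

#' Read reflectance spectra from a delimited text file
#'
#' Two dialects are supported. `"long"`: columns `wavelength_nm`,
#' `reflectance_pct` plus metadata columns (`species`, `order`, `sex`,
#' `specimen_id`, `patch`, optionally `spectrum_id`); absent metadata becomes
#' `"unknown"`. `"wide"`: first column `wavelength_nm`, every other column one
#' spectrum, named `<species>|<order>|<sex>|<specimen_id>|<patch>`.
#'
#' Spectra whose reflectance fails to parse as numbers are dropped and listed
#' in the `read_report` attribute of the result, never silently repaired.
#'
#' @param path File path (UTF-8 CSV, "." decimal separator).
#' @param format `"long"` or `"wide"`.
#' @return A [spectrum_set()]; `attr(, "read_report")` is a tibble of dropped
#'   spectra with reasons.
#' @export
read_spectra <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read spectra file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"wavelength_nm" %in% names(raw))
    stop("spectra file has no wavelength_nm column: ", path, call. = FALSE)
  if (format == "long") {
    if (!"reflectance_pct" %in% names(raw))
      stop("long-format file has no reflectance_pct column: ", path,
           call. = FALSE)
    df <- raw
    df$wavelength_nm <- suppressWarnings(as.numeric(df$wavelength_nm))
    refl <- suppressWarnings(as.numeric(df$reflectance_pct))
    df$reflectance_pct <- refl
    set <- spectrum_set(df, provenance = paste0("read_spectra(long): ", path))
  } else {
    spec_cols <- setdiff(names(raw), "wavelength_nm")
    wl <- suppressWarnings(as.numeric(raw$wavelength_nm))
    pieces <- lapply(spec_cols, function(cn) {
      meta <- strsplit(cn, "|", fixed = TRUE)[[1]]
      meta <- c(meta, rep("unknown", max(0, 5 - length(meta))))[1:5]
      tibble(spectrum_id = cn, species = meta[1], order = meta[2],
             sex = meta[3], specimen_id = meta[4], patch = meta[5],
             wavelength_nm = wl,
             reflectance_pct = suppressWarnings(as.numeric(raw[[cn]])))
    })
    set <- spectrum_set(bind_rows(pieces),
                        provenance = paste0("read_spectra(wide): ", path))
  }
  # drop spectra with non-numeric reflectance or wavelength, keep a report
  bad <- set |>
    group_by(.data$spectrum_id) |>
    summarise(n_bad = sum(is.na(.data$reflectance_pct) |
                            is.na(.data$wavelength_nm)), .groups = "drop") |>
    filter(.data$n_bad > 0)
  report <- tibble(spectrum_id = bad$spectrum_id,
                   reason = sprintf("%d unparseable value(s); spectrum dropped",
                                    bad$n_bad))
  out <- set[!set$spectrum_id %in% bad$spectrum_id, ]
  out <- spectrum_set(out, provenance = attr(set, "provenance"))
  attr(out, "read_report") <- report
  out
}

#' Write a spectrum set to CSV
#'
#' @param set A [spectrum_set()].
#' @param path Output path.
#' @param format `"long"` or `"wide"` (see [read_spectra()]).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    readr::write_csv(as_tibble(as.data.frame(set)), path, progress = FALSE)
  } else {
    wide <- set |>
      mutate(col = paste(.data$species, .data$order, .data$sex,
                         .data$specimen_id, .data$patch, sep = "|")) |>
      select("wavelength_nm", "col", "reflectance_pct") |>
      tidyr::pivot_wider(names_from = "col", values_from = "reflectance_pct")
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}

#' Resample one spectrum onto the standard 5-nm grid
#'
#' Linear interpolation onto 300--700 nm in 5-nm steps, with reflectance
#' clamped to \[0, 100\] (small negative instrument noise is tolerated on
#' input but never propagated).
#'
#' @param wavelengths,reflectance Numeric vectors of equal length (>= 2),
#'   wavelengths strictly increasing.
#' @param id Spectrum name used in error messages.
#' @return List with `wavelength_nm` (the standard grid) and
#'   `reflectance_pct` (length 81, in \[0, 100\]).
#' @export
resample_spectrum <- function(wavelengths, reflectance, id = "spectrum") {
  if (length(wavelengths) != length(reflectance) || length(wavelengths) < 2)
    stop("spectrum '", id, "': wavelengths and reflectance must have equal length >= 2",
         call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("spectrum '", id, "': wavelengths must be strictly increasing",
         call. = FALSE)
  grid <- std_grid()
  if (min(wavelengths) > grid[1] || max(wavelengths) < grid[length(grid)])
    stop("spectrum '", id, "' does not cover 300-700 nm (",
         min(wavelengths), "-", max(wavelengths), ")", call. = FALSE)
  y <- approx(wavelengths, reflectance, xout = grid, method = "linear")$y
  list(wavelength_nm = grid, reflectance_pct = pmin(100, pmax(0, y)))
}

#' Resample every spectrum in a set onto the standard grid
#'
#' @param set A [spectrum_set()].
#' @return A [spectrum_set()] on the 81-point grid.
#' @export
resample_spectra <- function(set) {
  sp <- split(seq_len(nrow(set)), set$spectrum_id)
  pieces <- lapply(names(sp), function(id) {
    rows <- sp[[id]]
    o <- order(set$wavelength_nm[rows])
    rows <- rows[o]
    rs <- resample_spectrum(set$wavelength_nm[rows],
                            set$reflectance_pct[rows], id = id)
    meta <- set[rows[1], c("spectrum_id", .meta_cols)]
    tibble(meta, wavelength_nm = rs$wavelength_nm,
           reflectance_pct = rs$reflectance_pct)
  })
  spectrum_set(bind_rows(pieces),
               provenance = paste0(attr(set, "provenance"), " | resampled"))
}

#' Validate a spectrum set
#'
#' Pure reporting: flags spectra off the standard grid, reflectance outside
#' \[0, 100\], unknown sex or order, and duplicated
#' (species, sex, specimen_id, patch) metadata tuples. Never mutates data.
#'
#' @param set A [spectrum_set()].
#' @param patches Expected patch labels (default [default_patches()]); `NULL`
#'   disables the patch check.
#' @return List of tibbles: `off_grid`, `out_of_range`, `unknown_sex`,
#'   `unknown_order`, `bad_patch`, `duplicates`; plus `n_issues`.
#' @export
validate_set <- function(set, patches = default_patches()) {
  grid <- std_grid()
  per <- set |>
    group_by(.data$spectrum_id, .data$species, .data$order, .data$sex,
             .data$specimen_id, .data$patch) |>
    summarise(
      off_grid = !identical(sort(unique(.data$wavelength_nm)), grid) &&
        !isTRUE(all.equal(sort(unique(.data$wavelength_nm)), grid)),
      n_out = sum(.data$reflectance_pct < 0 | .data$reflectance_pct > 100,
                  na.rm = TRUE),
      .groups = "drop")
  dup <- per |>
    count(.data$species, .data$sex, .data$specimen_id, .data$patch,
          name = "n_spectra") |>
    filter(.data$n_spectra > 1)
  out <- list(
    off_grid = per[per$off_grid, c("spectrum_id")],
    out_of_range = per[per$n_out > 0, c("spectrum_id", "n_out")],
    unknown_sex = per[!per$sex %in% c("male", "female"), c("spectrum_id", "sex")],
    unknown_order = per[per$order == "unknown", c("spectrum_id")],
    bad_patch = if (is.null(patches)) tibble(spectrum_id = character())
      else per[!per$patch %in% patches, c("spectrum_id", "patch")],
    duplicates = dup)
  out$n_issues <- sum(vapply(out[1:6], nrow, 1L))
  out
}

#' Average replicate scans within specimen
#'
#' Collapses repeated scans of the same (species, sex, specimen, patch) to
#' their mean reflectance at each wavelength, before visual modelling.
#' Averaging across specimens of a species happens later, in colour space
#' (see [aggregate_species_sex()]).
#'
#' @param set A [spectrum_set()] on a common grid.
#' @return A [spectrum_set()] with one spectrum per metadata tuple.
#' @export
average_replicates <- function(set) {
  out <- set |>
    group_by(.data$species, .data$order, .data$sex, .data$specimen_id,
             .data$patch, .data$wavelength_nm) |>
    summarise(reflectance_pct = mean(.data$reflectance_pct), .groups = "drop")
  spectrum_set(out, provenance = paste0(attr(set, "provenance"),
                                        " | replicates averaged"))
}

#' Spectrum set as a wavelength-by-spectrum matrix
#'
#' @param set A [spectrum_set()] on the standard grid.
#' @return List: `wl` (grid), `R` (81 x n matrix, percent), `meta` (tibble,
#'   one row per spectrum, column order matching `R`).
#' @export
spectra_matrix <- function(set) {
  grid <- std_grid()
  ids <- unique(set$spectrum_id)
  set <- arrange(set, match(.data$spectrum_id, ids), .data$wavelength_nm)
  if (nrow(set) != length(grid) * length(ids) ||
      !isTRUE(all.equal(set$wavelength_nm[seq_along(grid)], grid)))
    stop("spectra_matrix: set is not on the standard grid; resample first",
         call. = FALSE)
  R <- matrix(set$reflectance_pct, nrow = length(grid))
  meta <- set[seq(1, nrow(set), by = length(grid)),
              c("spectrum_id", .meta_cols)]
  list(wl = grid, R = R, meta = as_tibble(meta))
}
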