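# End-to-end analysis: spectra -> visual model -> mechanism classification ->
# gamut metrics -> bootstrap comparisons -> tidy report bundle.

#' Analysis configuration
#'
#' @param input Path to a long-format spectra CSV, or `NULL` to simulate a
#'   synthetic avifauna with `avifauna`.
#' @param avifauna An [avifauna_config()] (used when `input` is `NULL`).
#' @param visual_system `"U"` or `"V"`.
#' @param sensitivities Optional sensitivity CSV path (overrides templates).
#' @param irradiance `"flat"` or a numeric vector on the grid.
#' @param cell_size Chromatic-locus edge (default 0.022).
#' @param denominator `"tetra"` (percent of the theoretical tetrahedron) or
#'   `"sample"` (percent of the full-sample gamut) for top-level volume
#'   percentages; table columns always name their denominator.
#' @param bootstrap_B Bootstrap replicates (default 2000 at desk scale; the
#'   classical choice is 10000).
#' @param boot_metric Metric for the order tables: `"n_loci"` or
#'   `"hull_volume"`.
#' @param average_replicates Collapse replicate scans within specimen first.
#' @param seed Root seed; per-stage seeds are derived from it.
#' @param out_dir Output directory.
#' @param write_plots Also write shadow-plot PNGs.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, avifauna = avifauna_config(),
                            visual_system = c("U", "V"),
                            sensitivities = NULL, irradiance = "flat",
                            cell_size = 0.022,
                            denominator = c("tetra", "sample"),
                            bootstrap_B = 2000,
                            boot_metric = c("n_loci", "hull_volume"),
                            average_replicates = TRUE, seed = 1,
                            out_dir = tempfile("avigamut_run_"),
                            write_plots = FALSE) {
  structure(list(input = input, avifauna = avifauna,
                 visual_system = match.arg(visual_system),
                 sensitivities = sensitivities, irradiance = irradiance,
                 cell_size = cell_size, denominator = match.arg(denominator),
                 bootstrap_B = bootstrap_B,
                 boot_metric = match.arg(boot_metric),
                 average_replicates = average_replicates,
                 seed = seed, out_dir = out_dir, write_plots = write_plots),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Scalar fields map one-to-one onto [analysis_config()] arguments; an
#' `avifauna:` block maps onto [avifauna_config()] (its `orders` table, if
#' given, as a list of name/size/is_parrot_like/freq entries).
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  av <- if (!is.null(y$avifauna)) {
    a <- y$avifauna
    if (!is.null(a$orders)) {
      a$orders <- tibble(
        name = vapply(a$orders, `[[`, "", "name"),
        size = vapply(a$orders, `[[`, 1, "size"),
        is_parrot_like = vapply(a$orders, `[[`, TRUE, "is_parrot_like"),
        freq = lapply(a$orders, function(o) unlist(o$freq)))
    }
    do.call(avifauna_config, a)
  } else avifauna_config()
  y$avifauna <- NULL
  do.call(analysis_config, c(y, list(avifauna = av)))
}

.stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    unlink(out_dir, recursive = TRUE)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full colour-gamut analysis
#'
#' Deterministic for a given config (all randomness flows from the root
#' seed, split per stage). Writes to `config$out_dir`:
#' `summary.json`, `mechanism_table.csv`, `sex_table.csv`,
#' `order_table.csv` (per order and sex: n, observed %, 2.5% and 97.5%
#' bootstrap quantiles, two-tailed p), `run_log.txt`, and optionally shadow
#' plots. Any stage failure aborts with a stage-named error and removes
#' partial outputs.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with every table plus the paths written.
#' @export
run_full_analysis <- function(config) {
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- cf$seed + c(sim = 0, overlap = 1, boot_sex_vol = 2,
                       boot_sex_loci = 3, boot_order = 4)

  truth <- NULL
  set <- .stage("input", {
    if (is.null(cf$input)) {
      cf$avifauna$seed <- unname(seeds["sim"])
      sim <- gen_avifauna(cf$avifauna)
      truth <- sim$truth
      sim$spectra
    } else {
      resample_spectra(read_spectra(cf$input, format = "long"))
    }
  }, cf$out_dir)
  if (isTRUE(cf$average_replicates))
    set <- .stage("average_replicates", average_replicates(set), cf$out_dir)

  sens <- .stage("sensitivities",
                 build_sensitivity_set(type = cf$visual_system,
                                       file = cf$sensitivities), cf$out_dir)
  pts <- .stage("visual_model", model_colours(set, sens, cf$irradiance),
                cf$out_dir)
  cls <- .stage("classify", classify_set(set), cf$out_dir)
  pts$mechanism <- cls$labels$mechanism[match(pts$spectrum_id,
                                              cls$labels$spectrum_id)]
  agg <- .stage("aggregate", aggregate_species_sex(pts), cf$out_dir)

  # ---- whole-sample gamut -------------------------------------------------
  hv <- hull_volume(agg)
  lm_all <- rasterize_loci(agg, cf$cell_size)
  ls_all <- locus_summary(lm_all)
  denom_note <- if (cf$denominator == "tetra") "tetrahedron" else "sample hull"
  denom_vol <- if (cf$denominator == "tetra") tetra_volume() else hv$volume

  # ---- mechanism table ----------------------------------------------------
  mech_tab <- .stage("mechanism_table", {
    by_m <- split(agg, agg$mechanism)
    all_keys <- .locus_keys(lm_all)
    rows <- lapply(mechanism_labels(), function(mm) {
      share <- cls$shares$share_pct[cls$shares$mechanism == mm]
      if (is.null(by_m[[mm]])) {
        return(tibble(mechanism = mm, n_points = 0L, share_pct = share,
                      hull_volume = 0,
                      pct_volume_of_sample = 0, n_loci = 0L,
                      pct_loci_of_sample = 0, pct_unique_loci = 0))
      }
      g <- by_m[[mm]]
      hvm <- hull_volume(g)$volume
      lmm <- rasterize_loci(g, cf$cell_size)
      km <- .locus_keys(lmm)
      other <- unlist(lapply(setdiff(names(by_m), mm), function(o)
        .locus_keys(rasterize_loci(by_m[[o]], cf$cell_size))))
      tibble(mechanism = mm, n_points = nrow(g), share_pct = share,
             hull_volume = hvm,
             pct_volume_of_sample = 100 * hvm / hv$volume,
             n_loci = nrow(lmm),
             pct_loci_of_sample = 100 * nrow(lmm) / ls_all$n_occupied,
             pct_unique_loci = 100 * length(setdiff(km, other)) /
               ls_all$n_occupied)
    })
    bind_rows(rows)
  }, cf$out_dir)

  # ---- sex comparison -----------------------------------------------------
  sex_res <- .stage("sex_comparison", {
    males <- agg[agg$sex == "male", ]
    females <- agg[agg$sex == "female", ]
    both_sp <- intersect(unique(males$species), unique(females$species))
    m2 <- males[males$species %in% both_sp, ]
    f2 <- females[females$species %in% both_sp, ]
    ov <- hull_overlap(m2, f2, method = "exact",
                       seed = unname(seeds["overlap"]))
    lmm <- rasterize_loci(m2, cf$cell_size)
    lmf <- rasterize_loci(f2, cf$cell_size)
    su <- shared_unique_loci(lmf, lmm) # a = females, b = males
    bs_vol <- bootstrap_sex_ratio(bind_rows(m2, f2), "hull_volume",
                                  B = cf$bootstrap_B,
                                  seed = unname(seeds["boot_sex_vol"]),
                                  cell_size = cf$cell_size)
    bs_loci <- bootstrap_sex_ratio(bind_rows(m2, f2), "n_loci",
                                   B = cf$bootstrap_B,
                                   seed = unname(seeds["boot_sex_loci"]),
                                   cell_size = cf$cell_size)
    tab <- tibble(
      quantity = c("hull_volume", "pct_volume_of_tetra",
                   "n_loci", "pct_loci_of_sample",
                   "overlap_pct_of_own_volume", "pct_loci_shared_of_union",
                   "pct_loci_unique_of_union",
                   "ratio_f_over_m_median", "ratio_f_over_m_q025",
                   "ratio_f_over_m_q975",
                   "ratio_loci_f_over_m_median", "ratio_loci_f_over_m_q025",
                   "ratio_loci_f_over_m_q975"),
      male = c(ov$vol_a, 100 * ov$vol_a / tetra_volume(),
               nrow(lmm), 100 * nrow(lmm) / ls_all$n_occupied,
               100 * ov$frac_of_a, 100 * su$frac_shared,
               100 * su$frac_only_b,
               bs_vol$median, bs_vol$q025, bs_vol$q975,
               bs_loci$median, bs_loci$q025, bs_loci$q975),
      female = c(ov$vol_b, 100 * ov$vol_b / tetra_volume(),
                 nrow(lmf), 100 * nrow(lmf) / ls_all$n_occupied,
                 100 * ov$frac_of_b, 100 * su$frac_shared,
                 100 * su$frac_only_a,
                 bs_vol$median, bs_vol$q025, bs_vol$q975,
                 bs_loci$median, bs_loci$q025, bs_loci$q975))
    list(table = tab, overlap = ov, shared = su,
         boot_volume = bs_vol, boot_loci = bs_loci)
  }, cf$out_dir)

  # ---- per-order observed vs expected ------------------------------------
  order_tab <- .stage("order_table", {
    rows <- list()
    for (sx in c("male", "female")) {
      px <- agg[agg$sex == sx, ]
      for (oo in sort(unique(px$order))) {
        bo <- bootstrap_order_null(px, order = oo, metric = cf$boot_metric,
                                   B = cf$bootstrap_B,
                                   seed = unname(seeds["boot_order"]),
                                   cell_size = cf$cell_size)
        rows[[paste(sx, oo)]] <- tibble(
          order = oo, sex = sx,
          n = length(unique(px$species[px$order == oo])),
          metric = cf$boot_metric,
          observed_pct_of_sample = bo$observed,
          q025_pct_of_sample = bo$q025, q975_pct_of_sample = bo$q975,
          p_two_tailed = bo$p_two_tailed)
      }
    }
    bind_rows(rows)
  }, cf$out_dir)

  # ---- write bundle -------------------------------------------------------
  paths <- .stage("write", {
    p <- list(
      mechanism_table = file.path(cf$out_dir, "mechanism_table.csv"),
      sex_table = file.path(cf$out_dir, "sex_table.csv"),
      order_table = file.path(cf$out_dir, "order_table.csv"),
      summary = file.path(cf$out_dir, "summary.json"),
      log = file.path(cf$out_dir, "run_log.txt"))
    readr::write_csv(mech_tab, p$mechanism_table, progress = FALSE)
    readr::write_csv(sex_res$table, p$sex_table, progress = FALSE)
    readr::write_csv(order_tab, p$order_table, progress = FALSE)
    summary <- list(
      n_spectra = length(unique(set$spectrum_id)),
      n_species = length(unique(set$species)),
      visual_system = cf$visual_system,
      hull_volume = hv$volume,
      pct_of_theoretical_space = 100 * hv$volume / tetra_volume(),
      volume_denominator = denom_note,
      pct_volume = 100 * hv$volume / denom_vol,
      n_occupied_loci = ls_all$n_occupied,
      half_mass_locus_fraction = ls_all$mass_fraction,
      cell_size = cf$cell_size, bootstrap_B = cf$bootstrap_B,
      seed = cf$seed)
    jsonlite::write_json(summary, p$summary, auto_unbox = TRUE, digits = NA)
    writeLines(c(
      sprintf("avigamut %s", as.character(utils::packageVersion("avigamut"))),
      sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("input: %s", if (is.null(cf$input)) "synthetic" else cf$input),
      sprintf("visual_system: %s", cf$visual_system),
      sprintf("cell_size: %g", cf$cell_size),
      sprintf("bootstrap_B: %d", cf$bootstrap_B),
      sprintf("boot_metric: %s", cf$boot_metric),
      sprintf("seed: %d", cf$seed)), p$log)
    if (isTRUE(cf$write_plots)) {
      for (pl in c("yz", "yx")) {
        f <- file.path(cf$out_dir, sprintf("shadow_%s.png", pl))
        grDevices::png(f, width = 900, height = 800, res = 150)
        print(plot_shadow(agg, plane = pl, cell_size = cf$cell_size))
        grDevices::dev.off()
        p[[paste0("shadow_", pl)]] <- f
      }
    }
    p
  }, cf$out_dir)

  invisible(list(config = cf, points = agg, truth = truth,
                 hull = hv, loci = ls_all,
                 mechanism_table = mech_tab, sex = sex_res,
                 order_table = order_tab, paths = paths))
}
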