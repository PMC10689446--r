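#' Run the full synthetic-to-summary analysis pipeline
#'
#' Chains the package's stages end to end on synthetic data with known
#' truth: generate gridded cubes, a flux-tower series and a warming
#' synthesis; derive flux metrics (inverted canopy conductance, underlying
#' water-use efficiency); map the detrended GPP-VPD partial correlation and
#' summarise it regionally, along the peatland-extent gradient and by
#' aridity class; run the warming analysis (paired tests, exponential
#' temperature-VPD fit, growth-response regression); fit the random-forest
#' sensitivity model on a planted pixel table; and run the mediation
#' battery. All artifacts are plain text (CSV/JSON) plus a manifest with the
#' configuration hash, seed and input checksums; reruns of the same
#' configuration are reproducible.
#'
#' @param config A YAML path or a named list. Recognised entries: `seed`
#'   (integer, default 1), `out_dir` (default `tempfile("peatvpd_run")`),
#'   `grid` (arguments to [grid_gen_config()]), `flux` (arguments to
#'   [flux_gen_config()]), `warming` (arguments to [gen_warming_sites()]),
#'   `pixels` (arguments to [gen_predictor_table()]), `alpha` (significance
#'   level, default 0.05), `n_boot` (mediation bootstrap, default 1000),
#'   `rf_repeats` (default 15).
#' @return The output directory path, invisibly; side effect: artifact files
#'   under it (`region_summary.csv`, `extent_gradient.csv`,
#'   `aridity_summary.csv`, `pcor_map.csv`, `flux_metrics.csv`,
#'   `warming.json`, `sensitivities.json`, `mediation.json`, truth sidecars
#'   and `manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("peatvpd_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha %||% 0.05
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  grid <- stage("simulate", {
    gcfg <- do.call(grid_gen_config,
                    utils::modifyList(list(seed = seed), config$grid %||% list()))
    gen_gridded(gcfg)
  })
  flux <- stage("simulate", {
    fcfg <- do.call(flux_gen_config,
                    utils::modifyList(list(seed = seed + 1L), config$flux %||% list()))
    gen_flux_tower(fcfg)
  })
  warming <- stage("simulate", {
    do.call(gen_warming_sites,
            utils::modifyList(list(seed = seed + 2L), config$warming %||% list()))
  })
  pixels <- stage("simulate", {
    do.call(gen_predictor_table,
            utils::modifyList(list(seed = seed + 3L), config$pixels %||% list()))
  })
  write_truth_sidecar(list(grid = list(n_rh_resampled = grid$n_rh_resampled),
                           flux = flux$truth[c("gc", "uwue")],
                           warming = warming$truth[c("effect_slope", "vpd_law")],
                           pixels = pixels$truth),
                      file.path(out_dir, "truth.json"))

  # -- flux metrics --------------------------------------------------------
  fd <- flux$data
  flux_metrics <- stage("flux_metrics", {
    gc <- canopy_conductance(fd$le, fd$h, fd$vpd, fd$ws, fd$ustar, fd$ta,
                             pressure = fd$pa)
    data.frame(year = fd$year, month = fd$month,
               gc = as.numeric(gc),
               uwue = uwue(fd$gpp, fd$vpd / 10, fd$et),
               growing_season = growing_season_mask(fd$ta))
  })
  utils::write.csv(flux_metrics, file.path(out_dir, "flux_metrics.csv"),
                   row.names = FALSE)

  # -- pcor map and regional summaries -------------------------------------
  cb <- grid$cubes
  rmap <- stage("pcor_map", {
    pcor_map(cb$gpp, cb$vpd,
             list(cb$ta, cb$radiation, cb$wind, cb$precip))
  })
  utils::write.csv(
    data.frame(lat = rep(rmap$lat, times = length(rmap$lon)),
               lon = rep(rmap$lon, each = length(rmap$lat)),
               r = as.vector(rmap$r), p_value = as.vector(rmap$p_value)),
    file.path(out_dir, "pcor_map.csv"), row.names = FALSE)
  region <- stage("summaries", region_summary(rmap, alpha = alpha, label = "all"))
  utils::write.csv(as.data.frame(region),
                   file.path(out_dir, "region_summary.csv"), row.names = FALSE)
  gradient <- stage("summaries", extent_gradient(rmap, grid$extent, alpha = alpha))
  utils::write.csv(gradient, file.path(out_dir, "extent_gradient.csv"),
                   row.names = FALSE)
  ai_masks <- aridity_split(grid$ai)
  ai_rows <- lapply(c("nonhumid_mask", "humid_mask"), function(nm) {
    if (!any(ai_masks[[nm]])) return(NULL)
    as.data.frame(region_summary(rmap, ai_masks[[nm]], alpha = alpha,
                                 label = sub("_mask", "", nm)))
  })
  utils::write.csv(do.call(rbind, ai_rows),
                   file.path(out_dir, "aridity_summary.csv"), row.names = FALSE)

  # -- warming analysis ----------------------------------------------------
  warming_out <- stage("warming", {
    st <- warming$sites
    fit <- fit_ta_vpd_exponential(c(st$ta_c, st$ta_w), c(st$vpd_c, st$vpd_w))
    dvpd <- synthesis_vpd_delta(st)
    reg <- vpd_effect_regression(growth_response(st$growth_c, st$growth_w), dvpd)
    tests <- lapply(c(ta = "ta", vpd = "vpd"), function(v) {
      unclass(paired_warming_test(st[[paste0(v, "_c")]], st[[paste0(v, "_w")]]))
    })
    list(ta_vpd_fit = unclass(fit), effect_regression = unclass(reg),
         paired_tests = tests)
  })
  jsonlite::write_json(warming_out, file.path(out_dir, "warming.json"),
                       auto_unbox = TRUE, digits = NA)

  # -- random-forest sensitivity ------------------------------------------
  sens <- stage("sensitivity", {
    rf <- fit_rf(pixels$table, seed = seed + 4L)
    list(model_r = rf$model_r, gate_passed = rf$gate_passed,
         sensitivity = as.list(rf_sensitivity_all(
           rf, seed = seed + 5L,
           n_repeats = config$rf_repeats %||% 15)))
  })
  jsonlite::write_json(sens, file.path(out_dir, "sensitivities.json"),
                       auto_unbox = TRUE, digits = NA)

  # -- mediation -----------------------------------------------------------
  med <- stage("mediation", {
    battery <- mediation_battery(pixels$table,
                                 n_boot = config$n_boot %||% 1000,
                                 seed = seed + 6L)
    lapply(battery, function(m) {
      list(effects = as.list(m$effects),
           ci_lower = as.list(m$ci[1, names(m$effects)]),
           ci_upper = as.list(m$ci[2, names(m$effects)]),
           significant = as.list(m$significant), n = m$n)
    })
  })
  jsonlite::write_json(med, file.path(out_dir, "mediation.json"),
                       auto_unbox = TRUE, digits = NA)

  # -- manifest ------------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config[setdiff(names(config), "out_dir")], cfg_file)
  artifacts <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "peatvpd",
    version = as.character(utils::packageVersion("peatvpd")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    checksums = as.list(tools::md5sum(file.path(out_dir, artifacts)))
  )
  names(manifest$checksums) <- artifacts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
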