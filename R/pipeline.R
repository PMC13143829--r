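#' Default pipeline configuration
#'
#' Stage parameters default to the analysis' stated settings: 80 px windows
#' with 50% overlap, 20-frame chunks with 50% overlap, a 100-cell exclusion
#' threshold and the 0-2 / 3-5 ECM grouping.
#'
#' @return nested named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    stages = c("generate", "piv", "metrics", "wetting", "tma"),
    movie = list(kind = "correlated", xi_true = 40, vrms = 1.5, drift = c(0, 0),
                 shape = c(320L, 320L), n_frames = 21L,
                 pixel_size_um = 0.65, frame_interval_min = 10),
    piv = list(window_size_px = 80L, overlap = 0.5, frame_lag = 1L,
               chunk_length = 20L, chunk_overlap = 0.5),
    metrics = list(bin_width_px = NULL, fit_range = NULL),
    wetting = list(r0_um = 100, radial_speed_um_per_h = 10,
                   times_h = seq(0, 48, by = 2), pixel_size_um = 2),
    tma = list(n_patients = 198L, n_low_cell = 5L, hazard_ratio = 2,
               censoring_rate = 0.3, min_cells = 100L)
  )
}

validate_config <- function(config, defaults = default_pipeline_config()) {
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) {
    stop_input(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
               "collmot_schema_error")
  }
  merged <- utils::modifyList(defaults, config)
  for (blk in intersect(names(config), setdiff(names(defaults), "stages"))) {
    bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(bad)) {
      stop_input(paste0("unknown config key(s) in '", blk, "': ",
                        paste(bad, collapse = ", ")), "collmot_schema_error")
    }
  }
  merged
}

# small deterministic polynomial string hash for the run report
config_hash <- function(config) {
  s <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# per-stage seed fan-out from one pipeline seed; kept below 2^31
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("generate", "piv", "metrics", "wetting", "tma"))
  (as.integer(seed) * 1009L + idx * 7919L) %% 2147483647L
}

#' Run the synthetic end-to-end pipeline
#'
#' Wires the stages generate -> PIV -> motility metrics -> wetting -> TMA
#' scoring on synthetic inputs, writing per-stage CSV artifacts and a
#' machine-readable JSON run report into `out_dir`.  Deterministic given
#' `seed`: one pipeline seed fans out to fixed per-stage seeds.
#'
#' @param config nested list overriding [default_pipeline_config()], or a
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created if absent).
#' @param seed integer pipeline seed.
#' @return invisibly, the run report list.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_input(paste0("config file does not exist: ", config), "collmot_schema_error")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(r_version = as.character(getRversion()),
                 package_version = as.character(utils::packageVersion("collmot")),
                 seed = as.integer(seed), config_hash = config_hash(cfg),
                 outputs = list())

  metrics <- NULL
  if (any(c("generate", "piv", "metrics") %in% cfg$stages)) {
    mv <- cfg$movie
    flow <- flow_spec(kind = mv$kind, drift = mv$drift, vrms = mv$vrms,
                      xi_true = mv$xi_true, seed = stage_seed(seed, "generate"))
    movie <- make_speckle_movie(flow, shape = mv$shape, n_frames = mv$n_frames,
                                pixel_size_um = mv$pixel_size_um,
                                frame_interval_min = mv$frame_interval_min)
    pc <- do.call(piv_config, c(cfg$piv, list(
      pixel_size_um = mv$pixel_size_um, frame_interval_min = mv$frame_interval_min)))
    fields <- compute_velocity_fields(movie, pc)
    chunks <- temporal_average(fields, pc$chunk_length, pc$chunk_overlap)
    fields_csv <- file.path(out_dir, "velocity_fields.csv")
    write_fields_csv(chunks, fields_csv)
    report$outputs$velocity_fields <- fields_csv
    metrics <- motility_metrics(chunks, bin_width_px = cfg$metrics$bin_width_px,
                                fit_range = cfg$metrics$fit_range)
    metrics_csv <- file.path(out_dir, "motility_metrics.csv")
    utils::write.csv(metrics, metrics_csv, row.names = FALSE)
    report$outputs$motility_metrics <- metrics_csv
  }

  if ("wetting" %in% cfg$stages) {
    w <- cfg$wetting
    series <- make_spheroid_series(w$r0_um, w$radial_speed_um_per_h,
                                   w$times_h, w$pixel_size_um)
    res <- wetting_analysis(series)
    wet_csv <- file.path(out_dir, "wetting.csv")
    utils::write.csv(res$areas, wet_csv, row.names = FALSE)
    summary_csv <- file.path(out_dir, "wetting_summary.csv")
    utils::write.csv(
      data.frame(speed_um_per_h = res$speed_um_per_h,
                 r0_um = w$r0_um, true_speed = w$radial_speed_um_per_h),
      summary_csv, row.names = FALSE)
    report$outputs$wetting <- wet_csv
  }

  if ("tma" %in% cfg$stages) {
    tm <- cfg$tma
    spec <- cohort_spec(n_patients = tm$n_patients, n_low_cell = tm$n_low_cell,
                        hazard_ratio = tm$hazard_ratio,
                        censoring_rate = tm$censoring_rate,
                        seed = stage_seed(seed, "tma"))
    cohort <- make_tma_cohort(spec)
    scored <- score_cohort(cohort$cells, cohort$survival,
                           min_cells = tm$min_cells)
    scored_csv <- file.path(out_dir, "scored_cohort.csv")
    utils::write.csv(scored$cohort, scored_csv, row.names = FALSE)
    sv <- scored$survival
    km_csv <- file.path(out_dir, "km_curves.csv")
    utils::write.csv(km_by_group(sv$time_months, sv$event, sv$ecm_group),
                     km_csv, row.names = FALSE)
    lr <- logrank_test(sv$time_months, sv$event, sv$ecm_group)
    report$outputs$scored_cohort <- scored_csv
    report$outputs$km_curves <- km_csv
    report$logrank <- list(statistic = lr$statistic, p_value = lr$p_value)
  }

  report_path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}
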