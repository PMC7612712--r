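sim_config_fields <- function() {
  c("stage_start", "stage_end", "frame_interval", "somite_period",
    "n_cells_initial", "motility_posterior", "motility_anterior",
    "convergence_slope_dv", "convergence_intercept_dv",
    "convergence_slope_ml", "convergence_intercept_ml",
    "noise_r2_dv", "noise_r2_ml", "cell_volume_mean_by_stage",
    "cell_volume_cv", "drift_amplitude", "rotation_amplitude",
    "intercalation_rate", "psm_boundary_frac", "seed")
}

#' Validate a simulation/benchmark YAML configuration
#'
#' Strict schema check: unknown keys are rejected, types are checked, and
#' the simulation invariants (stage ordering, positive scales, motility
#' gradient direction, R-squared bounds) are verified.  Never mutates
#' state.
#'
#' @param path Path to a YAML file whose keys are [sim_config()] arguments.
#' @return `TRUE` when valid; otherwise a character vector of error
#'   messages (invisibly TRUE / visibly the errors).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  errs <- character(0)
  unknown <- setdiff(names(raw), sim_config_fields())
  if (length(unknown))
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  for (k in setdiff(names(raw), "cell_volume_mean_by_stage")) {
    if (k %in% sim_config_fields() && !is.numeric(raw[[k]]))
      errs <- c(errs, sprintf("%s: expected a number, got %s",
                              k, class(raw[[k]])[1L]))
  }
  if (!is.null(raw$cell_volume_mean_by_stage)) {
    m <- unlist(raw$cell_volume_mean_by_stage)
    if (!is.numeric(m) || is.null(names(m)))
      errs <- c(errs, "cell_volume_mean_by_stage: expected a stage -> volume mapping")
  }
  if (!length(errs)) {
    cfg <- tryCatch({
      do.call(sim_config, raw[!vapply(raw, is.null, logical(1))])
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(cfg)) errs <- c(errs, cfg)
  }
  if (length(errs)) errs else TRUE
}

config_from_yaml <- function(path) {
  v <- validate_config(path)
  if (!isTRUE(v)) stop(paste(v, collapse = "; "))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cell_volume_mean_by_stage))
    raw$cell_volume_mean_by_stage <- unlist(raw$cell_volume_mean_by_stage)
  do.call(sim_config, raw)
}

#' Run the end-to-end compaction-extension benchmark
#'
#' Orchestrates simulate -> measure -> normalise -> statistics on
#' ground-truth tracks and writes a machine-readable report:
#' \enumerate{
#'   \item simulate a tissue bundle from the configuration;
#'   \item tissue morphometrics: stage series, trendline refits of the
#'     simulated series, density increase, cumulative paraxial cell-number
#'     reconstruction from the reference trendlines;
#'   \item reference-frame round trip: world tracks normalised back into
#'     local coordinates;
#'   \item track statistics: posterior vs anterior neighbourhood exchange,
#'     neighbour-pair angle-change analysis with KS comparison, and DV/ML
#'     convergence-field regressions at the configured R-squared targets.
#' }
#' The ground-truth track path is the default benchmark; spot detection
#' and linking are exercised by their own test fixtures so that statistic
#' correctness is separated from tracker error.
#'
#' @param config A [sim_config()], or a path to a YAML file.
#' @param seed Overrides the config seed when not NULL.
#' @param out_dir Optional run directory; when given, the report JSON and
#'   CSV artifacts are written there.
#' @param exchange_cells Number of cells subsampled (deterministically) for
#'   the neighbourhood-exchange summary.
#' @param cum_stage_end Terminal stage of the cumulative paraxial
#'   reconstruction (end of somitogenesis; independent of the simulated
#'   span).
#' @return The report as a nested list (class `pipeline_report`).
#' @export
run_benchmark <- function(config = sim_config(), seed = NULL, out_dir = NULL,
                          exchange_cells = 300L, cum_stage_end = 32L) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    validate_sim_config(config)
  }
  tl <- psm_reference_trendlines()

  bundle <- simulate_tissue(config)
  fi <- config$frame_interval

  ss <- bundle$stage_series
  density_increase_pct <-
    100 * (ss$density[nrow(ss)] / ss$density[1L] - 1)
  refit <- if (nrow(ss) >= 3L) list(
    psm_cells = fit_trendline(ss$stage, ss$psm_cells),
    psm_volume = fit_trendline(ss$stage, ss$psm_volume),
    density = fit_trendline(ss$stage, ss$density)
  ) else list()
  cum_cells <- cumulative_paraxial(tl$psm_cells, tl$somite_cells,
                                   config$stage_start, cum_stage_end)
  cumulative_cell_increase_pct <-
    100 * (cum_cells$cumulative[nrow(cum_cells)] / cum_cells$cumulative[1L] - 1)

  # reference-frame round trip on the drifted tracks
  local_back <- transform_to_local(bundle$tracks_world, bundle$frames)
  roundtrip_max_um <- max(abs(
    as.matrix(local_back[, c("x_um", "y_um", "z_um")]) -
      as.matrix(bundle$tracks[, c("x_um", "y_um", "z_um")])))

  # statistic windows never exceed the simulated span
  span_min <- (bundle$n_frames - 1L) * fi
  win_exchange <- min(60, span_min)
  win_angle <- min(60, span_min)

  # neighbourhood exchange, posterior vs anterior third at frame 0
  psm0 <- bundle$tracks[bundle$tracks$frame == 0L, ]
  psm0 <- psm0[psm0$region == "psm", ]
  qs <- stats::quantile(psm0$x_um, c(1 / 3, 2 / 3))
  post_ids <- psm0$track_id[psm0$x_um <= qs[1L]]
  ant_ids <- psm0$track_id[psm0$x_um >= qs[2L]]
  pick <- function(ids) ids[seq_len(min(length(ids), exchange_cells))]
  exch <- neighbour_exchange(bundle$tracks, k = 10, window_min = win_exchange,
                             frame_interval = fi,
                             cells = c(pick(sort(post_ids)), pick(sort(ant_ids))))
  exch$zone <- ifelse(exch$track_id %in% as.character(post_ids),
                      "posterior", "anterior")
  exchange_summary <- stats::aggregate(count ~ zone, exch, mean)

  ang <- angle_change_analysis(bundle$tracks[bundle$tracks$region == "psm", ],
                               window_min = win_angle, frame_interval = fi)
  ks <- compare_angle_distributions(ang)
  # the non-directional null evaluated on the convergence-field construction
  cloud <- simulate_field_cloud(n = 450, frame_interval = fi,
                                motility = config$motility_posterior,
                                slope_dv = config$convergence_slope_dv,
                                intercept_dv = config$convergence_intercept_dv,
                                slope_ml = config$convergence_slope_ml,
                                intercept_ml = config$convergence_intercept_ml,
                                seed = config$seed + 17L)
  ks_field_null <- compare_angle_distributions(
    angle_change_analysis(cloud, window_min = 60, frame_interval = fi))

  conv <- lapply(c(DV = "DV", ML = "ML"), function(axname) {
    fld <- if (axname == "DV")
      list(s = config$convergence_slope_dv, i = config$convergence_intercept_dv,
           r2 = config$noise_r2_dv)
    else
      list(s = config$convergence_slope_ml, i = config$convergence_intercept_ml,
           r2 = config$noise_r2_ml)
    sim <- simulate_convergence_tracks(
      n = 1161, slope = fld$s, intercept = fld$i, r2 = fld$r2,
      window_min = 120, frame_interval = fi, axis = axname,
      seed = config$seed + match(axname, c("DV", "ML")))
    fit <- convergence_regression(sim$tracks, axis = axname,
                                  window_min = 120, frame_interval = fi)
    list(fit = fit, truth = sim$truth)
  })

  checks <- list(
    density_increase_substantial = density_increase_pct > 50,
    volume_strictly_decreasing = all(diff(ss$psm_volume) < 0),
    density_monotonic = all(diff(ss$density) > 0),
    posterior_exchange_exceeds_anterior =
      exchange_summary$count[exchange_summary$zone == "posterior"] >
      exchange_summary$count[exchange_summary$zone == "anterior"],
    field_null_not_rejected = ks_field_null$p > 0.05,
    roundtrip_below_tol = roundtrip_max_um < 1e-6,
    dv_slope_recovered = abs(conv$DV$fit$slope - config$convergence_slope_dv) <= 0.03,
    ml_slope_recovered = abs(conv$ML$fit$slope - config$convergence_slope_ml) <= 0.03
  )

  report <- structure(list(
    config = unclass(config), seed = config$seed,
    stage_series = ss,
    density_increase_pct = density_increase_pct,
    cumulative_cell_increase_pct = cumulative_cell_increase_pct,
    trendline_refits = lapply(refit, unclass),
    exchange_summary = exchange_summary,
    ks = unclass(ks),
    ks_field_null = unclass(ks_field_null),
    convergence = lapply(conv, function(cc)
      list(fit = unclass(cc$fit), truth = cc$truth)),
    roundtrip_max_um = roundtrip_max_um,
    checks = checks), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bundle(bundle, file.path(out_dir, "bundle"))
    utils::write.csv(ss, file.path(out_dir, "stage_series.csv"),
                     row.names = FALSE)
    utils::write.csv(cum_cells, file.path(out_dir, "cumulative_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(exch, file.path(out_dir, "exchange.csv"),
                     row.names = FALSE)
    utils::write.csv(ang, file.path(out_dir, "angle_pairs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      report[setdiff(names(report), c("stage_series"))],
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
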