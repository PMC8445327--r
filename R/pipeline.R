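# End-to-end pipeline: simulate (optional) -> preprocess -> detect ->
# profile -> hotspots -> sheaths, writing all intermediates so every
# reported statistic can be reconstructed from files.  Fixed config + seed
# gives byte-identical tables.

#' Run the full analysis pipeline on a synthetic scene
#'
#' @param config list with an optional `scene` element (arguments to
#'   [scene_config()]), optional `detection` element (arguments to
#'   [detection_config()]) and optional `register` flag; or a path to a JSON
#'   file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the scene seed when not NULL.
#' @return invisible list with the main result objects and output paths.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  scene_args <- config$scene
  if (is.null(scene_args)) scene_args <- list()
  scene_args <- scene_args[names(scene_args) %in% names(formals(scene_config))]
  cfg <- do.call(scene_config, scene_args)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  det_args <- config$detection
  if (is.null(det_args)) det_args <- list()
  det_args <- det_args[names(det_args) %in% names(formals(detection_config))]
  dcfg <- do.call(detection_config, det_args)
  register <- isTRUE(config$register) || cfg$drift_max_px > 0
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  scene <- simulate_scene(cfg)
  write_movie(scene$movie, p("movie.tif"))
  write_tiff(scene$red, p("red.tif"))
  write_ground_truth(scene, p("ground_truth.json"))
  write_geometry(scene$geometry, p("geometry.json"))

  prep <- preprocess_movie(scene$movie, register = register)
  events <- detect_events(prep$movie, prep$dff, scene$geometry, dcfg,
                          keep_rejected = TRUE)
  write_event_table(events, p("events.csv"))

  intensity <- profile_intensity(scene$red, scene$geometry)
  seg <- segment_profile(intensity, cfg$pixel_size)
  write_profile(seg, p("profile.csv"))

  duration_h <- cfg$n_frames * cfg$frame_interval / 3600
  labelled <- assign_compartments(events, seg)
  freq <- frequency_report(labelled, seg, scene$geometry, duration_h)
  enr <- heminodal_enrichment(labelled, seg, duration_h)
  jsonlite::write_json(
    list(percent_myelination = seg$percent_myelination,
         axon_class = seg$axon_class,
         n_heminodes = nrow(seg$heminodes), n_nodes = nrow(seg$nodes),
         gap_threshold_fraction = seg$config$gap_threshold_fraction,
         counts = as.list(freq$counts), lengths = as.list(freq$lengths),
         freq_per_um_h = as.list(freq$freq),
         enrichment = enr[c("observed", "predicted", "ratio", "n_heminodes")]),
    p("hotspots.json"), auto_unbox = TRUE, digits = NA, na = "null")

  tc <- simulate_sheath_timecourse(cfg, scene$profile, scene$events)
  sheath_summary <- NULL
  if (!is.null(tc)) {
    utils::write.csv(tc, p("sheaths.csv"), row.names = FALSE)
    profile_t2 <- profile_after_timecourse(scene$profile, tc)
    mm <- match_sheaths(scene$profile, profile_t2,
                        scene$collateral_arcs, scene$collateral_arcs)
    fate <- nascent_fate_table(tc)
    gva <- growth_vs_heminodal_activity(tc)
    sheath_summary <- list(
      n_sheaths = nrow(tc), n_matched = nrow(mm$matched),
      n_retracted = length(mm$retracted), n_new = length(mm$new),
      fate_table = as.list(as.data.frame(fate$table)),
      fisher_p = fate$fisher_p,
      nascent_heminodal_r = gva$nascent$heminodal$r,
      nascent_heminodal_p = gva$nascent$heminodal$p)
    jsonlite::write_json(sheath_summary, p("sheath_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("vesiscope")),
         seed = cfg$seed, scene = unclass(cfg), detection = unclass(dcfg),
         registered = register,
         anterior_convention = "anterior = low arc position"),
    p("run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, config = cfg, detection = dcfg,
                 scene = scene, events = events, profile = seg,
                 frequency = freq, enrichment = enr, timecourse = tc,
                 sheath_summary = sheath_summary))
}
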