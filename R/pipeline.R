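#' Pipeline configuration
#'
#' One structured document describing a whole study run: simulation
#' conditions, preprocessing, inverse, spectral and robustness parameters.
#' Loadable from YAML with [read_pipeline_config()]; unknown keys are
#' flagged as warnings by [validate_config()], invalid values as errors.
#'
#' @param simulate a [sim_config()] (or list of its arguments).
#' @param preprocess list: `fs_target`, `low`, `high`, `order`, `discard`,
#'   `ssp_k`, `ssp_window`.
#' @param inverse list: `snr`.
#' @param spectral list: `window`, `overlap`, `epoch_start`,
#'   `epoch_duration`.
#' @param robustness list: `enabled`, `epoch_duration`, `n_epochs`.
#' @param out_dir output directory (`NULL` = nothing written).
#' @param seed root seed; overrides the simulate seed so one number
#'   reproduces the run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            preprocess = list(), inverse = list(),
                            spectral = list(), robustness = list(),
                            out_dir = NULL, seed = NULL) {
  if (!inherits(simulate, "sim_config"))
    simulate <- do.call(sim_config, simulate)
  cfg <- list(
    simulate = simulate,
    preprocess = utils::modifyList(
      list(fs_target = 250, low = 0.5, high = 47.5, order = 4,
           discard = 30, ssp_k = 1, ssp_window = 0.2), preprocess),
    inverse = utils::modifyList(list(snr = 3), inverse),
    spectral = utils::modifyList(
      list(window = 2, overlap = 0.5, epoch_start = 0, epoch_duration = 60),
      spectral),
    robustness = utils::modifyList(
      list(enabled = FALSE, epoch_duration = 30, n_epochs = 3), robustness),
    out_dir = out_dir, seed = seed)
  if (!is.null(seed)) cfg$simulate$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Omitted keys fall back to defaults (e.g. Welch overlap 0.5); unknown keys
#' are preserved so [validate_config()] can warn about them.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- c("simulate", "preprocess", "inverse", "spectral", "robustness",
             "out_dir", "seed")
  cfg <- do.call(pipeline_config, doc[intersect(names(doc), known)])
  attr(cfg, "unknown_keys") <- setdiff(names(doc), known)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against the preconditions of the stage consuming
#' it. Errors block execution; warnings (e.g. unknown keys) do not.
#'
#' @param config a [pipeline_config()].
#' @return data.frame with columns `level` ("error"/"warning") and
#'   `message`; zero rows when the config is clean.
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(level, msg)
    findings[[length(findings) + 1]] <<- data.frame(level = level, message = msg)
  pp <- config$preprocess
  sim <- config$simulate
  if (pp$high >= pp$fs_target / 2)
    add("error", sprintf("band-pass high edge (%g Hz) must be below Nyquist (%g Hz)",
                         pp$high, pp$fs_target / 2))
  if (pp$low <= 0 || pp$low >= pp$high)
    add("error", sprintf("need 0 < low < high (got %g, %g)", pp$low, pp$high))
  if (pp$fs_target > sim$fs)
    add("error", sprintf("fs_target (%g) exceeds simulated fs (%g): no upsampling",
                         pp$fs_target, sim$fs))
  if (pp$ssp_k < 0) add("error", "ssp_k must be >= 0")
  sp <- config$spectral
  if (sp$overlap < 0 || sp$overlap >= 1)
    add("error", sprintf("overlap must be in [0,1) (got %g)", sp$overlap))
  post <- sim$duration - pp$discard
  if (post < sp$epoch_start + sp$epoch_duration)
    add("error", sprintf("epoch [%g,%g] s does not fit the %g s post-discard recording",
                         sp$epoch_start, sp$epoch_start + sp$epoch_duration, post))
  if (isTRUE(config$robustness$enabled) &&
      config$robustness$n_epochs * config$robustness$epoch_duration > post)
    add("error", sprintf("robustness plan (%d x %g s) exceeds %g s post-discard",
                         config$robustness$n_epochs,
                         config$robustness$epoch_duration, post))
  if (config$inverse$snr <= 0) add("error", "inverse snr must be > 0")
  err <- tryCatch({ validate_sim_config(sim); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(err)) add("error", err)
  for (k in attr(config, "unknown_keys") %||% character())
    add("warning", sprintf("unknown configuration key '%s' ignored", k))
  if (!length(findings))
    return(data.frame(level = character(), message = character()))
  do.call(rbind, findings)
}

# one subject through the sensor-to-map chain
process_subject <- function(rec, config, inv, leadfield, parcellation,
                            subject_id) {
  pp <- config$preprocess
  if (pp$fs_target < rec$fs) rec <- resample_recording(rec, pp$fs_target)
  rec <- bandpass_recording(rec, pp$low, pp$high, pp$order)
  rec <- common_average_reference(rec)
  n_proj <- 0L
  if (pp$ssp_k > 0 && any(rec$channel_types == "ECG")) {
    ev <- detect_heartbeats(rec)
    if (length(ev$times) >= 5) {
      proj <- fit_ssp(rec, ev, window = pp$ssp_window, k = pp$ssp_k)
      rec <- apply_ssp(rec, proj)
      n_proj <- ncol(proj$components)
    }
  }
  rec <- discard_settle(rec, pp$discard)
  src <- apply_inverse(rec, inv)
  ts <- roi_average(src, leadfield, parcellation)
  sp <- config$spectral
  map <- bandpower_map(ts, config$simulate$scheme,
                       epoch_start = sp$epoch_start,
                       epoch_duration = sp$epoch_duration,
                       window = sp$window, overlap = sp$overlap,
                       subject_id = subject_id)
  list(map = map, ts = ts, n_projected = n_proj)
}

#' Run the full synthetic study pipeline
#'
#' Simulate the cohorts, preprocess every recording (band-pass, common
#' average reference, ECG-guided SSP, settling discard), source-localise
#' (sLORETA + sign-flip ROI averaging), compute relative band-power maps,
#' build the normative map from the healthy cohort, optionally assess epoch
#' robustness and left-right symmetry, z-score every patient and lateralise
#' temporal-lobe abnormality. Deterministic given the seed. All tabular
#' artifacts are written to `config$out_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @return a run manifest (class `run_manifest`): config snapshot, seeds,
#'   package version, stage timings, output files, result checksums, and the
#'   in-memory `$results` (normative map, reports, lateralisation).
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  if (any(findings$level == "error"))
    stop_named("invalid configuration: %s",
               paste(findings$message[findings$level == "error"],
                     collapse = "; "))
  t_start <- Sys.time()
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, name) timings[name] <<- as.numeric(Sys.time() - t0, units = "secs")

  t0 <- tic()
  sim <- simulate_cohorts(config$simulate)
  toc(t0, "simulate")

  inv <- make_inverse(sim$leadfield, snr = config$inverse$snr)

  t0 <- tic()
  healthy <- lapply(seq_along(sim$healthy), function(i)
    process_subject(sim$healthy[[i]]$recording, config, inv, sim$leadfield,
                    sim$parcellation, sprintf("healthy_%02d", i)))
  patients <- lapply(seq_along(sim$patients), function(i)
    process_subject(sim$patients[[i]]$recording, config, inv, sim$leadfield,
                    sim$parcellation, sprintf("patient_%02d", i)))
  toc(t0, "process")

  t0 <- tic()
  healthy_maps <- lapply(healthy, `[[`, "map")
  norm <- build_normative_map(
    healthy_maps,
    provenance = sprintf("%d healthy subjects, %g s epoch, Welch %g s/%g%%",
                         length(healthy_maps),
                         config$spectral$epoch_duration,
                         config$spectral$window,
                         100 * config$spectral$overlap))
  sym <- lr_symmetry(norm, sim$parcellation)
  robust <- NULL
  if (isTRUE(config$robustness$enabled))
    robust <- epoch_robustness(lapply(healthy, `[[`, "ts"),
                               config$simulate$scheme,
                               config$robustness$epoch_duration,
                               config$robustness$n_epochs,
                               config$spectral$window, config$spectral$overlap)
  toc(t0, "normative")

  t0 <- tic()
  ab_maps <- lapply(patients, function(p) zscore_map(p$map, norm))
  lat <- lateralize(ab_maps, sim$truth$patient_sides, sim$parcellation)
  toc(t0, "abnormality")

  outputs <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- function(name) file.path(config$out_dir, name)
    write_parcellation(sim$parcellation, f("parcellation.tsv"))
    write_normative_map(norm, f("normative_map.tsv"))
    write_bandpower_maps(healthy_maps, f("bandpower_healthy.tsv"))
    write_bandpower_maps(lapply(patients, `[[`, "map"), f("bandpower_patients.tsv"))
    write_abnormality(ab_maps, f("abnormality.tsv"))
    utils::write.table(lat$table, f("lateralization.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_ground_truth(sim$truth, f("ground_truth.json"))
    reports <- list(symmetry = list(rho_lr = sym$rho_lr,
                                    n_pairs = sym$n_pairs_used,
                                    excluded = sym$excluded_rois))
    if (!is.null(robust))
      reports$robustness <- list(rho_mean = robust$rho_mean,
                                 rho_sd = robust$rho_sd)
    jsonlite::write_json(reports, f("reports.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    outputs <- list.files(config$out_dir)
  }

  results <- list(normative = norm, symmetry = sym, robustness = robust,
                  lateralization = lat, truth = sim$truth,
                  parcellation = sim$parcellation,
                  healthy_maps = healthy_maps,
                  patient_maps = lapply(patients, `[[`, "map"),
                  abnormality = ab_maps)
  manifest <- list(
    package_version = as.character(utils::packageVersion("eegnorm")),
    seed = config$simulate$seed,
    config = config[c("preprocess", "inverse", "spectral", "robustness")],
    sim_config = unclass(config$simulate)[setdiff(names(config$simulate), "scheme")],
    checksums = list(
      normative = object_checksum(norm),
      lateralization = object_checksum(lat$table),
      abnormality = object_checksum(lapply(ab_maps, `[[`, "z"))),
    outputs = outputs,
    timings = timings,
    total_seconds = as.numeric(Sys.time() - t_start, units = "secs"))
  structure(c(manifest, list(results = results)), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> eegnorm %s, seed %d, %.1f s total\n",
              x$package_version, x$seed, x$total_seconds))
  cat("  checksums:", paste(names(x$checksums), unlist(x$checksums),
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Strip volatile fields from a manifest for determinism comparison
#'
#' @param manifest a [run_pipeline()] manifest.
#' @return the manifest minus timings and in-memory results.
#' @export
manifest_fingerprint <- function(manifest) {
  m <- unclass(manifest)
  m$timings <- NULL
  m$total_seconds <- NULL
  m$results <- NULL
  m
}
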