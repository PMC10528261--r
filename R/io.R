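# Serialization: data-cube containers, image and report files, run
# configurations. Cubes use an R-native .rds container holding the
# same named members an HDF5 layout would (data, fast_time_s,
# slow_time_s, channel_tx, channel_rx, attributes); small cubes are
# also exportable as long-format CSV with a JSON metadata sidecar.

#' Save a radar data cube
#'
#' `.rds` gives a lossless round trip of the tensor and all axis and
#' attribute metadata. `.csv` writes the long format (columns
#' `fast_time_s, slow_time_s, channel, value`, one row per tensor
#' element) with a `.json` metadata sidecar; intended for small cubes.
#'
#' @param cube an `mw_cube`.
#' @param path output path ending in `.rds` or `.csv`.
#' @return `path`, invisibly.
#' @export
save_cube <- function(cube, path) {
  stopifnot(inherits(cube, "mw_cube"))
  if (grepl("\\.rds$", path)) {
    saveRDS(unclass(cube), path)
  } else if (grepl("\\.csv$", path)) {
    d <- dim(cube$data)
    df <- data.frame(
      fast_time_s = rep(cube$fast_time_s, times = d[2] * d[3]),
      slow_time_s = rep(rep(cube$slow_time_s, each = d[1]), times = d[3]),
      channel = rep(seq_len(d[3]), each = d[1] * d[2]),
      value = as.vector(cube$data))
    utils::write.csv(df, path, row.names = FALSE)
    meta <- cube$meta
    meta$channel_tx <- cube$channel_tx
    meta$channel_rx <- cube$channel_rx
    meta$dims <- d
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else stop("unsupported cube format (use .rds or .csv)")
  invisible(path)
}

#' Load a radar data cube saved by [save_cube()]
#'
#' @param path `.rds` path.
#' @return an `mw_cube`.
#' @export
load_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!grepl("\\.rds$", path)) stop("load_cube reads the .rds container")
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt or truncated cube file: ",
                                           conditionMessage(e)))
  need <- c("data", "fast_time_s", "slow_time_s", "channel_tx",
            "channel_rx", "meta")
  if (!is.list(obj) || !all(need %in% names(obj)))
    stop("cube file missing required members: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  radar_data_cube(obj$data, obj$fast_time_s, obj$slow_time_s,
                  obj$channel_tx, obj$channel_rx, obj$meta)
}

#' Save / load a reconstructed image
#'
#' `.rds` for lossless round trips; `.csv` writes the value grid in
#' long format (`ax1_m, ax2_m, value`); `.png` writes a preview.
#'
#' @param image an `mw_image`.
#' @param path output path (`.rds`, `.csv`, or `.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "mw_image"))
  if (grepl("\\.rds$", path)) {
    saveRDS(unclass(image), path)
  } else if (grepl("\\.csv$", path)) {
    df <- data.frame(ax1_m = rep(image$ax1, times = length(image$ax2)),
                     ax2_m = rep(image$ax2, each = length(image$ax1)),
                     value = as.vector(image$values))
    utils::write.csv(df, path, row.names = FALSE)
  } else if (grepl("\\.png$", path)) {
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    graphics::image(image$ax1, image$ax2, image$values,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "x (m)",
                    ylab = if (image$plane == "lateral") "y (m)" else "z (m)",
                    main = sprintf("%s plane at %.2f cm", image$plane,
                                   100 * image$at), asp = 1)
  } else stop("unsupported image format (use .rds, .csv or .png)")
  invisible(path)
}

#' @rdname save_image
#' @export
load_image <- function(path) {
  obj <- readRDS(path)
  class(obj) <- "mw_image"
  obj
}

# 32-bit FNV-1a hash of a string, as 8 hex digits (config fingerprint)
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a double mod 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # h * 16777619 mod 2^32 without integer overflow: 16-bit split
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Run configuration: defaults, validation, loading
#'
#' A run configuration describes an end-to-end experiment: the
#' scenario, the acquisition (fast/slow sampling, observation time,
#' noise, seed), the beamformer (mode, gating window, voxel size,
#' plane, pulsation frequency) and the evaluation thresholds.
#' Boundary units follow the field's prose (cm, mm, Hz); everything is
#' converted to metres/seconds internally. A seed is mandatory.
#'
#' @param scenario scenario id 1..6.
#' @param seed RNG seed (required).
#' @param fs_hz,mseq_order,slow_rate_hz,duration_s,snr_db acquisition.
#' @param fp_hz pulsation frequency to image at.
#' @param mode `"coherent"` or `"incoherent"`.
#' @param window_samples gating window length.
#' @param voxel_mm voxel edge, millimetres.
#' @param plane `"lateral"` or `"longitudinal"`.
#' @param plane_cm fixed plane coordinate, centimetres.
#' @param tolerance_mm detection match radius, millimetres.
#' @param min_prominence detection prominence fraction.
#' @param postfilter apply the adaptive post-filter to saved images.
#' @return validated config list of class `mw_config`.
#' @export
run_config <- function(scenario = 1, seed = NULL, fs_hz = 13e9,
                       mseq_order = 9, slow_rate_hz = 0.8,
                       duration_s = 125, snr_db = Inf, fp_hz = 0.08,
                       mode = "coherent", window_samples = 4,
                       voxel_mm = 2, plane = "lateral", plane_cm = -5,
                       tolerance_mm = 10, min_prominence = 0.1,
                       postfilter = TRUE, n_tx = 16, n_rx = 16,
                       scatterer_dz_mm = 5, clutter = TRUE) {
  cfg <- list(scenario = scenario, seed = seed, fs_hz = fs_hz,
              mseq_order = mseq_order, slow_rate_hz = slow_rate_hz,
              duration_s = duration_s, snr_db = snr_db, fp_hz = fp_hz,
              mode = mode, window_samples = window_samples,
              voxel_mm = voxel_mm, plane = plane, plane_cm = plane_cm,
              tolerance_mm = tolerance_mm,
              min_prominence = min_prominence,
              postfilter = isTRUE(postfilter),
              n_tx = n_tx, n_rx = n_rx,
              scatterer_dz_mm = scatterer_dz_mm,
              clutter = isTRUE(clutter))
  validate_config(cfg)
}

#' @rdname run_config
#' @param cfg a config list to validate.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("config validation: a numeric seed is required")
  for (f in c("fs_hz", "slow_rate_hz", "duration_s", "fp_hz",
              "window_samples", "voxel_mm", "tolerance_mm"))
    if (is.null(cfg[[f]]) || !is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config validation: ", f, " must be a positive number")
  n_slow <- cfg$duration_s * cfg$slow_rate_hz
  if (abs(n_slow - round(n_slow)) > 1e-9)
    stop("config validation: duration_s * slow_rate_hz must be an integer")
  if (!cfg$mode %in% c("coherent", "incoherent"))
    stop("config validation: unknown beamformer mode")
  if (!cfg$plane %in% c("lateral", "longitudinal"))
    stop("config validation: unknown plane")
  structure(cfg, class = "mw_config")
}

#' @rdname run_config
#' @param path JSON config file path.
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- formals(run_config)
  cfg <- lapply(defaults, function(x) if (is.call(x)) eval(x) else x)
  cfg$seed <- NULL
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  validate_config(cfg)
}

#' Fingerprint of a run configuration
#'
#' FNV-1a hash of the canonical config JSON; embedded in every pipeline
#' output file so artifacts can be traced to the exact configuration.
#'
#' @param cfg an `mw_config`.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  .fnv1a(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                       digits = NA)))
}
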