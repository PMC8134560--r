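#' Analysis configuration
#'
#' Collects every tunable threshold of the activation-mapping and network
#' stages in one validated object that round-trips losslessly through JSON.
#'
#' @param p_voxel Voxel-wise two-sided p-value threshold (default 0.001).
#' @param fwe_alpha Cluster-extent family-wise error rate (default 0.05).
#' @param sd_fraction Voxels whose temporal SD exceeds this fraction of
#'   their temporal mean are excluded (default 0.08, the 8 percent rule).
#' @param smooth_fwhm_mm Isotropic Gaussian smoothing FWHM in mm
#'   (default 4; 0 disables smoothing).
#' @param corr_threshold Threshold theta on `|C_ij|` for voxel-network
#'   links, in (0, 1] (default 0.6).
#' @param common_retention Fraction tau of subjects a link must appear in to
#'   enter the common network, in (0, 1] (default 1, i.e. all subjects).
#' @param n_bins Number of normalized-shell occupancy bins (default 15).
#' @param hrf_peak_s,hrf_sd_s Gaussian hemodynamic kernel parameters in
#'   seconds (defaults 5 and 2.5).
#' @param n_null Number of circular-shift surrogates for the cluster-extent
#'   null (default 1000; below 100 a warning is emitted).
#' @param connectivity Voxel neighborhood for clustering: 6 (faces), 18
#'   (faces + edges) or 26 (full cube). Default 6.
#' @param detrend Remove a per-voxel linear trend before statistics and
#'   correlations (default `TRUE`).
#' @param seed Optional integer seed recorded with the configuration and
#'   used by [run_pipeline()].
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(p_voxel = 0.001, fwe_alpha = 0.05,
                            sd_fraction = 0.08, smooth_fwhm_mm = 4,
                            corr_threshold = 0.6, common_retention = 1,
                            n_bins = 15, hrf_peak_s = 5, hrf_sd_s = 2.5,
                            n_null = 1000, connectivity = 6,
                            detrend = TRUE, seed = NULL) {
  in_open01 <- function(x) is.finite(x) && x > 0 && x < 1
  if (!in_open01(p_voxel)) stop("`p_voxel` must be in (0, 1)")
  if (!in_open01(fwe_alpha)) stop("`fwe_alpha` must be in (0, 1)")
  if (!is.finite(sd_fraction) || sd_fraction <= 0)
    stop("`sd_fraction` must be > 0")
  if (!is.finite(smooth_fwhm_mm) || smooth_fwhm_mm < 0)
    stop("`smooth_fwhm_mm` must be >= 0")
  if (!is.finite(corr_threshold) || corr_threshold <= 0 || corr_threshold > 1)
    stop("`corr_threshold` must be in (0, 1]")
  if (!is.finite(common_retention) || common_retention <= 0 ||
      common_retention > 1)
    stop("`common_retention` must be in (0, 1]")
  if (!is.finite(n_bins) || n_bins < 1 || n_bins != round(n_bins))
    stop("`n_bins` must be a positive integer")
  if (!is.finite(hrf_peak_s) || hrf_peak_s <= 0) stop("`hrf_peak_s` must be > 0")
  if (!is.finite(hrf_sd_s) || hrf_sd_s <= 0) stop("`hrf_sd_s` must be > 0")
  if (!is.finite(n_null) || n_null < 1 || n_null != round(n_null))
    stop("`n_null` must be a positive integer")
  if (!connectivity %in% c(6, 18, 26))
    stop("`connectivity` must be one of 6, 18, 26")
  if (!is.null(seed)) {
    if (!is.finite(seed) || seed != round(seed)) stop("`seed` must be an integer")
    seed <- as.integer(seed)
  }
  structure(list(p_voxel = as.numeric(p_voxel),
                 fwe_alpha = as.numeric(fwe_alpha),
                 sd_fraction = as.numeric(sd_fraction),
                 smooth_fwhm_mm = as.numeric(smooth_fwhm_mm),
                 corr_threshold = as.numeric(corr_threshold),
                 common_retention = as.numeric(common_retention),
                 n_bins = as.integer(n_bins),
                 hrf_peak_s = as.numeric(hrf_peak_s),
                 hrf_sd_s = as.numeric(hrf_sd_s), n_null = as.integer(n_null),
                 connectivity = as.integer(connectivity),
                 detrend = isTRUE(detrend), seed = seed),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-16s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Write / read an analysis configuration as JSON
#'
#' @param cfg An [analysis_config()].
#' @param path File path.
#' @return `read_analysis_config` returns an `analysis_config`;
#'   `write_analysis_config` returns `path` invisibly.
#' @export
write_analysis_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; stamped on every output table so
#' results produced under different thresholds are never mixed silently.
#'
#' @param cfg An `analysis_config` (or any serializable list).
#' @return A character MD5 digest.
#' @export
config_hash <- function(cfg) {
  # canonicalize through a JSON round trip so that equivalent
  # representations (integer vs double, list vs named vector) hash equal
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         null = "null")
  js <- jsonlite::toJSON(jsonlite::fromJSON(js, simplifyVector = TRUE),
                         auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(as.character(js), tf, eos = NULL)
  unname(tools::md5sum(tf))
}
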