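#' Hydrographic analysis parameters
#'
#' Parameter bundle for mixed-layer depth, light-depth, deep-chlorophyll-
#' maximum detection and stability-period classification.
#'
#' @param delta_sigma Density offset (kg m^-3) above the surface sigma-t that
#'   defines the mixed-layer depth. Default 0.125.
#' @param dcm_fraction Fractional drop from the fluorescence maximum that
#'   bounds the DCM region; the region is the contiguous depth interval where
#'   fluorescence >= (1 - dcm_fraction) times the maximum. Default 0.35.
#' @param euphotic_par_fraction Fraction of surface PAR defining the euphotic
#'   zone depth. Default 0.001 (0.1 percent).
#' @param comparison_par_fraction Fraction of surface PAR defining the
#'   irradiance level used as the deep-mixing-period analogue of the DCM.
#'   Default 0.01 (1 percent).
#' @param st_mld_threshold_m Mixed-layer depth (m) at or above which the
#'   spring transition begins once deep mixing has ended. Default 100.
#' @param smoothing_window Odd number of consecutive profiles over which the
#'   MLD is median-smoothed before classification; 1 disables smoothing
#'   (default).
#' @param zone_tolerance_m Half-width (m) of the depth band around the 1
#'   percent light level used for zone assignment during deep mixing.
#'   Default 10.
#' @param surface_max_depth_m Maximum depth (m) of the surface zone.
#'   Default 5.
#'
#' @return A list of class `hydro_params`.
#' @export
#' @examples
#' p <- hydro_params()
#' p$delta_sigma
hydro_params <- function(delta_sigma = 0.125,
                         dcm_fraction = 0.35,
                         euphotic_par_fraction = 0.001,
                         comparison_par_fraction = 0.01,
                         st_mld_threshold_m = 100,
                         smoothing_window = 1,
                         zone_tolerance_m = 10,
                         surface_max_depth_m = 5) {
  stopifnot(
    delta_sigma > 0,
    dcm_fraction > 0, dcm_fraction < 1,
    euphotic_par_fraction > 0,
    comparison_par_fraction > euphotic_par_fraction,
    comparison_par_fraction < 1,
    st_mld_threshold_m > 0,
    smoothing_window >= 1, smoothing_window %% 2 == 1,
    zone_tolerance_m > 0,
    surface_max_depth_m > 0
  )
  structure(
    list(
      delta_sigma = delta_sigma,
      dcm_fraction = dcm_fraction,
      euphotic_par_fraction = euphotic_par_fraction,
      comparison_par_fraction = comparison_par_fraction,
      st_mld_threshold_m = st_mld_threshold_m,
      smoothing_window = smoothing_window,
      zone_tolerance_m = zone_tolerance_m,
      surface_max_depth_m = surface_max_depth_m
    ),
    class = "hydro_params"
  )
}

#' Community analysis parameters
#'
#' @param slope_threshold Rarefaction endpoint slope below which a sample is
#'   considered saturated and kept. Default 0.1.
#' @param min_plastid_reads Minimum plastid amplicon count below which a
#'   sample is flagged (not removed) for plastid-denominator analyses.
#'   Default 50.
#' @param quantile Percentile (as a fraction) used for the chlorophyll /
#'   prasinophyte quadrant thresholds. Default 0.75.
#' @param max_depth_m Maximum sample depth (m) entering quadrant and
#'   persistence analyses. Default 140.
#' @param surface_max_depth_m Maximum depth (m) of the surface zone.
#'   Default 5.
#' @param analysis_years Calendar years entering the persistence analysis.
#'   Default 2017:2019.
#' @param min_detection_reads Minimum read count for an ASV to count as
#'   detected in a sample for persistence. Default 1 (presence).
#' @param lod_nitrate,lod_phosphate Detection limits (umol kg^-1) below which
#'   nutrient values are reported as zero. Defaults 0.05 and 0.03.
#'
#' @return A list of class `community_params`.
#' @export
community_params <- function(slope_threshold = 0.1,
                             min_plastid_reads = 50,
                             quantile = 0.75,
                             max_depth_m = 140,
                             surface_max_depth_m = 5,
                             analysis_years = 2017:2019,
                             min_detection_reads = 1,
                             lod_nitrate = 0.05,
                             lod_phosphate = 0.03) {
  stopifnot(
    slope_threshold > 0,
    min_plastid_reads > 0,
    quantile > 0, quantile < 1,
    max_depth_m > 0,
    surface_max_depth_m > 0,
    min_detection_reads >= 1,
    lod_nitrate > 0, lod_phosphate > 0
  )
  structure(
    list(
      slope_threshold = slope_threshold,
      min_plastid_reads = min_plastid_reads,
      quantile = quantile,
      max_depth_m = max_depth_m,
      surface_max_depth_m = surface_max_depth_m,
      analysis_years = as.integer(analysis_years),
      min_detection_reads = min_detection_reads,
      lod_nitrate = lod_nitrate,
      lod_phosphate = lod_phosphate
    ),
    class = "community_params"
  )
}

#' Cross-marker linking parameters
#'
#' @param min_genus_reads Minimum genus-level amplicon count a sample must
#'   reach, in each marker, to enter a correlation. Default 10.
#' @param alpha Two-sided significance level for declaring a link. Default
#'   0.05.
#' @param min_samples Minimum number of qualifying samples for a correlation
#'   to be reported at all. Default 3.
#'
#' @return A list of class `link_params`.
#' @export
link_params <- function(min_genus_reads = 10,
                        alpha = 0.05,
                        min_samples = 3) {
  stopifnot(
    min_genus_reads >= 1,
    alpha > 0, alpha < 1,
    min_samples >= 3
  )
  structure(
    list(
      min_genus_reads = min_genus_reads,
      alpha = alpha,
      min_samples = min_samples
    ),
    class = "link_params"
  )
}
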