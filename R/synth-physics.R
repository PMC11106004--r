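#' Configuration for the synthetic water-column generator
#'
#' Describes one or more annual cycles at a subtropical time-series station:
#' a seasonal mixed-layer depth curve (deep winter convective mixing, rapid
#' spring shoaling, shallow stratified summer, autumn deepening), a Gaussian
#' deep chlorophyll maximum during stratified periods, exponential PAR
#' attenuation, and noise levels for each measured field. The planted
#' stability-period calendar is defined by four day-of-year transition
#' dates; the mixed-layer curve is an interpolated log-depth curve through
#' knots chosen to be consistent with that calendar (winter MLD deeper than
#' the euphotic zone, spring-transition MLD between the top of the DCM and
#' the transition threshold, summer MLD above the DCM, autumn MLD inside
#' the DCM).
#'
#' @param start,end ISO dates bounding the simulation (defaults one year).
#' @param profiles_per_month Casts per month (spread through the month).
#' @param process_cruise Optional list(month=, days=) adding a burst of
#'   daily casts in one month of every simulated year.
#' @param bottle_depths Depths (m) at which bottle samples are drawn
#'   (default 8 depths between 1 and 300 m).
#' @param ctd_depths Fine grid (m) for CTD fields (default 1..300 by 1).
#' @param st_onset_doy,ss_onset_doy,at_onset_doy,dm_onset_doy Day-of-year
#'   transition dates of the planted calendar.
#' @param mld_knots_doy,mld_knots_m Knots of the seasonal MLD curve
#'   (interpolated linearly in log depth).
#' @param sst_min_C,sst_max_C Seasonal sea-surface temperature range.
#' @param dcm_center_m,dcm_sd_m Center and Gaussian width of the DCM.
#' @param dcm_fluor_max,fluor_background,ml_fluor Fluorescence levels (RFU)
#'   of the DCM peak, the deep background, and the mixed layer during deep
#'   mixing.
#' @param par_surface Surface PAR (arbitrary units).
#' @param k_par Diffuse attenuation coefficient (m^-1); 0.046 puts the 1
#'   percent light level near 100 m and the euphotic (0.1 percent) depth
#'   near 150 m.
#' @param sigma_jump Density step (kg m^-3) at the base of the mixed layer;
#'   slightly above the 0.125 MLD criterion so the threshold crossing lands
#'   at the planted MLD within one grid step.
#' @param sigma_gradient Pycnocline sigma-t gradient (kg m^-3 per m).
#' @param sigma_t_noise,fluor_noise_frac,par_noise_frac,mld_jitter_sd Noise:
#'   additive sigma-t sd (kg m^-3, CTD precision scale), multiplicative
#'   fluorescence and PAR fractional sds, and the sd (m) of cast-to-cast MLD
#'   displacement around the seasonal curve. Defaults are calibrated so the
#'   planted stability calendar is perturbed but not erased: the spring
#'   transition occupies a ~15 m MLD band, so its displacement sd (2 m)
#'   keeps transition casts several sd away from the classification
#'   thresholds while still exercising every noise path.
#'
#' @return A list of class `physics_config`.
#' @export
physics_config <- function(start = "2017-01-01",
                           end = "2017-12-31",
                           profiles_per_month = 1,
                           process_cruise = NULL,
                           bottle_depths = c(1, 5, 20, 60, 100, 140, 200, 300),
                           ctd_depths = seq(1, 300, by = 1),
                           st_onset_doy = 100,
                           ss_onset_doy = 130,
                           at_onset_doy = 300,
                           dm_onset_doy = 350,
                           mld_knots_doy = c(1, 45, 95, 100, 129, 130, 169,
                                             250, 295, 300, 349, 350, 365),
                           mld_knots_m = c(230, 250, 170, 92, 86, 55, 20,
                                           20, 70, 100, 128, 165, 225),
                           sst_min_C = 20.5,
                           sst_max_C = 27.3,
                           dcm_center_m = 100,
                           dcm_sd_m = 20,
                           dcm_fluor_max = 1.0,
                           fluor_background = 0.02,
                           ml_fluor = 0.3,
                           par_surface = 1500,
                           k_par = 0.046,
                           sigma_jump = 0.13,
                           sigma_gradient = 0.008,
                           sigma_t_noise = 0.003,
                           fluor_noise_frac = 0.05,
                           par_noise_frac = 0.02,
                           mld_jitter_sd = 2) {
  euphotic <- log(1000) / k_par
  stopifnot(
    profiles_per_month >= 1,
    length(mld_knots_doy) == length(mld_knots_m),
    st_onset_doy < ss_onset_doy, ss_onset_doy < at_onset_doy,
    at_onset_doy < dm_onset_doy,
    max(mld_knots_m) > euphotic, # winter mixing exceeds the euphotic depth
    dcm_center_m > min(ctd_depths), dcm_center_m < max(ctd_depths),
    sigma_jump > 0.125, sigma_gradient > 0,
    sigma_t_noise >= 0, fluor_noise_frac >= 0, par_noise_frac >= 0,
    mld_jitter_sd >= 0
  )
  structure(as.list(environment())[c(
    "start", "end", "profiles_per_month", "process_cruise",
    "bottle_depths", "ctd_depths",
    "st_onset_doy", "ss_onset_doy", "at_onset_doy", "dm_onset_doy",
    "mld_knots_doy", "mld_knots_m", "sst_min_C", "sst_max_C",
    "dcm_center_m", "dcm_sd_m", "dcm_fluor_max", "fluor_background",
    "ml_fluor", "par_surface", "k_par", "sigma_jump", "sigma_gradient",
    "sigma_t_noise", "fluor_noise_frac", "par_noise_frac", "mld_jitter_sd"
  )], class = "physics_config")
}

#' Zero-noise variant of a physics configuration
#'
#' @param config A [physics_config()].
#' @return The same configuration with every noise level set to 0.
#' @export
noiseless <- function(config) {
  config$sigma_t_noise <- 0
  config$fluor_noise_frac <- 0
  config$par_noise_frac <- 0
  config$mld_jitter_sd <- 0
  config
}

planted_period_for_doy <- function(doy, config) {
  ifelse(doy < config$st_onset_doy | doy >= config$dm_onset_doy, "DM",
    ifelse(doy < config$ss_onset_doy, "ST",
      ifelse(doy < config$at_onset_doy, "SS", "AT")
    )
  )
}

seasonal_mld <- function(doy, config) {
  exp(approx(config$mld_knots_doy, log(config$mld_knots_m),
             xout = doy, rule = 2)$y)
}

seasonal_sst <- function(doy, config) {
  mid <- (config$sst_max_C + config$sst_min_C) / 2
  amp <- (config$sst_max_C - config$sst_min_C) / 2
  mid + amp * cos(2 * pi * (doy - 232) / 365) # warmest ~late August
}

profile_dates <- function(config) {
  start <- as.Date(config$start)
  end <- as.Date(config$end)
  months <- seq(as.Date(format(start, "%Y-%m-01")), end, by = "month")
  k <- config$profiles_per_month
  days <- floor(28 * (seq_len(k) - 0.5) / k) + 1
  dates <- as.Date(unlist(lapply(months, function(m) {
    as.character(m + days - 1)
  })))
  if (!is.null(config$process_cruise)) {
    pc <- config$process_cruise
    yrs <- unique(format(months, "%Y"))
    extra <- as.Date(unlist(lapply(yrs, function(y) {
      as.character(as.Date(sprintf("%s-%02d-01", y, pc$month)) +
                     seq_len(pc$days) - 1)
    })))
    dates <- c(dates, extra)
  }
  sort(unique(dates[dates >= start & dates <= end]))
}

#' Simulate CTD profiles with a planted stability calendar
#'
#' Emits a fine-grid CTD table for every cast date and the ground truth it
#' was generated from. Sigma-t is uniform at the seasonal surface value
#' above the planted mixed-layer depth with a density step and pycnocline
#' gradient below, so the 0.125 kg m^-3 threshold crossing recovers the
#' planted MLD within one grid step. Fluorescence carries a Gaussian DCM
#' during stratified planted periods and an elevated uniform mixed-layer
#' signal during deep mixing. PAR decays exponentially. Noise (additive
#' sigma-t, multiplicative fluorescence/PAR, MLD displacement) is applied on
#' top; the truth records the noiseless planted values.
#'
#' @param config A [physics_config()].
#' @param seed Integer seed.
#'
#' @return A list with `ctd` (long tibble: profile_id, timestamp, depth_m,
#'   temp_C, salinity, sigma_t, fluor_rfu, par) and `truth` (one row per
#'   profile: planted period, MLD, DCM bounds, light depths).
#' @export
simulate_physics <- function(config = physics_config(), seed = 1) {
  set.seed(seed)
  dates <- profile_dates(config)
  zeu <- log(1 / 0.001) / config$k_par
  z1pct <- log(1 / 0.01) / config$k_par
  # closed-form half-width of the 65%-of-max Gaussian region
  half <- config$dcm_sd_m * sqrt(2 * log(1 / 0.65))

  z <- config$ctd_depths
  ctd <- vector("list", length(dates))
  truth <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    date <- dates[i]
    doy <- as.integer(format(date, "%j"))
    pid <- sprintf("P%03d", i)
    period <- planted_period_for_doy(doy, config)
    mld_true <- seasonal_mld(doy, config)
    mld_real <- max(5, mld_true + rnorm(1, 0, config$mld_jitter_sd))
    sst <- seasonal_sst(doy, config)
    sigma0 <- 26.4 - 0.28 * (sst - 20)

    sigma <- ifelse(
      z <= mld_real, sigma0,
      sigma0 + config$sigma_jump + (z - mld_real) * config$sigma_gradient
    ) + rnorm(length(z), 0, config$sigma_t_noise)
    temp <- ifelse(z <= mld_real, sst,
                   18 + (sst - 18) * exp(-(z - mld_real) / 60)) +
      rnorm(length(z), 0, 0.01)
    sal <- 36.6 + rnorm(length(z), 0, 0.01)

    fluor_clean <- if (period == "DM") {
      ifelse(z <= mld_real,
             config$ml_fluor,
             config$fluor_background +
               (config$ml_fluor - config$fluor_background) *
                 exp(-(z - mld_real) / 20))
    } else {
      config$fluor_background + config$dcm_fluor_max *
        exp(-(z - config$dcm_center_m)^2 / (2 * config$dcm_sd_m^2))
    }
    fluor <- pmax(0, fluor_clean *
                    (1 + rnorm(length(z), 0, config$fluor_noise_frac)))
    par <- config$par_surface * exp(-config$k_par * z) *
      exp(rnorm(length(z), 0, config$par_noise_frac))

    ts <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC")
    ctd[[i]] <- tibble(
      profile_id = pid, timestamp = ts, depth_m = z,
      temp_C = temp, salinity = sal, sigma_t = sigma,
      fluor_rfu = fluor, par = par
    )
    stratified <- period != "DM"
    truth[[i]] <- tibble(
      profile_id = pid, timestamp = ts, doy = doy, period = period,
      mld_m = mld_true,
      euphotic_depth_m = zeu, light1pct_depth_m = z1pct,
      dcm_center_m = if (stratified) config$dcm_center_m else NA_real_,
      dcm_upper_m = if (stratified) config$dcm_center_m - half else NA_real_,
      dcm_lower_m = if (stratified) config$dcm_center_m + half else NA_real_
    )
  }
  list(ctd = bind_rows(ctd), truth = bind_rows(truth))
}
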