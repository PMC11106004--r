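PERIOD_LEVELS <- c("DM", "ST", "SS", "AT")
ZONE_LEVELS <- c("surface", "dcm", "light1pct", "ml", "below_euphotic", "other")

#' Classify water-column stability periods
#'
#' Runs a state machine over time-ordered per-profile features to label each
#' cast with one of four annual stability periods: deep mixing (DM, mixed
#' layer deeper than the euphotic zone), spring transition (ST, mixed layer
#' shoaled to the transition threshold), stratified summer (SS, mixed layer
#' above the top of the DCM region), and autumn transition (AT, first
#' entrainment of the DCM into the deepening mixed layer). The DM trigger has
#' precedence from any state, so renewed deep mixing always re-enters DM.
#' Within one observation, transitions are applied to a fixed point so the
#' labelling is idempotent under repeated observations of the same cast.
#' Labels persist between observations until a transition fires; casts
#' lacking the features a transition needs simply carry the previous label.
#'
#' @param features Tibble from [profile_features()], time-ordered (it is
#'   re-sorted by `timestamp` defensively).
#' @param params A [hydro_params()] bundle; `st_mld_threshold_m` and
#'   `smoothing_window` are used here.
#'
#' @return A tibble (`profile_id`, `timestamp`, `period`, `trigger`) of class
#'   `picocycle_timeline`. `trigger` names the rule that fired ("carried"
#'   when the previous label persisted).
#' @export
classify_stability_periods <- function(features, params = hydro_params()) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  features <- arrange(features, .data$timestamp)
  mld <- features$mld_m
  if (params$smoothing_window > 1 && length(mld) >= params$smoothing_window) {
    mld <- stats::runmed(mld, params$smoothing_window, endrule = "keep")
  }
  zeu <- features$euphotic_depth_m
  upper <- features$dcm_upper_m

  n <- nrow(features)
  period <- character(n)
  trigger <- character(n)
  state <- NA_character_

  dm_trig <- function(i) {
    !is.na(mld[i]) && !is.na(zeu[i]) && mld[i] > zeu[i]
  }
  st_trig <- function(i) {
    !is.na(mld[i]) && mld[i] <= params$st_mld_threshold_m
  }
  ss_trig <- function(i) {
    !is.na(mld[i]) && !is.na(upper[i]) && mld[i] < upper[i]
  }
  at_trig <- function(i) {
    !is.na(mld[i]) && !is.na(upper[i]) && mld[i] >= upper[i]
  }

  for (i in seq_len(n)) {
    trg <- "carried"
    if (is.na(state)) {
      # seed the first classifiable profile: DM > SS > ST fallback
      if (dm_trig(i)) {
        state <- "DM"; trg <- "seed: MLD > euphotic depth"
      } else if (!is.na(mld[i]) && !is.na(upper[i]) && ss_trig(i)) {
        state <- "SS"; trg <- "seed: MLD < DCM upper bound"
      } else if (!is.na(mld[i])) {
        state <- "ST"; trg <- "seed: fallback"
      }
      period[i] <- state %||% NA_character_
      trigger[i] <- if (is.na(state)) "unclassifiable" else trg
      next
    }
    # iterate transitions to a fixed point (at most one pass per state)
    repeat {
      if (state != "DM" && dm_trig(i)) {
        state <- "DM"; trg <- "MLD > euphotic depth"
        next
      }
      if (state == "DM" && !dm_trig(i) && st_trig(i)) {
        state <- "ST"; trg <- "MLD <= ST threshold"
        next
      }
      if (state == "ST" && ss_trig(i)) {
        state <- "SS"; trg <- "MLD < DCM upper bound"
        next
      }
      if (state == "SS" && !dm_trig(i) && at_trig(i)) {
        state <- "AT"; trg <- "DCM entrainment (MLD >= DCM upper bound)"
        next
      }
      break
    }
    period[i] <- state
    trigger[i] <- trg
  }

  if (all(is.na(period) | period == "")) {
    abort("No profile satisfies any stability-period trigger.",
          class = "picocycle_unclassified_timeline")
  }
  out <- tibble(
    profile_id = features$profile_id,
    timestamp = features$timestamp,
    period = factor(period, levels = PERIOD_LEVELS),
    trigger = trigger
  )
  class(out) <- c("picocycle_timeline", class(out))
  out
}

#' Assign a vertical zone to sampled depths
#'
#' Vectorized zone rule, evaluated in fixed precedence order (first match
#' wins): `surface` for depths at or above the surface cutoff; `dcm` for
#' depths inside the DCM region on stratified-period casts (ST/SS/AT with a
#' detected DCM above the mixed layer); `light1pct` for depths within the
#' tolerance band around the 1 percent light level on deep-mixing casts;
#' `ml` inside the mixed layer; `below_euphotic` beneath the euphotic-zone
#' depth; `other` otherwise. A rule whose feature is missing is skipped.
#'
#' @param depth_m Sample depths (m).
#' @param period Stability-period labels, recycled against `depth_m`.
#' @param mld_m,euphotic_depth_m,light1pct_depth_m,dcm_upper_m,dcm_lower_m,dcm_is_dcm
#'   Per-sample profile features (recycled).
#' @param params A [hydro_params()] bundle.
#'
#' @return A factor with levels surface, dcm, light1pct, ml, below_euphotic,
#'   other; every input receives exactly one zone.
#' @export
assign_zone <- function(depth_m, period, mld_m,
                        euphotic_depth_m = NA_real_,
                        light1pct_depth_m = NA_real_,
                        dcm_upper_m = NA_real_,
                        dcm_lower_m = NA_real_,
                        dcm_is_dcm = FALSE,
                        params = hydro_params()) {
  n <- length(depth_m)
  period <- as.character(rep_len(period, n))
  mld_m <- rep_len(mld_m, n)
  euphotic_depth_m <- rep_len(euphotic_depth_m, n)
  light1pct_depth_m <- rep_len(light1pct_depth_m, n)
  dcm_upper_m <- rep_len(dcm_upper_m, n)
  dcm_lower_m <- rep_len(dcm_lower_m, n)
  dcm_is_dcm <- rep_len(dcm_is_dcm, n)

  isTRUEv <- function(x) !is.na(x) & x
  zone <- rep("other", n)
  in_dcm <- isTRUEv(period != "DM") & isTRUEv(dcm_is_dcm) &
    !is.na(dcm_upper_m) & !is.na(dcm_lower_m) &
    depth_m >= dcm_upper_m & depth_m <= dcm_lower_m
  in_1pct <- isTRUEv(period == "DM") & !is.na(light1pct_depth_m) &
    abs(depth_m - light1pct_depth_m) <= params$zone_tolerance_m
  in_ml <- !is.na(mld_m) & depth_m <= mld_m
  below <- !is.na(euphotic_depth_m) & depth_m > euphotic_depth_m

  zone[below] <- "below_euphotic"
  zone[in_ml] <- "ml"
  zone[in_1pct] <- "light1pct"
  zone[in_dcm] <- "dcm"
  zone[depth_m <= params$surface_max_depth_m] <- "surface"
  factor(zone, levels = ZONE_LEVELS)
}

#' Annotate sample metadata with period, zone and year
#'
#' Joins sample metadata to per-profile features and the stability timeline,
#' then derives each sample's vertical zone and calendar year. This is the
#' bridge between the hydrographic module and all community summaries.
#'
#' @param meta Tibble with `sample_id`, `profile_id`, `depth_m`, `timestamp`.
#' @param features Output of [profile_features()].
#' @param timeline Output of [classify_stability_periods()].
#' @param params A [hydro_params()] bundle (zone rules).
#'
#' @return `meta` with `period`, `zone` and `year` columns added.
#' @export
annotate_samples <- function(meta, features, timeline,
                             params = hydro_params()) {
  stopifnot(all(c("sample_id", "profile_id", "depth_m") %in% names(meta)))
  feats <- select(
    features, "profile_id", "mld_m", "euphotic_depth_m",
    "light1pct_depth_m", "dcm_upper_m", "dcm_lower_m", "dcm_is_dcm"
  )
  tl <- select(as_tibble(timeline), "profile_id", "period")
  out <- meta |>
    left_join(feats, by = "profile_id") |>
    left_join(tl, by = "profile_id")
  out$zone <- assign_zone(
    out$depth_m, out$period, out$mld_m,
    out$euphotic_depth_m, out$light1pct_depth_m,
    out$dcm_upper_m, out$dcm_lower_m, out$dcm_is_dcm,
    params = params
  )
  if ("timestamp" %in% names(out)) {
    out$year <- as.integer(format(as.Date(substr(
      as.character(out$timestamp), 1, 10
    )), "%Y"))
  }
  select(out, -dplyr::any_of(c(
    "mld_m", "euphotic_depth_m", "light1pct_depth_m",
    "dcm_upper_m", "dcm_lower_m", "dcm_is_dcm"
  )))
}
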