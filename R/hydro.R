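#' Mixed-layer depth from a sigma-t profile
#'
#' The mixed-layer depth (MLD) is the shallowest depth at which sigma-t
#' reaches the surface value plus `delta_sigma` (the classical 0.125 kg m^-3
#' density-offset criterion). The crossing is located by linear interpolation
#' in sigma-t between the bracketing samples; the shallowest sample is
#' treated as "surface". Profiles that never reach the threshold (fully mixed
#' casts) return the deepest sampled depth with `bottom_limited = TRUE` so
#' that deep-mixing detection still works on bottom-limited casts.
#'
#' @param depth_m Strictly increasing numeric vector of depths (m,
#'   positive-down), length >= 2.
#' @param sigma_t Numeric vector of density anomalies (kg m^-3), same length.
#' @param delta_sigma Density offset above the surface value (kg m^-3).
#'
#' @return A list with `mld_m` and `bottom_limited`.
#' @export
#' @examples
#' compute_mld(c(1, 10), c(24.0, 24.2))  # crossing at 6.625 m
compute_mld <- function(depth_m, sigma_t, delta_sigma = 0.125) {
  check_profile_arrays(depth_m, sigma_t, "sigma_t")
  if (!all(is.finite(sigma_t))) {
    abort("`sigma_t` must be finite.", class = "picocycle_invalid_profile")
  }
  stopifnot(delta_sigma > 0)
  target <- sigma_t[1] + delta_sigma
  hit <- which(sigma_t >= target)
  if (length(hit) == 0) {
    return(list(mld_m = depth_m[length(depth_m)], bottom_limited = TRUE))
  }
  i <- hit[1]
  # i == 1 cannot happen because delta_sigma > 0
  frac <- (target - sigma_t[i - 1]) / (sigma_t[i] - sigma_t[i - 1])
  mld <- depth_m[i - 1] + frac * (depth_m[i] - depth_m[i - 1])
  list(mld_m = unname(mld), bottom_limited = FALSE)
}

#' Depth of a given fraction of surface PAR
#'
#' Locates the depth at which photosynthetically active radiation (PAR)
#' first falls to `fraction` times its value at the shallowest sample,
#' interpolating linearly in log(PAR) against depth (exact for exponential
#' attenuation). Zero PAR readings are excluded from the interpolation; if
#' PAR never falls to the target within the profile the depth is undefined
#' and `NA` is returned.
#'
#' @param depth_m Strictly increasing depths (m), length >= 2.
#' @param par PAR values (any consistent unit), same length, >= 0 with a
#'   positive value at the shallowest sample.
#' @param fraction Target fraction of surface PAR in (0, 1].
#'
#' @return Depth in metres, or `NA_real_` when the level is not reached.
#' @export
#' @examples
#' z <- seq(1, 200, by = 1)
#' compute_light_depth(z, 1500 * exp(-0.046 * z), 0.01)  # ~ ln(100)/0.046
compute_light_depth <- function(depth_m, par, fraction) {
  check_profile_arrays(depth_m, par, "par")
  stopifnot(fraction > 0, fraction <= 1)
  if (any(par < 0, na.rm = TRUE)) {
    abort("`par` must be nonnegative.", class = "picocycle_invalid_profile")
  }
  if (is.na(par[1]) || par[1] <= 0) {
    abort("PAR at the shallowest sample must be positive.",
          class = "picocycle_invalid_profile")
  }
  if (fraction == 1) {
    return(depth_m[1])
  }
  keep <- !is.na(par) & par > 0
  z <- depth_m[keep]
  lp <- log(par[keep])
  target <- log(par[1] * fraction)
  hit <- which(lp <= target)
  if (length(hit) == 0) {
    return(NA_real_)
  }
  i <- hit[1]
  if (i == 1) {
    return(z[1])
  }
  frac <- (target - lp[i - 1]) / (lp[i] - lp[i - 1])
  unname(z[i - 1] + frac * (z[i] - z[i - 1]))
}

#' Deep chlorophyll maximum region from a fluorescence profile
#'
#' Finds the depth of maximum in-vivo fluorescence (shallowest on ties) and
#' the contiguous depth interval around it where fluorescence stays within
#' `dcm_fraction` of the maximum, i.e. >= (1 - dcm_fraction) * max. Region
#' boundaries are linearly interpolated between samples; an interval clipped
#' by the top or bottom of the profile ends at the profile limit. The region
#' is a genuine DCM (`is_dcm`) only when the mixed layer is shallower than
#' the region's upper bound.
#'
#' @param depth_m Strictly increasing depths (m), length >= 2.
#' @param fluor_rfu Fluorescence (relative units, >= 0), same length.
#' @param mld_m Mixed-layer depth (m) for the same cast.
#' @param dcm_fraction Fractional drop from the maximum bounding the region.
#'
#' @return A one-row tibble with `upper_m`, `max_m`, `lower_m`, `max_fluor`,
#'   `is_dcm`; all-`NA` (with `is_dcm = FALSE`) when fluorescence has no
#'   positive maximum.
#' @export
detect_dcm <- function(depth_m, fluor_rfu, mld_m, dcm_fraction = 0.35) {
  check_profile_arrays(depth_m, fluor_rfu, "fluor_rfu")
  stopifnot(dcm_fraction > 0, dcm_fraction < 1)
  absent <- tibble(
    upper_m = NA_real_, max_m = NA_real_, lower_m = NA_real_,
    max_fluor = NA_real_, is_dcm = FALSE
  )
  f <- fluor_rfu
  if (all(is.na(f)) || max(f, na.rm = TRUE) <= 0 ||
      !is.finite(max(f, na.rm = TRUE))) {
    return(absent)
  }
  f[is.na(f)] <- 0
  imax <- which.max(f) # shallowest index on ties
  fmax <- f[imax]
  thr <- (1 - dcm_fraction) * fmax

  # walk outward from the maximum while fluorescence stays at/above threshold
  i_up <- imax
  while (i_up > 1 && f[i_up - 1] >= thr) i_up <- i_up - 1
  i_lo <- imax
  n <- length(f)
  while (i_lo < n && f[i_lo + 1] >= thr) i_lo <- i_lo + 1

  upper <- if (i_up == 1) {
    depth_m[1]
  } else {
    frac <- (thr - f[i_up - 1]) / (f[i_up] - f[i_up - 1])
    depth_m[i_up - 1] + frac * (depth_m[i_up] - depth_m[i_up - 1])
  }
  lower <- if (i_lo == n) {
    depth_m[n]
  } else {
    frac <- (f[i_lo] - thr) / (f[i_lo] - f[i_lo + 1])
    depth_m[i_lo] + frac * (depth_m[i_lo + 1] - depth_m[i_lo])
  }
  tibble(
    upper_m = unname(upper),
    max_m = depth_m[imax],
    lower_m = unname(lower),
    max_fluor = fmax,
    is_dcm = isTRUE(!is.na(mld_m) && mld_m < upper)
  )
}

#' Per-profile physical features from long-format CTD data
#'
#' Computes, for every cast in a long-format CTD table, the mixed-layer
#' depth, the euphotic-zone depth (0.1 percent surface PAR), the 1 percent
#' light depth, and the deep-chlorophyll-maximum region. Casts lacking PAR or
#' fluorescence get `NA` for the features that depend on them.
#'
#' @param ctd Data frame with columns `profile_id`, `timestamp`, `depth_m`,
#'   `sigma_t` and optionally `fluor_rfu`, `par` (one row per depth).
#' @param params A [hydro_params()] bundle.
#'
#' @return A tibble with one row per profile: `profile_id`, `timestamp`,
#'   `mld_m`, `mld_bottom_limited`, `euphotic_depth_m`, `light1pct_depth_m`,
#'   `dcm_upper_m`, `dcm_max_m`, `dcm_lower_m`, `dcm_max_fluor`,
#'   `dcm_is_dcm`, ordered by timestamp.
#' @export
profile_features <- function(ctd, params = hydro_params()) {
  stopifnot(is.data.frame(ctd))
  req <- c("profile_id", "timestamp", "depth_m", "sigma_t")
  missing_cols <- setdiff(req, names(ctd))
  if (length(missing_cols) > 0) {
    abort(paste0("`ctd` lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  one <- function(df) {
    df <- arrange(df, .data$depth_m)
    z <- df$depth_m
    mld <- compute_mld(z, df$sigma_t, params$delta_sigma)
    light <- function(frac) {
      if (!"par" %in% names(df) || all(is.na(df$par)) ||
          is.na(df$par[1]) || df$par[1] <= 0) {
        return(NA_real_)
      }
      compute_light_depth(z, df$par, frac)
    }
    dcm <- if ("fluor_rfu" %in% names(df) && !all(is.na(df$fluor_rfu))) {
      detect_dcm(z, df$fluor_rfu, mld$mld_m, params$dcm_fraction)
    } else {
      tibble(upper_m = NA_real_, max_m = NA_real_, lower_m = NA_real_,
             max_fluor = NA_real_, is_dcm = FALSE)
    }
    tibble(
      profile_id = df$profile_id[1],
      timestamp = df$timestamp[1],
      mld_m = mld$mld_m,
      mld_bottom_limited = mld$bottom_limited,
      euphotic_depth_m = light(params$euphotic_par_fraction),
      light1pct_depth_m = light(params$comparison_par_fraction),
      dcm_upper_m = dcm$upper_m,
      dcm_max_m = dcm$max_m,
      dcm_lower_m = dcm$lower_m,
      dcm_max_fluor = dcm$max_fluor,
      dcm_is_dcm = dcm$is_dcm
    )
  }
  split(ctd, ctd$profile_id) |>
    purrr::map(one) |>
    bind_rows() |>
    arrange(.data$timestamp)
}

check_profile_arrays <- function(depth_m, values, what) {
  if (length(depth_m) < 2) {
    abort("A profile needs at least 2 depths.",
          class = "picocycle_invalid_profile")
  }
  if (length(values) != length(depth_m)) {
    abort(paste0("`", what, "` and `depth_m` must have equal length."),
          class = "picocycle_invalid_profile")
  }
  if (any(diff(depth_m) <= 0)) {
    abort("`depth_m` must be strictly increasing.",
          class = "picocycle_invalid_profile")
  }
  invisible(TRUE)
}
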