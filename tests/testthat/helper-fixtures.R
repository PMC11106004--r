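# analytic CTD profile builders used across test files

# exponential-light, two-layer-density cast; depths start at 0 so the
# closed-form light depths are ln(1/f)/k exactly
make_cast <- function(depths = seq(0, 250, by = 1),
                      sigma_surface = 24,
                      mld = 60,
                      jump = 0.13,
                      grad = 0.01,
                      k = 0.046,
                      par0 = 1500,
                      fluor = NULL) {
  sigma <- ifelse(depths <= mld, sigma_surface,
                  sigma_surface + jump + (depths - mld) * grad)
  if (is.null(fluor)) {
    fluor <- exp(-(depths - 100)^2 / (2 * 20^2))
  }
  tibble::tibble(
    profile_id = "T1",
    timestamp = as.POSIXct("2017-06-15 12:00:00", tz = "UTC"),
    depth_m = depths,
    temp_C = 22, salinity = 36.6,
    sigma_t = sigma,
    fluor_rfu = fluor,
    par = par0 * exp(-k * depths)
  )
}

# minimal taxonomy with two plastid groups, one prasinophyte
toy_taxonomy <- function() {
  tibble::tibble(
    asv_id = c("p1", "p2", "q1", "c1", "h1"),
    marker = "plastid16S",
    category = c("plastid", "plastid", "plastid", "cyanobacteria",
                 "heterotroph"),
    group = c("prasinophyte_ClassII", "prasinophyte_ClassVI",
              "stramenopile", NA, NA),
    genus = c("Ostreococcus", "Prasinoderma", NA, NA, NA),
    species = NA_character_
  )
}

toy_counts <- function(...) {
  rows <- list(...)
  tibble::tibble(
    sample_id = vapply(rows, `[[`, character(1), 1),
    asv_id = vapply(rows, `[[`, character(1), 2),
    count = as.integer(vapply(rows, function(r) as.numeric(r[[3]]),
                              numeric(1)))
  )
}

# features row constructor for zone/persistence tests
toy_features <- function(profile_id = "T1", mld = 50, zeu = 150,
                         l1 = 95, up = 85, lo = 115, isdcm = TRUE) {
  tibble::tibble(
    profile_id = profile_id,
    timestamp = as.POSIXct("2017-06-15 12:00:00", tz = "UTC"),
    mld_m = mld, mld_bottom_limited = FALSE,
    euphotic_depth_m = zeu, light1pct_depth_m = l1,
    dcm_upper_m = up, dcm_max_m = (up + lo) / 2, dcm_lower_m = lo,
    dcm_max_fluor = 1, dcm_is_dcm = isdcm
  )
}
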