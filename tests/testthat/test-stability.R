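mk_feat <- function(n, mld, zeu = 150, up = NA, lo = NA, isdcm = FALSE) {
  tibble::tibble(
    profile_id = sprintf("P%02d", seq_len(n)),
    timestamp = as.POSIXct("2017-01-01", tz = "UTC") + seq_len(n) * 86400 * 30,
    mld_m = mld, mld_bottom_limited = FALSE,
    euphotic_depth_m = zeu, light1pct_depth_m = zeu - 50,
    dcm_upper_m = up, dcm_max_m = up + 15, dcm_lower_m = lo,
    dcm_max_fluor = 1, dcm_is_dcm = isdcm
  )
}

test_that("single-profile triggers classify directly", {
  # deep mixing: MLD below the euphotic depth
  tl <- classify_stability_periods(mk_feat(1, mld = 300, zeu = 150))
  expect_equal(as.character(tl$period), "DM")

  # stratified: from ST, an MLD above the DCM's top switches to SS
  f <- dplyr::bind_rows(
    mk_feat(1, mld = 95, up = 85, lo = 115),
    mk_feat(1, mld = 15, up = 85, lo = 115)
  )
  f$timestamp <- f$timestamp + c(0, 86400)
  tl2 <- classify_stability_periods(f)
  expect_equal(as.character(tl2$period), c("ST", "SS"))
})

test_that("the annual cycle is recovered from the synthetic year", {
  pc <- noiseless(physics_config())
  phys <- simulate_physics(pc, seed = 3)
  feats <- profile_features(phys$ctd)
  tl <- classify_stability_periods(feats)
  expect_identical(as.character(tl$period), phys$truth$period)
  expect_identical(rle(as.character(tl$period))$values,
                   c("DM", "ST", "SS", "AT"))
})

test_that("timeline labels are unchanged when a cast is observed twice", {
  pc <- noiseless(physics_config())
  phys <- simulate_physics(pc, seed = 2)
  feats <- profile_features(phys$ctd)
  base <- classify_stability_periods(feats)
  for (i in c(1, 4, 5, 11, 12)) {
    dup <- dplyr::bind_rows(feats, feats[i, ]) |>
      dplyr::arrange(timestamp)
    tl <- classify_stability_periods(dup)
    collapsed <- dplyr::distinct(
      tibble::tibble(profile_id = tl$profile_id,
                     period = as.character(tl$period))
    )
    expect_identical(collapsed$period[match(base$profile_id,
                                            collapsed$profile_id)],
                     as.character(base$period))
  }
})

test_that("renewed deep mixing re-enters DM from any state", {
  f <- dplyr::bind_rows(
    mk_feat(1, mld = 300),
    mk_feat(1, mld = 90, up = 85, lo = 115),
    mk_feat(1, mld = 20, up = 85, lo = 115, isdcm = TRUE),
    mk_feat(1, mld = 280)
  )
  f$timestamp <- f$timestamp + 86400 * seq_len(4)
  tl <- classify_stability_periods(f)
  expect_equal(as.character(tl$period), c("DM", "ST", "SS", "DM"))
})

test_that("casts lacking features carry the previous label", {
  f <- dplyr::bind_rows(
    mk_feat(1, mld = 300),
    mk_feat(1, mld = NA)
  )
  f$timestamp <- f$timestamp + c(0, 86400)
  tl <- classify_stability_periods(f)
  expect_equal(as.character(tl$period), c("DM", "DM"))
  expect_equal(tl$trigger[2], "carried")
})

test_that("a timeline with no classifiable profile errors", {
  f <- mk_feat(2, mld = NA)
  expect_error(classify_stability_periods(f),
               class = "picocycle_unclassified_timeline")
})

test_that("zone assignment follows the precedence rules and partitions", {
  # surface beats everything
  expect_equal(as.character(assign_zone(3, "SS", mld_m = 50)), "surface")
  # DCM containment during stratification
  expect_equal(
    as.character(assign_zone(100, "SS", mld_m = 20, dcm_upper_m = 85,
                             dcm_lower_m = 115, dcm_is_dcm = TRUE)),
    "dcm"
  )
  # 1%-light band during deep mixing (tolerance 10 m)
  expect_equal(
    as.character(assign_zone(100, "DM", mld_m = 200,
                             euphotic_depth_m = 150,
                             light1pct_depth_m = 95)),
    "light1pct"
  )
  # inside the mixed layer otherwise
  expect_equal(
    as.character(assign_zone(60, "DM", mld_m = 200,
                             euphotic_depth_m = 150,
                             light1pct_depth_m = 95)),
    "ml"
  )
  # beneath the euphotic zone
  expect_equal(
    as.character(assign_zone(250, "SS", mld_m = 20,
                             euphotic_depth_m = 150)),
    "below_euphotic"
  )
  # a missing feature skips its rule rather than erroring
  expect_equal(as.character(assign_zone(100, "SS", mld_m = NA)), "other")

  # partition: every sample of a synthetic year gets exactly one zone
  sim <- simulate_annual_cycle(seed = 4)
  feats <- profile_features(sim$ctd)
  tl <- classify_stability_periods(feats)
  meta <- annotate_samples(sim$meta, feats, tl)
  expect_false(any(is.na(meta$zone)))
  expect_equal(nrow(meta), nrow(sim$meta))
})
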