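test_that("rarefaction endpoint slope equals the singleton fraction", {
  expect_equal(rarefaction_slope(rep(1, 1000)), 1)
  expect_equal(rarefaction_slope(1000), 0)
  expect_equal(rarefaction_slope(c(950, rep(1, 50))), 0.05)
  expect_error(rarefaction_slope(1), class = "picocycle_undefined_slope")

  # difference of analytical expected-richness values agrees with f1/N
  set.seed(9)
  for (i in 1:50) {
    counts <- rpois(30, 3) + ifelse(runif(30) < 0.3, 1, 0)
    counts <- counts[counts > 0]
    if (sum(counts) < 2) next
    N <- sum(counts)
    slope <- rarefaction_richness(counts, N) -
      rarefaction_richness(counts, N - 1)
    expect_equal(slope, rarefaction_slope(counts), tolerance = 1e-10)
  }
})

test_that("rarefaction slope agrees with vegan and a subsampling oracle", {
  skip_if_not_installed("vegan")
  set.seed(21)
  for (i in 1:20) {
    counts <- c(rpois(40, 8), rep(1, rpois(1, 10)))
    counts <- counts[counts > 0]
    N <- sum(counts)
    vegan_diff <- as.numeric(vegan::rarefy(t(counts), N)) -
      as.numeric(vegan::rarefy(t(counts), N - 1))
    expect_equal(rarefaction_slope(counts), vegan_diff, tolerance = 1e-8)
  }
  # Monte-Carlo oracle: dropping one random read loses a species iff the
  # read belonged to a singleton
  set.seed(22)
  counts <- c(950, rep(1, 50))
  reps <- 10000
  drop_is_singleton <- sample(seq_along(counts), reps, replace = TRUE,
                              prob = counts)
  mc <- mean(counts[drop_is_singleton] == 1)
  se <- sd(counts[drop_is_singleton] == 1) / sqrt(reps)
  expect_lt(abs(mc - rarefaction_slope(counts)), 3 * se + 1e-12)
})

test_that("sample filter keeps saturated samples and flags low plastid", {
  tax <- toy_taxonomy()
  tab <- dplyr::bind_rows(
    # saturated, plenty of plastid
    toy_counts(c("A", "p1", 5000), c("A", "q1", 4995), c("A", "h1", 5)),
    # all-singleton sample: slope 1
    toy_counts(c("B", "p1", 1), c("B", "q1", 1), c("B", "c1", 1)),
    # saturated but only 30 plastid reads
    toy_counts(c("C", "p1", 30), c("C", "c1", 4970))
  )
  res <- filter_samples(tab, tax)
  res <- res[match(c("A", "B", "C"), res$sample_id), ]
  expect_equal(res$kept, c(TRUE, FALSE, TRUE))
  expect_equal(res$low_plastid, c(FALSE, TRUE, TRUE))
  expect_match(res$reason[2], "slope")
  expect_true(is.na(res$reason[1]))
  expect_warning(filter_samples(tab[0, ], tax), "Empty")
})

test_that("normalization yields fractions of the chosen denominator", {
  tax <- toy_taxonomy()
  tab <- toy_counts(
    c("A", "p1", 30), c("A", "p2", 10), c("A", "q1", 60),
    c("A", "c1", 100), c("A", "h1", 300)
  )
  # prasinophytes (incl. Class VI) are 40 of 100 plastid reads
  pf <- prasinophyte_fraction(tab, tax)
  expect_equal(pf$pras_fraction, 0.4)

  rel <- normalize_abundance(tab, tax, "plastid", "group")
  expect_equal(sum(rel$value), 1)
  rel_tot <- normalize_abundance(tab, tax, "total", "asv")
  expect_equal(sum(rel_tot$value), 1)
  expect_equal(rel_tot$value[rel_tot$unit == "h1"], 0.6)

  # prasinophyte denominator over prasinophyte ASVs
  rel_p <- normalize_abundance(tab, tax, "prasinophyte", "asv")
  expect_equal(sort(rel_p$value), c(0.25, 0.75))

  # zero-denominator sample is absent, not zero
  tab2 <- toy_counts(c("Z", "c1", 50))
  rel_z <- normalize_abundance(tab2, tax, "plastid", "group")
  expect_true(all(is.na(rel_z$value)))
})

test_that("normalization is invariant to scaling a sample's counts", {
  tax <- toy_taxonomy()
  tab <- toy_counts(
    c("A", "p1", 3), c("A", "q1", 6), c("A", "c1", 10)
  )
  tab10 <- dplyr::mutate(tab, count = count * 17L)
  r1 <- normalize_abundance(tab, tax, "plastid", "asv")
  r2 <- normalize_abundance(tab10, tax, "plastid", "asv")
  expect_equal(r1$value, r2$value)
})

test_that("composition summaries report mean, sd and n by period and zone", {
  rel <- tibble::tibble(
    sample_id = c("A", "B", "C"),
    unit = "prasinophyte_ClassII",
    value = c(0.2, 0.4, 0.9)
  )
  meta <- tibble::tibble(
    sample_id = c("A", "B", "C"),
    period = c("DM", "DM", "SS"),
    zone = c("ml", "ml", "surface")
  )
  s <- summarize_composition(rel, meta)
  dm <- s[s$period == "DM", ]
  expect_equal(dm$mean, 0.3)
  expect_equal(dm$sd, sd(c(0.2, 0.4)))
  expect_equal(dm$n, 2L)
  ss <- s[s$period == "SS", ]
  expect_equal(ss$mean, 0.9)
  expect_true(is.na(ss$sd))
})

test_that("group means converge to the planted template at n = 200", {
  # DM mixed-layer template: prasinophyte fraction of plastid 0.463; the
  # Dirichlet aggregation makes the fraction Beta-distributed with that
  # mean, so the group mean at n = 200 sits within 3 standard errors
  set.seed(31)
  cfg <- community_config()
  pc <- physics_config()
  phys <- simulate_physics(noiseless(pc), seed = 31)
  comm <- simulate_community(cfg, phys, pc, seed = 31)
  feats <- profile_features(phys$ctd)
  tl <- classify_stability_periods(feats)
  meta <- annotate_samples(comm$meta, feats, tl)
  pf <- dplyr::inner_join(prasinophyte_fraction(comm$asv16, comm$taxonomy),
                          meta, by = "sample_id")
  vals <- pf$pras_fraction[pf$period == "DM" & pf$zone == "ml"]
  # top up with more simulated years until 200 samples
  s <- 32
  while (length(vals) < 200) {
    phys2 <- simulate_physics(noiseless(pc), seed = s)
    comm2 <- simulate_community(cfg, phys2, pc, seed = s)
    meta2 <- annotate_samples(comm2$meta, profile_features(phys2$ctd),
                              classify_stability_periods(
                                profile_features(phys2$ctd)))
    pf2 <- dplyr::inner_join(
      prasinophyte_fraction(comm2$asv16, comm2$taxonomy),
      meta2, by = "sample_id"
    )
    vals <- c(vals, pf2$pras_fraction[pf2$period == "DM" & pf2$zone == "ml"])
    s <- s + 1
  }
  vals <- vals[1:200]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.463), 3 * se)
})

test_that("quadrants partition the eligible set at oracle thresholds", {
  set.seed(41)
  df <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:120),
    depth_m = sample(c(1, 40, 100, 139, 200), 120, replace = TRUE),
    chla_ug_kg = rlnorm(120, -2, 0.8),
    pras_fraction = runif(120)
  )
  q <- assign_quadrants(df)
  eligible <- df[df$depth_m <= 140, ]
  expect_equal(nrow(q), nrow(eligible))
  expect_equal(sum(table(q$quadrant)), nrow(eligible))

  # sort-based percentile oracle (linear interpolation definition)
  oracle_q75 <- function(x) {
    x <- sort(x)
    h <- (length(x) - 1) * 0.75 + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  thr <- attr(q, "thresholds")
  expect_equal(unname(thr["chla"]), oracle_q75(eligible$chla_ug_kg),
               tolerance = 1e-12)
  expect_equal(unname(thr["frac"]), oracle_q75(eligible$pras_fraction),
               tolerance = 1e-12)

  # assignment against the printed field thresholds: exceeding both is Q4,
  # below both is Q1; threshold-equal values fall in the lower half
  df2 <- tibble::tibble(
    sample_id = c("a", "b", "c", "d", "e"),
    depth_m = 10,
    chla_ug_kg = c(0.25, 0.10, 0.188, 0.05, 0.30),
    pras_fraction = c(0.40, 0.10, 0.332, 0.40, 0.332)
  )
  hi_c <- df2$chla_ug_kg > 0.188
  hi_f <- df2$pras_fraction > 0.332
  manual <- dplyr::case_when(
    hi_c & hi_f ~ "Q4", hi_c ~ "Q2", hi_f ~ "Q3", TRUE ~ "Q1"
  )
  expect_equal(manual, c("Q4", "Q1", "Q1", "Q3", "Q2"))

  # order invariance of thresholds
  q_shuf <- assign_quadrants(df[sample.int(nrow(df)), ])
  expect_equal(attr(q_shuf, "thresholds"), thr)

  expect_error(assign_quadrants(df[1:3, ]),
               class = "picocycle_quadrant_error")
})

test_that("persistence categories follow period counts with singleton exclusion", {
  meta <- tibble::tibble(
    sample_id = sprintf("S%d", 1:8),
    depth_m = c(rep(10, 7), 200),
    period = c("DM", "DM", "ST", "SS", "AT", "DM", "SS", "DM"),
    year = c(2017, 2018, 2017, 2017, 2017, 2019, 2018, 2017)
  )
  tab <- dplyr::bind_rows(
    toy_counts(c("S1", "everywhere", 5), c("S3", "everywhere", 2),
               c("S4", "everywhere", 8), c("S5", "everywhere", 1)),
    toy_counts(c("S1", "dm_only", 4), c("S2", "dm_only", 2),
               c("S6", "dm_only", 9)),
    toy_counts(c("S4", "ss_two", 3), c("S7", "ss_two", 2)),
    toy_counts(c("S2", "singleton", 1)),
    toy_counts(c("S8", "deep_only", 7))
  )
  res <- classify_persistence(tab, meta)
  g <- function(id) res[res$asv_id == id, ]
  expect_equal(as.character(g("everywhere")$category), "persistent")
  expect_equal(g("everywhere")$n_periods_detected, 4L)
  expect_equal(as.character(g("dm_only")$category), "ephemeral")
  expect_equal(g("dm_only")$n_years, 3L)
  expect_equal(as.character(g("ss_two")$category), "ephemeral")
  expect_false("singleton" %in% res$asv_id)      # one read total
  expect_false("deep_only" %in% res$asv_id)      # below 140 m only

  sets <- persistence_set_counts(res)
  expect_equal(
    sets$n_asvs[sets$set_type == "periods" &
                  sets$combination == "AT+DM+SS+ST"], 1L
  )
  expect_equal(
    sets$n_asvs[sets$set_type == "ss_only_years" &
                  sets$combination == "2017+2018"], 1L
  )
})

test_that("nutrient detection limits zero sub-LOD values only", {
  expect_equal(apply_detection_limit(c(0.04, 0.05, 0.2), 0.05),
               c(0, 0.05, 0.2))
  expect_equal(apply_detection_limit(0.2, 0.03), 0.2)
  expect_error(apply_detection_limit(c(-0.1, 0.2), 0.05))
})
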