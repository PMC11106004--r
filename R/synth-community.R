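#' Configuration for the synthetic community generator
#'
#' Defines the planted amplicon community: per-(period, habitat) plastid and
#' prasinophyte fractions, the within-prasinophyte ASV weights (with
#' persistent ASVs present year-round and summer-only ephemerals), the
#' Micromonas species latent model shared between markers, library-size
#' distributions, and the Dirichlet concentration controlling
#' sample-to-sample compositional spread. The defaults plant the field
#' values this generator emulates: mean 16S library size 60,279 with sd
#' 26,939; a deep-mixing mixed-layer prasinophyte fraction of plastid
#' amplicons of 0.463, with the Dirichlet concentration set so its
#' sample-to-sample sd is near the observed 0.242.
#'
#' @param library_mean_16s,library_sd_16s Arithmetic mean and sd of the
#'   lognormal 16S library-size distribution.
#' @param library_mean_18s,library_sd_18s Same for the 18S libraries.
#' @param dirichlet_conc Concentration of the per-sample Dirichlet draw
#'   around the (period, habitat) template. With the default plastid
#'   fraction, 9 reproduces the observed spread of the prasinophyte
#'   fraction.
#' @param micro_conc Concentration of the Micromonas within-genus species
#'   latent (small = strong sample-to-sample turnover among species).
#' @param micro_template Template shares of the four simulated Micromonas
#'   species (commoda, candidate sp. 1, candidate sp. 2, species 4).
#' @param copy_multipliers Per-species 18S/16S copy-number multipliers.
#' @param link_noise_sd Lognormal sd of the 18S abundance noise around the
#'   shared latent.
#' @param genus18_mult Multiplier from the 16S Micromonas fraction of total
#'   amplicons to the 18S Micromonas fraction.
#' @param chla_per_rfu Bottle chlorophyll a (ug kg^-1) per fluorescence RFU.
#'
#' @return A list of class `community_config`.
#' @export
community_config <- function(library_mean_16s = 60279,
                             library_sd_16s = 26939,
                             library_mean_18s = 30000,
                             library_sd_18s = 15000,
                             dirichlet_conc = 9,
                             micro_conc = 1,
                             micro_template = c(commoda = 0.40,
                                                cand1 = 0.30,
                                                cand2 = 0.15,
                                                sp4 = 0.15),
                             copy_multipliers = c(commoda = 1,
                                                  cand1 = 3,
                                                  cand2 = 5,
                                                  sp4 = 2),
                             link_noise_sd = 0.25,
                             genus18_mult = 4,
                             chla_per_rfu = 0.2) {
  stopifnot(
    library_mean_16s > 0, library_sd_16s > 0,
    library_mean_18s > 0, library_sd_18s > 0,
    dirichlet_conc > 0, micro_conc > 0,
    abs(sum(micro_template) - 1) < 1e-9,
    all(copy_multipliers > 0), link_noise_sd >= 0, genus18_mult > 0,
    chla_per_rfu > 0
  )
  structure(as.list(environment()), class = "community_config")
}

#' Taxonomy of the planted synthetic community
#'
#' The fixed ASV roster emitted by [simulate_community()]: cyanobacteria,
#' heterotrophic bacteria, non-prasinophyte plastid groups, prasinophyte
#' classes (II, I, VI, VII, IX) including two planted persistent Class II
#' ASVs and two planted summer-only ephemerals, four Micromonas species
#' split across both markers, and 18S filler taxa.
#'
#' @return Tibble (`asv_id`, `marker`, `category`, `group`, `genus`,
#'   `species`).
#' @export
synthetic_taxonomy <- function() {
  t16 <- tibble(
    asv_id = c(
      "ASV_cy1", "ASV_cy2", "ASV_h1", "ASV_h2", "ASV_h3",
      "ASV_pm1", "ASV_pm2", "ASV_st1", "ASV_st2", "ASV_op1",
      "ASV6", "ASV77", "ASV177",
      "ASV61", "ASV81", "ASV1156", "ASV_m4",
      "ASV_c1a", "ASV_c6a", "ASV_c7a", "ASV_c9a",
      "ASV_eph1", "ASV_eph2"
    ),
    marker = "plastid16S",
    category = c(
      "cyanobacteria", "cyanobacteria", rep("heterotroph", 3),
      rep("plastid", 18)
    ),
    group = c(
      rep(NA_character_, 5),
      "prymnesiophyte", "prymnesiophyte", "stramenopile", "stramenopile",
      "other_plastid",
      rep("prasinophyte_ClassII", 7),
      "prasinophyte_ClassI", "prasinophyte_ClassVI",
      "prasinophyte_ClassVII", "prasinophyte_ClassIX",
      "prasinophyte_ClassIX", "prasinophyte_ClassIX"
    ),
    genus = c(
      "Prochlorococcus", "Synechococcus", NA, NA, NA,
      NA, NA, NA, NA, NA,
      "Ostreococcus", "Ostreococcus", "Bathycoccus",
      "Micromonas", "Micromonas", "Micromonas", "Micromonas",
      "Pyramimonas", "Prasinoderma", "Chloropicon", NA, NA, NA
    ),
    species = c(
      rep(NA_character_, 10),
      "Ostreococcus Clade OII", "Ostreococcus Clade OII",
      "Bathycoccus calidus",
      "Micromonas commoda", NA, NA, NA,
      rep(NA_character_, 6)
    )
  )
  t18 <- tibble(
    asv_id = c("ASV18_mc1", "ASV18_mc2", "ASV18_cs1a", "ASV18_cs1b",
               "ASV18_cs2a", "ASV18_m4a", "ASV18_o1", "ASV18_o2"),
    marker = "18SV4",
    category = c(rep("other", 8)),
    group = NA_character_,
    genus = c(rep("Micromonas", 6), NA, NA),
    species = c("Micromonas commoda", "Micromonas commoda",
                "Micromonas candidate species 1",
                "Micromonas candidate species 1",
                "Micromonas candidate species 2",
                "Micromonas species 4", NA, NA)
  )
  bind_rows(t16, t18)
}

# species -> 18S ASV split (fixed shares within a species)
MICRO18_ASVS <- list(
  commoda = c(ASV18_mc1 = 0.7, ASV18_mc2 = 0.3),
  cand1 = c(ASV18_cs1a = 0.6, ASV18_cs1b = 0.4),
  cand2 = c(ASV18_cs2a = 1),
  sp4 = c(ASV18_m4a = 1)
)
MICRO16_ASVS <- c(commoda = "ASV61", cand1 = "ASV81",
                  cand2 = "ASV1156", sp4 = "ASV_m4")

#' Cross-marker candidate pairs planted by the generator
#'
#' @return Tibble (`asv16_id`, `species18_label`, `asv18_ids` list column,
#'   `linked_truth`).
#' @export
synthetic_link_pairs <- function() {
  tibble(
    asv16_id = unname(MICRO16_ASVS),
    species18_label = c("Micromonas commoda",
                        "Micromonas candidate species 1",
                        "Micromonas candidate species 2",
                        "Micromonas species 4"),
    asv18_ids = lapply(MICRO18_ASVS, names),
    linked_truth = c(TRUE, TRUE, TRUE, FALSE)
  )
}

# planted fraction of amplicons that are plastid, by (period, habitat)
planted_plastid_frac <- function(period, habitat) {
  base <- switch(period,
    DM = c(surface = 0.30, ml = 0.35, light1pct = 0.35,
           below_euphotic = 0.05, other = 0.20, dcm = 0.35),
    ST = c(surface = 0.30, ml = 0.30, dcm = 0.40,
           below_euphotic = 0.05, other = 0.20, light1pct = 0.30),
    SS = c(surface = 0.12, ml = 0.12, dcm = 0.40,
           below_euphotic = 0.05, other = 0.15, light1pct = 0.15),
    AT = c(surface = 0.15, ml = 0.15, dcm = 0.40,
           below_euphotic = 0.05, other = 0.15, light1pct = 0.15)
  )
  unname(base[habitat])
}

# planted prasinophyte fraction of plastid amplicons, by (period, habitat);
# deep-mixing mixed layer carries the 0.463 headline value
planted_pras_frac <- function(period, habitat) {
  base <- switch(period,
    DM = c(surface = 0.336, ml = 0.463, light1pct = 0.463,
           below_euphotic = 0.20, other = 0.30, dcm = 0.30),
    ST = c(surface = 0.088, ml = 0.088, dcm = 0.29,
           below_euphotic = 0.15, other = 0.15, light1pct = 0.15),
    SS = c(surface = 0.036, ml = 0.036, dcm = 0.29,
           below_euphotic = 0.15, other = 0.10, light1pct = 0.15),
    AT = c(surface = 0.066, ml = 0.066, dcm = 0.29,
           below_euphotic = 0.15, other = 0.10, light1pct = 0.15)
  )
  unname(base[habitat])
}

# relative weights of prasinophyte ASVs (Micromonas pooled as one unit);
# persistent ASVs (ASV6, ASV77, ASV177) keep mass everywhere, ephemerals
# only in stratified summer, Class I / putative Class IX bloom in the
# summer surface
pras_weights <- function(period, habitat) {
  w <- c(
    ASV6 = 0.24, ASV77 = 0.10, ASV177 = 0.16, MICRO = 0.27,
    ASV_c1a = 0.07, ASV_c6a = 0.03, ASV_c7a = 0.04, ASV_c9a = 0.09,
    ASV_eph1 = 0, ASV_eph2 = 0
  )
  if (period == "SS") {
    w[c("ASV_eph1", "ASV_eph2")] <- c(0.06, 0.04)
    if (habitat == "surface") {
      w[c("ASV_c1a", "ASV_c9a")] <- c(0.22, 0.28)
      w[c("ASV6", "ASV77", "ASV177", "MICRO")] <- c(0.08, 0.04, 0.06, 0.10)
    }
  }
  w / sum(w)
}

# within-genus 18S species shares: linked species share the 16S latent
# (times copy multipliers and lognormal noise) inside 1 - s_null, while the
# null species' share is the independent draw's share of that species
build_comp18_shares <- function(latent, latent_ind, null_species,
                                copy_multipliers, link_noise_sd) {
  species <- names(latent)
  linked_sp <- setdiff(species, null_species)
  null_share <- if (is.null(null_species)) 0 else unname(latent_ind[null_species])
  m <- latent[linked_sp] * copy_multipliers[linked_sp] *
    exp(rnorm(length(linked_sp), 0, link_noise_sd))
  if (sum(m) == 0) m[] <- 1 / length(m)
  out <- setNames(numeric(length(species)), species)
  out[linked_sp] <- (1 - null_share) * m / sum(m)
  if (!is.null(null_species)) out[null_species] <- null_share
  out
}

sample_habitat <- function(depth, truth_row, zone_tol = 10, surface_max = 5,
                           euphotic = truth_row$euphotic_depth_m) {
  if (depth <= surface_max) return("surface")
  if (truth_row$period != "DM" && !is.na(truth_row$dcm_upper_m) &&
      depth >= truth_row$dcm_upper_m && depth <= truth_row$dcm_lower_m) {
    return("dcm")
  }
  if (truth_row$period == "DM" &&
      abs(depth - truth_row$light1pct_depth_m) <= zone_tol) {
    return("light1pct")
  }
  if (depth <= truth_row$mld_m) return("ml")
  if (depth > euphotic) return("below_euphotic")
  "other"
}

#' Simulate paired 16S/18S amplicon tables over a planted physical year
#'
#' For every bottle sample (profile x depth), draws a community composition
#' from a Dirichlet distribution around the planted (period, habitat)
#' template, a library size from the lognormal library model, and read
#' counts multinomially. Micromonas species abundances are a shared latent:
#' the 16S ASVs of the four species receive the latent shares directly,
#' while the 18S species abundances are the same latent times per-species
#' copy-number multipliers and lognormal noise - except species 4, whose
#' 18S latent is drawn independently (the planted null pair). Summer-only
#' ephemeral ASVs have template mass only in the stratified summer; two
#' Class II ASVs are planted persistent. Bottle chlorophyll a follows the
#' planted fluorescence profile at the sampled depth.
#'
#' @param config A [community_config()].
#' @param physics Output of [simulate_physics()] (uses `$truth`).
#' @param pconfig The [physics_config()] used to generate `physics`.
#' @param seed Integer seed.
#'
#' @return A list with `meta`, `asv16`, `asv18` (long count tibbles),
#'   `taxonomy`, `bottle`, and `truth` (per-ASV planted category plus the
#'   planted link truth as `attr(truth, "links")`).
#' @export
simulate_community <- function(config = community_config(),
                               physics,
                               pconfig = physics_config(),
                               seed = 1) {
  set.seed(seed + 1L)
  truth <- physics$truth
  tax <- synthetic_taxonomy()
  depths <- pconfig$bottle_depths

  meta <- truth |>
    dplyr::reframe(
      sample_id = sprintf("%s_D%03d", .data$profile_id, round(depths)),
      depth_m = depths,
      .by = "profile_id"
    ) |>
    left_join(select(truth, "profile_id", "timestamp"), by = "profile_id") |>
    select("sample_id", "profile_id", "depth_m", "timestamp")

  species <- names(config$micro_template)
  rows16 <- vector("list", nrow(meta))
  rows18 <- vector("list", nrow(meta))
  bottle <- vector("list", nrow(meta))

  for (s in seq_len(nrow(meta))) {
    tr <- truth[truth$profile_id == meta$profile_id[s], ]
    depth <- meta$depth_m[s]
    habitat <- sample_habitat(depth, tr)
    period <- tr$period

    pf <- planted_plastid_frac(period, habitat)
    qf <- planted_pras_frac(period, habitat)
    pw <- pras_weights(period, habitat)

    # template over outer units (Micromonas pooled)
    pras_mass <- pf * qf
    plast_rest <- pf * (1 - qf)
    eph <- pw[c("ASV_eph1", "ASV_eph2")] * pras_mass
    pw <- pw[setdiff(names(pw), c("ASV_eph1", "ASV_eph2"))]
    template <- c(
      pw * pras_mass,
      ASV_pm1 = plast_rest * 0.22, ASV_pm2 = plast_rest * 0.13,
      ASV_st1 = plast_rest * 0.35, ASV_st2 = plast_rest * 0.20,
      ASV_op1 = plast_rest * 0.10,
      ASV_cy1 = (1 - pf) * 0.30, ASV_cy2 = (1 - pf) * 0.15,
      ASV_h1 = (1 - pf) * 0.25, ASV_h2 = (1 - pf) * 0.18,
      ASV_h3 = (1 - pf) * 0.12
    )
    comp <- setNames(rdirichlet1(config$dirichlet_conc * template),
                     names(template))
    # planted ephemerals ride their own lognormal latent so that, in the
    # stratified summer, they are present in essentially every sample
    # rather than scattered by the overdispersed community Dirichlet
    if (any(eph > 0)) {
      eph_mass <- eph * exp(rnorm(length(eph), 0, 0.5))
      comp <- c(comp * (1 - sum(eph_mass)), eph_mass)
    } else {
      comp <- c(comp, eph)
    }

    # shared Micromonas species latent
    micro <- setNames(rdirichlet1(config$micro_conc * config$micro_template),
                      species)
    comp_full <- comp[setdiff(names(comp), "MICRO")]
    comp_full <- c(comp_full,
                   setNames(comp[["MICRO"]] * micro,
                            unname(MICRO16_ASVS[species])))

    lib16 <- max(1000, round(rlnorm_mean_sd(1, config$library_mean_16s,
                                            config$library_sd_16s)))
    counts16 <- as.integer(rmultinom(1, lib16, comp_full))
    keep <- counts16 > 0
    rows16[[s]] <- tibble(
      sample_id = meta$sample_id[s],
      asv_id = names(comp_full)[keep],
      count = counts16[keep]
    )

    # 18S: linked species share the latent (times copy number and noise);
    # the null species' genus share comes from a fully independent draw so
    # its within-genus fraction carries no compositional echo of the 16S
    # side
    micro_null <- setNames(
      rdirichlet1(config$micro_conc * config$micro_template), species
    )
    sp_frac <- build_comp18_shares(micro, micro_null, "sp4",
                                   config$copy_multipliers,
                                   config$link_noise_sd)
    genus_frac18 <- min(0.9, comp[["MICRO"]] * config$genus18_mult)
    comp18 <- c(
      unlist(lapply(species, function(sp) {
        MICRO18_ASVS[[sp]] * genus_frac18 * sp_frac[[sp]]
      })),
      ASV18_o1 = (1 - genus_frac18) * 0.6,
      ASV18_o2 = (1 - genus_frac18) * 0.4
    )
    lib18 <- max(500, round(rlnorm_mean_sd(1, config$library_mean_18s,
                                           config$library_sd_18s)))
    counts18 <- as.integer(rmultinom(1, lib18, comp18))
    keep18 <- counts18 > 0
    rows18[[s]] <- tibble(
      sample_id = meta$sample_id[s],
      asv_id = names(comp18)[keep18],
      count = counts18[keep18]
    )

    # bottle chemistry: chlorophyll follows planted fluorescence; nutrients
    # climb below the euphotic zone and sit near/below detection above it
    fl <- if (period == "DM") {
      if (depth <= tr$mld_m) pconfig$ml_fluor else pconfig$fluor_background
    } else {
      pconfig$fluor_background + pconfig$dcm_fluor_max *
        exp(-(depth - pconfig$dcm_center_m)^2 / (2 * pconfig$dcm_sd_m^2))
    }
    chla <- config$chla_per_rfu * fl * exp(rnorm(1, 0, 0.15))
    no3 <- max(0, 0.03 + 2.5 * pmax(0, depth - 100) / 100 +
                 rnorm(1, 0, 0.05))
    po4 <- max(0, no3 / 16 + rnorm(1, 0, 0.01))
    poc <- max(0, 40 * exp(-depth / 300) * (1 + 0.5 * fl) * exp(rnorm(1, 0, 0.1)))
    bottle[[s]] <- tibble(
      sample_id = meta$sample_id[s],
      chla_ug_kg = chla,
      nitrate_nitrite_umol_kg = no3,
      phosphate_umol_kg = po4,
      poc = poc
    )
  }

  # ASV77 is an ordinary abundant Class II ASV, not part of the planted
  # truth: its template mass leaves full four-period coverage uncertain
  truth_asv <- tibble(
    asv_id = c("ASV6", "ASV177", "ASV_eph1", "ASV_eph2"),
    planted_category = c("persistent", "persistent",
                         "ephemeral_ss", "ephemeral_ss")
  )
  attr(truth_asv, "links") <- synthetic_link_pairs()

  list(
    meta = meta,
    asv16 = bind_rows(rows16),
    asv18 = bind_rows(rows18),
    taxonomy = tax,
    bottle = bind_rows(bottle),
    truth = truth_asv
  )
}

#' Simulate one focused cross-marker pair
#'
#' Small generator for calibrating the 16S-18S linking procedure: `n`
#' samples of a four-species genus, with the target species' 16S and 18S
#' fractions driven by a shared latent (`linked = TRUE`) or by independent
#' latents (`linked = FALSE`, the null). Returns count tables and
#' taxonomies ready for [link_candidates()].
#'
#' @param n Number of samples.
#' @param linked Whether the target pair shares its latent.
#' @param seed Integer seed.
#' @param config A [community_config()] (latent concentration, copy
#'   multipliers, link noise).
#' @param genus_reads_mean Mean genus read count per sample and marker.
#'
#' @return List with `table16`, `table18`, `taxonomy`, `pairs` (single-row,
#'   the target pair).
#' @export
simulate_crossmarker_pair <- function(n = 30, linked = TRUE, seed = 1,
                                      config = community_config(),
                                      genus_reads_mean = 200) {
  set.seed(seed)
  species <- names(config$micro_template)
  tax <- synthetic_taxonomy()
  t16 <- vector("list", n)
  t18 <- vector("list", n)
  for (s in seq_len(n)) {
    sid <- sprintf("X%03d", s)
    micro <- setNames(rdirichlet1(config$micro_conc * config$micro_template),
                      species)
    micro2 <- setNames(rdirichlet1(config$micro_conc * config$micro_template),
                       species)
    null_sp <- if (linked) NULL else "cand1"
    shares18 <- build_comp18_shares(micro, micro2, null_sp,
                                    config$copy_multipliers,
                                    config$link_noise_sd)
    reads16 <- max(10, round(rlnorm_mean_sd(1, genus_reads_mean,
                                            genus_reads_mean * 0.6)))
    reads18 <- max(10, round(rlnorm_mean_sd(1, genus_reads_mean,
                                            genus_reads_mean * 0.6)))
    c16 <- as.integer(rmultinom(1, reads16, micro))
    comp18 <- unlist(lapply(species, function(sp) {
      MICRO18_ASVS[[sp]] * shares18[[sp]]
    }))
    c18 <- as.integer(rmultinom(1, reads18, comp18 / sum(comp18)))
    t16[[s]] <- tibble(sample_id = sid,
                       asv_id = unname(MICRO16_ASVS[species]),
                       count = c16)
    t18[[s]] <- tibble(sample_id = sid, asv_id = names(comp18), count = c18)
  }
  pairs <- synthetic_link_pairs()[2, ] # the candidate-species-1 pair
  list(
    table16 = filter(bind_rows(t16), .data$count > 0),
    table18 = filter(bind_rows(t18), .data$count > 0),
    taxonomy = tax,
    pairs = pairs
  )
}

#' Simulate a complete annual dataset
#'
#' Convenience wrapper chaining [simulate_physics()] and
#' [simulate_community()].
#'
#' @param pconfig A [physics_config()].
#' @param cconfig A [community_config()].
#' @param seed Integer seed (physics and community streams are derived from
#'   it).
#'
#' @return A list: `ctd`, `truth_physics`, `meta`, `asv16`, `asv18`,
#'   `taxonomy`, `bottle`, `truth_community`, `pairs`.
#' @export
simulate_annual_cycle <- function(pconfig = physics_config(),
                                  cconfig = community_config(),
                                  seed = 1) {
  phys <- simulate_physics(pconfig, seed)
  comm <- simulate_community(cconfig, phys, pconfig, seed)
  list(
    ctd = phys$ctd,
    truth_physics = phys$truth,
    meta = comm$meta,
    asv16 = comm$asv16,
    asv18 = comm$asv18,
    taxonomy = comm$taxonomy,
    bottle = comm$bottle,
    truth_community = comm$truth,
    pairs = attr(comm$truth, "links")
  )
}
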