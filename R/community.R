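#' Expected rarefaction richness
#'
#' Analytical expectation of the number of ASVs observed in a random
#' subsample of `n` reads drawn without replacement from a sample:
#' E[S(n)] = sum_i (1 - choose(N - N_i, n) / choose(N, n)), computed on the
#' log scale for numerical stability.
#'
#' @param counts Nonnegative integer read counts per ASV (zeros ignored).
#' @param n Subsample size(s), 0 <= n <= sum(counts).
#' @return Expected richness for each `n`.
#' @export
rarefaction_richness <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  stopifnot(all(n >= 0), all(n <= N))
  vapply(n, function(nn) {
    if (nn == 0) return(0)
    p_absent <- exp(lchoose(N - counts, nn) - lchoose(N, nn))
    p_absent[counts > N - nn] <- 0
    sum(1 - p_absent)
  }, numeric(1))
}

#' Endpoint slope of the rarefaction curve
#'
#' The derivative of expected richness at full sample size, defined as
#' E[S(N)] - E[S(N - 1)], which reduces in closed form to f1 / N where f1 is
#' the number of singleton ASVs. Values near zero indicate sequencing
#' saturation; the sample-filtering rule keeps samples with slope below a
#' threshold (default 0.1).
#'
#' @param counts Nonnegative integer read counts per ASV for one sample.
#' @return The endpoint slope, a number in `[0, 1]`.
#' @export
#' @examples
#' rarefaction_slope(c(950, rep(1, 50)))  # 50/1000 = 0.05
rarefaction_slope <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 2) {
    abort("Rarefaction slope is undefined for fewer than 2 reads.",
          class = "picocycle_undefined_slope")
  }
  sum(counts == 1) / N
}

#' Per-sample saturation filter
#'
#' Computes the all-ASV rarefaction endpoint slope and the plastid read
#' count for every sample, keeps samples whose slope is below
#' `slope_threshold`, and flags (without removing) kept samples with fewer
#' than `min_plastid_reads` plastid amplicons so that plastid-denominator
#' analyses can exclude them. The flagged-not-dropped behaviour mirrors time
#' series practice where a few deep casts fail the plastid criterion but are
#' still informative for whole-community questions.
#'
#' @param table Long-format count tibble (`sample_id`, `asv_id`, `count`).
#' @param taxonomy Taxonomy tibble (`asv_id`, `category`, ...).
#' @param params A [community_params()] bundle.
#'
#' @return A tibble with one row per sample: `sample_id`, `n_reads`,
#'   `slope`, `n_plastid`, `kept`, `low_plastid`, `reason` (`NA` when kept).
#' @export
filter_samples <- function(table, taxonomy, params = community_params()) {
  if (nrow(table) == 0) {
    warn("Empty count table; nothing to filter.")
    return(tibble(
      sample_id = character(), n_reads = integer(), slope = double(),
      n_plastid = integer(), kept = logical(), low_plastid = logical(),
      reason = character()
    ))
  }
  plastid_ids <- taxonomy$asv_id[taxonomy$category == "plastid"]
  per <- table |>
    group_by(.data$sample_id) |>
    summarise(
      n_reads = sum(.data$count),
      slope = if (sum(.data$count) >= 2) {
        rarefaction_slope(.data$count)
      } else {
        NA_real_
      },
      n_plastid = sum(.data$count[.data$asv_id %in% plastid_ids]),
      .groups = "drop"
    )
  per |>
    mutate(
      kept = !is.na(.data$slope) & .data$slope < params$slope_threshold,
      low_plastid = .data$n_plastid < params$min_plastid_reads,
      reason = case_when(
        is.na(.data$slope) ~ "fewer than 2 reads",
        .data$slope >= params$slope_threshold ~
          sprintf("rarefaction slope %.4g >= %.4g", .data$slope,
                  params$slope_threshold),
        TRUE ~ NA_character_
      )
    )
}

is_prasinophyte_group <- function(group) {
  !is.na(group) & startsWith(group, "prasinophyte")
}

denominator_ids <- function(taxonomy, denominator) {
  switch(denominator,
    total = taxonomy$asv_id,
    plastid = taxonomy$asv_id[taxonomy$category == "plastid"],
    prasinophyte = taxonomy$asv_id[
      taxonomy$category == "plastid" & is_prasinophyte_group(taxonomy$group)
    ],
    abort(paste0("Unknown denominator: ", denominator))
  )
}

#' Relative abundances against a chosen denominator
#'
#' Normalizes per-sample ASV counts to fractions of a denominator read
#' count: all amplicons (`total`), plastid amplicons (`plastid`), or
#' prasinophyte amplicons including Prasinodermophyta/"Class VI"
#' (`prasinophyte`). Numerator units are either individual ASVs restricted
#' to the denominator subset, or lineage groups (plastid groups; other
#' categories keep their category name). Samples with a zero denominator are
#' emitted with `NA` fractions, never zeros, so downstream averages are not
#' diluted by undefined compositions.
#'
#' @param table Long-format count tibble (`sample_id`, `asv_id`, `count`).
#' @param taxonomy Taxonomy tibble (`asv_id`, `category`, `group`, ...).
#' @param denominator One of "total", "plastid", "prasinophyte".
#' @param unit "asv" or "group".
#'
#' @return Tibble (`sample_id`, `unit`, `value`); per sample the non-`NA`
#'   values sum to 1.
#' @export
normalize_abundance <- function(table, taxonomy,
                                denominator = c("total", "plastid",
                                                "prasinophyte"),
                                unit = c("asv", "group")) {
  denominator <- match.arg(denominator)
  unit <- match.arg(unit)
  den_ids <- denominator_ids(taxonomy, denominator)

  tab <- table |>
    inner_join(
      select(taxonomy, "asv_id", "category", "group"),
      by = "asv_id"
    ) |>
    mutate(unit = if (unit == "asv") {
      .data$asv_id
    } else {
      ifelse(.data$category == "plastid", .data$group, .data$category)
    })

  den <- tab |>
    filter(.data$asv_id %in% den_ids) |>
    group_by(.data$sample_id) |>
    summarise(den_reads = sum(.data$count), .groups = "drop")

  num <- tab |>
    filter(.data$asv_id %in% den_ids) |>
    group_by(.data$sample_id, .data$unit) |>
    summarise(reads = sum(.data$count), .groups = "drop")

  all_samples <- distinct(table, .data$sample_id)
  out <- all_samples |>
    left_join(den, by = "sample_id") |>
    left_join(num, by = "sample_id") |>
    mutate(value = ifelse(
      is.na(.data$den_reads) | .data$den_reads == 0,
      NA_real_, .data$reads / .data$den_reads
    )) |>
    select("sample_id", "unit", "value")
  out
}

#' Per-sample prasinophyte fraction of plastid amplicons
#'
#' Convenience wrapper returning, for each sample, the summed fraction of
#' plastid amplicons belonging to prasinophyte groups (Class VI included).
#' Samples with zero plastid reads get `NA`.
#'
#' @inheritParams normalize_abundance
#' @return Tibble (`sample_id`, `pras_fraction`).
#' @export
prasinophyte_fraction <- function(table, taxonomy) {
  rel <- normalize_abundance(table, taxonomy, "plastid", "group")
  rel |>
    group_by(.data$sample_id) |>
    summarise(
      pras_fraction = if (all(is.na(.data$value))) {
        NA_real_
      } else {
        sum(.data$value[is_prasinophyte_group(.data$unit)], na.rm = TRUE)
      },
      .groups = "drop"
    )
}

#' Composition summaries by stability period and vertical zone
#'
#' Arithmetic mean, sample standard deviation and group size of relative
#' abundances per (period, zone, unit). Samples with `NA` fractions (zero
#' denominator) are excluded; empty groups are omitted; singleton groups
#' report `NA` standard deviation.
#'
#' @param relabund Output of [normalize_abundance()].
#' @param meta Annotated metadata from [annotate_samples()] (needs
#'   `sample_id`, `period`, `zone`).
#'
#' @return Tibble (`period`, `zone`, `unit`, `mean`, `sd`, `n`).
#' @export
summarize_composition <- function(relabund, meta) {
  stopifnot(all(c("sample_id", "period", "zone") %in% names(meta)))
  relabund |>
    filter(!is.na(.data$value)) |>
    inner_join(select(meta, "sample_id", "period", "zone"), by = "sample_id") |>
    filter(!is.na(.data$period)) |>
    group_by(.data$period, .data$zone, .data$unit) |>
    summarise(
      mean = mean(.data$value),
      sd = if (n() > 1) sd(.data$value) else NA_real_,
      n = n(),
      .groups = "drop"
    )
}

#' Zero-out nutrient values below the detection limit
#'
#' Bottle nutrient concentrations below the analytical limit of detection
#' are reported as zero; values at or above the limit pass through.
#'
#' @param values Nonnegative concentrations.
#' @param lod Positive detection limit in the same units.
#' @return `values` with sub-LOD entries replaced by 0.
#' @export
#' @examples
#' apply_detection_limit(c(0.04, 0.05, 0.2), lod = 0.05)
apply_detection_limit <- function(values, lod) {
  stopifnot(lod > 0)
  if (any(values < 0, na.rm = TRUE)) {
    abort("Nutrient concentrations must be nonnegative.")
  }
  ifelse(!is.na(values) & values < lod, 0, values)
}
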