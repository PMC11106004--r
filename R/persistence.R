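#' Ephemeral-to-persistent categorisation of ASVs
#'
#' Counts, for every ASV, the water-column stability periods and calendar
#' years in which it was detected, restricted to samples at or above
#' `max_depth_m` and within `analysis_years`, and categorises the ASV on the
#' ephemeral-to-persistent spectrum: ephemeral = detected in exactly one
#' period, persistent = detected in all four, intermediate = two or three.
#' ASVs whose total read count across the restricted data is one
#' (singletons) are excluded before categorisation. Detection defaults to
#' presence (count >= 1); `min_detection_reads` raises the floor.
#'
#' @param table Long-format count tibble (`sample_id`, `asv_id`, `count`).
#' @param meta Annotated metadata from [annotate_samples()] (`sample_id`,
#'   `depth_m`, `period`, `year`).
#' @param params A [community_params()] bundle.
#' @param asv_ids Optional subset of ASVs to categorise (e.g. prasinophyte
#'   ASVs only); default all ASVs in `table`.
#'
#' @return A tibble with one row per retained ASV: `asv_id`, `periods`
#'   (list), `n_periods_detected`, `years` (list), `n_years`,
#'   `total_reads`, `category` (factor ephemeral < intermediate <
#'   persistent). Detections underlying the categorisation are attached as
#'   `attr(, "detections")` (`asv_id`, `period`, `year`).
#' @export
classify_persistence <- function(table, meta, params = community_params(),
                                 asv_ids = NULL) {
  stopifnot(all(c("sample_id", "depth_m", "period", "year") %in% names(meta)))
  dat <- table |>
    inner_join(
      select(meta, "sample_id", "depth_m", "period", "year"),
      by = "sample_id"
    ) |>
    filter(
      .data$depth_m <= params$max_depth_m,
      .data$year %in% params$analysis_years,
      !is.na(.data$period)
    )
  if (!is.null(asv_ids)) {
    dat <- filter(dat, .data$asv_id %in% asv_ids)
  }
  if (nrow(dat) == 0) {
    empty <- tibble(
      asv_id = character(), periods = list(), n_periods_detected = integer(),
      years = list(), n_years = integer(), total_reads = integer(),
      category = factor(character(),
                        levels = c("ephemeral", "intermediate", "persistent"))
    )
    attr(empty, "detections") <-
      tibble(asv_id = character(), period = character(), year = integer())
    return(empty)
  }

  totals <- dat |>
    group_by(.data$asv_id) |>
    summarise(total_reads = sum(.data$count), .groups = "drop")
  keep_ids <- totals$asv_id[totals$total_reads > 1] # singleton exclusion

  detections <- dat |>
    filter(
      .data$count >= params$min_detection_reads,
      .data$asv_id %in% keep_ids
    ) |>
    distinct(.data$asv_id, period = as.character(.data$period), .data$year)

  out <- detections |>
    group_by(.data$asv_id) |>
    summarise(
      periods = list(sort(unique(.data$period))),
      n_periods_detected = length(unique(.data$period)),
      years = list(sort(unique(.data$year))),
      n_years = length(unique(.data$year)),
      .groups = "drop"
    ) |>
    left_join(totals, by = "asv_id") |>
    mutate(category = factor(
      case_when(
        .data$n_periods_detected == 1 ~ "ephemeral",
        .data$n_periods_detected == 4 ~ "persistent",
        TRUE ~ "intermediate"
      ),
      levels = c("ephemeral", "intermediate", "persistent")
    ))
  attr(out, "detections") <- detections
  out
}

#' Set summaries for period membership and year overlap
#'
#' From a persistence table, computes the counts an UpSet or Venn figure
#' would display: the exclusive period-combination sets (each ASV counted
#' once, under the exact set of periods it was detected in) and, for ASVs
#' detected only in the stratified summer, the exclusive year-combination
#' sets.
#'
#' @param persistence Output of [classify_persistence()].
#'
#' @return A tibble (`set_type`, `combination`, `n_asvs`) where `set_type`
#'   is "periods" or "ss_only_years" and `combination` is a "+"-joined
#'   label.
#' @export
persistence_set_counts <- function(persistence) {
  combo <- function(xs) paste(xs, collapse = "+")
  per <- persistence |>
    mutate(combination = vapply(.data$periods, combo, character(1))) |>
    dplyr::count(.data$combination, name = "n_asvs") |>
    mutate(set_type = "periods")
  ss_only <- persistence |>
    filter(vapply(.data$periods, function(p) identical(p, "SS"), logical(1)))
  yr <- ss_only |>
    mutate(combination = vapply(.data$years, combo, character(1))) |>
    dplyr::count(.data$combination, name = "n_asvs") |>
    mutate(set_type = "ss_only_years")
  bind_rows(per, yr) |>
    select("set_type", "combination", "n_asvs")
}
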