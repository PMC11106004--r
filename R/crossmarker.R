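#' Within-genus relative abundance of a unit
#'
#' Fraction of a genus's reads carried by a unit (one ASV or a set of ASVs
#' mapped to a candidate species) in each sample. Samples with zero genus
#' reads yield `NA` (absent), not zero, because the fraction is undefined
#' there.
#'
#' @param table Long-format count tibble (`sample_id`, `asv_id`, `count`).
#' @param taxonomy Taxonomy tibble with `asv_id` and `genus`.
#' @param genus Genus name (must occur in `taxonomy`).
#' @param unit_asvs Character vector of ASV ids making up the unit.
#'
#' @return Tibble (`sample_id`, `genus_reads`, `unit_reads`, `fraction`),
#'   one row per sample in `table`.
#' @export
genus_relative_abundance <- function(table, taxonomy, genus, unit_asvs) {
  genus_ids <- taxonomy$asv_id[!is.na(taxonomy$genus) &
                                 taxonomy$genus == genus]
  if (length(genus_ids) == 0) {
    abort(paste0("Genus '", genus, "' absent from taxonomy."),
          class = "picocycle_unknown_genus")
  }
  per <- table |>
    group_by(.data$sample_id) |>
    summarise(
      genus_reads = sum(.data$count[.data$asv_id %in% genus_ids]),
      unit_reads = sum(.data$count[.data$asv_id %in% unit_asvs]),
      .groups = "drop"
    )
  per |>
    mutate(fraction = ifelse(.data$genus_reads > 0,
                             .data$unit_reads / .data$genus_reads,
                             NA_real_))
}

#' Link 16S ASVs to 18S-defined candidate species
#'
#' For each (16S ASV, 18S species) pair, takes the samples where either side
#' is detected and where the genus reaches `min_genus_reads` amplicons in
#' each marker, computes within-genus relative abundances in both markers,
#' and correlates them with Spearman's rho (two-sided p). A pair is `linked`
#' when p < alpha with positive rho; a significant negative correlation is
#' reported but never flagged as a link, since negative co-occurrence cannot
#' indicate identity. Pairs with fewer than `min_samples` qualifying samples
#' are returned indeterminate (`NA` rho).
#'
#' Samples where the genus passes the read filter in a marker but the unit
#' itself has zero reads enter with fraction 0 in that marker.
#'
#' @param table16,table18 Long-format count tibbles for the two markers.
#' @param taxonomy16,taxonomy18 Taxonomy tibbles with `asv_id`, `genus`.
#' @param genus Genus whose reads form the denominator in both markers.
#' @param pairs Tibble with `asv16_id`, `species18_label`, and `asv18_ids`
#'   (a list column of character vectors, or a comma-separated string).
#' @param params A [link_params()] bundle.
#'
#' @return A tibble of class `picocycle_links`: `asv16_id`,
#'   `species18_label`, `n_samples`, `rho`, `p_value`, `linked`.
#' @export
link_candidates <- function(table16, table18, taxonomy16, taxonomy18,
                            genus, pairs, params = link_params()) {
  stopifnot(nrow(pairs) >= 1)
  if (!is.list(pairs$asv18_ids)) {
    pairs$asv18_ids <- strsplit(as.character(pairs$asv18_ids), ",\\s*")
  }
  one <- function(asv16, label18, asv18_vec) {
    f16 <- genus_relative_abundance(table16, taxonomy16, genus, asv16)
    f18 <- genus_relative_abundance(table18, taxonomy18, genus, asv18_vec)
    both <- inner_join(f16, f18, by = "sample_id",
                       suffix = c("_16", "_18"))
    qual <- both |>
      filter(
        .data$unit_reads_16 > 0 | .data$unit_reads_18 > 0,
        .data$genus_reads_16 >= params$min_genus_reads,
        .data$genus_reads_18 >= params$min_genus_reads
      )
    n_s <- nrow(qual)
    if (n_s < params$min_samples) {
      return(tibble(
        asv16_id = asv16, species18_label = label18, n_samples = n_s,
        rho = NA_real_, p_value = NA_real_, linked = NA
      ))
    }
    res <- tryCatch(
      spearman_rho(qual$fraction_16, qual$fraction_18),
      picocycle_constant_input = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble(
        asv16_id = asv16, species18_label = label18, n_samples = n_s,
        rho = NA_real_, p_value = NA_real_, linked = NA
      ))
    }
    tibble(
      asv16_id = asv16, species18_label = label18, n_samples = n_s,
      rho = res$rho, p_value = res$p_value,
      linked = res$p_value < params$alpha && res$rho > 0
    )
  }
  out <- purrr::pmap(
    list(pairs$asv16_id, pairs$species18_label, pairs$asv18_ids),
    one
  ) |> bind_rows()
  class(out) <- c("picocycle_links", class(out))
  out
}

#' @export
tidy.picocycle_links <- function(x, ...) as_tibble(unclass(x))
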