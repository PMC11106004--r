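#' Read long-format CTD profiles
#'
#' One row per (profile, depth): `profile_id`, `timestamp` (ISO 8601),
#' `depth_m`, `temp_C`, `salinity`, `sigma_t`, `fluor_rfu`, `par`. Missing
#' `par` or `fluor_rfu` columns are tolerated; the features that depend on
#' them become absent.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_ctd <- function(path) {
  ctd <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("profile_id", "timestamp", "depth_m", "sigma_t")
  miss <- setdiff(req, names(ctd))
  if (length(miss) > 0) {
    abort(paste0("CTD file lacks columns: ", paste(miss, collapse = ", ")))
  }
  ctd
}

#' Read a long-format ASV count table
#'
#' Tab-separated with columns `sample_id`, `asv_id`, `count`.
#'
#' @param path TSV file path.
#' @return A tibble with integer counts.
#' @export
read_asv_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "asv_id", "count") %in% names(tab)))
  if (any(tab$count < 0)) abort("Counts must be nonnegative.")
  mutate(tab, count = as.integer(.data$count))
}

#' Read a taxonomy map
#'
#' Tab-separated with columns `asv_id`, `marker`, `category`, `group`,
#' `genus`, `species`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("asv_id", "marker", "category") %in% names(tax)))
  tax
}

#' Read sample metadata
#'
#' Tab-separated with columns `sample_id`, `profile_id`, `depth_m`,
#' `timestamp`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "profile_id", "depth_m") %in% names(meta)))
  meta
}

#' Read bottle chemistry
#'
#' CSV with `sample_id`, `chla_ug_kg`, `nitrate_nitrite_umol_kg`,
#' `phosphate_umol_kg`, `poc`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_bottle <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a cross-marker pairs file
#'
#' Tab-separated with `asv16_id`, `species18_label`, `asv18_ids`
#' (comma-separated 18S ASV ids).
#'
#' @param path TSV file path.
#' @return A tibble with `asv18_ids` as a list column.
#' @export
read_link_pairs <- function(path) {
  pairs <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("asv16_id", "species18_label", "asv18_ids") %in%
                  names(pairs)))
  pairs$asv18_ids <- strsplit(as.character(pairs$asv18_ids), ",\\s*")
  pairs
}

#' Write a simulated dataset to disk
#'
#' Writes the outputs of [simulate_annual_cycle()] in the formats the
#' package readers consume: `ctd.csv`, `meta.tsv`, `asv16.tsv`,
#' `asv18.tsv`, `taxonomy.tsv`, `bottle.csv`, `pairs.tsv` and the ground
#' truth under `truth/`.
#'
#' @param sim Output of [simulate_annual_cycle()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(file.path(outdir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(sim$ctd, file.path(outdir, "ctd.csv"))
  readr::write_tsv(sim$meta, file.path(outdir, "meta.tsv"))
  readr::write_tsv(sim$asv16, file.path(outdir, "asv16.tsv"))
  readr::write_tsv(sim$asv18, file.path(outdir, "asv18.tsv"))
  readr::write_tsv(sim$taxonomy, file.path(outdir, "taxonomy.tsv"))
  readr::write_csv(sim$bottle, file.path(outdir, "bottle.csv"))
  pairs <- sim$pairs
  pairs$asv18_ids <- vapply(pairs$asv18_ids, paste, character(1),
                            collapse = ",")
  readr::write_tsv(pairs, file.path(outdir, "pairs.tsv"))
  readr::write_csv(sim$truth_physics, file.path(outdir, "truth",
                                                "physics.csv"))
  readr::write_csv(sim$truth_community, file.path(outdir, "truth",
                                                  "community.csv"))
  invisible(outdir)
}
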