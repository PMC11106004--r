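#' Plot a CTD cast with its derived features
#'
#' Depth profiles of sigma-t and fluorescence for one cast, with the
#' mixed-layer depth and DCM region overlaid when supplied.
#'
#' @param ctd Long CTD tibble (one or more casts).
#' @param profile Profile id to plot (default: the first).
#' @param features Optional [profile_features()] output for the overlay.
#' @return A ggplot object.
#' @export
plot_profile <- function(ctd, profile = NULL, features = NULL) {
  profile <- profile %||% ctd$profile_id[1]
  df <- filter(ctd, .data$profile_id == profile)
  long <- df |>
    select("depth_m", dplyr::any_of(c("sigma_t", "fluor_rfu"))) |>
    tidyr::pivot_longer(-"depth_m", names_to = "field")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$depth_m)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~field, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Depth (m)", title = profile) +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    f <- filter(features, .data$profile_id == profile)
    if (nrow(f) == 1) {
      p <- p + ggplot2::geom_hline(yintercept = f$mld_m, linetype = 2)
      if (!is.na(f$dcm_upper_m)) {
        p <- p + ggplot2::geom_hline(
          yintercept = c(f$dcm_upper_m, f$dcm_lower_m),
          linetype = 3
        )
      }
    }
  }
  p
}

#' @export
autoplot.picocycle_timeline <- function(object, ...) {
  df <- as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$timestamp, y = 1,
                                   fill = .data$period)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Period",
                  title = "Water-column stability periods") +
    ggplot2::theme_minimal()
}

#' Period-and-zone composition summary plot
#'
#' Bar chart of mean relative abundances per unit, faceted by zone, with
#' one bar group per stability period.
#'
#' @param summary Output of [summarize_composition()].
#' @return A ggplot object.
#' @export
plot_composition <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$period, .data$mean,
                                        fill = .data$unit)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~zone) +
    ggplot2::labs(x = "Stability period", y = "Mean fraction",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
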