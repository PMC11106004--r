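#' Chlorophyll / prasinophyte quadrant assignment
#'
#' Splits euphotic-zone samples into four quadrants by the chosen percentile
#' (default 75th) of chlorophyll a and of the prasinophyte fraction of
#' plastid amplicons, both computed over the eligible set (depth at or above
#' `max_depth_m` with both measurements present). Percentiles use the
#' linear-interpolation definition (R quantile type 7). Values exactly equal
#' to a threshold fall in the "<=" half, so Q4 requires strict exceedance on
#' both axes: Q1 both <=, Q2 chlorophyll >, Q3 prasinophyte >, Q4 both >.
#'
#' @param data Tibble with one row per sample.
#' @param chla_col,frac_col,depth_col Names of the chlorophyll a, fraction
#'   and depth columns.
#' @param params A [community_params()] bundle (`quantile`, `max_depth_m`).
#'
#' @return The eligible rows with a `quadrant` factor column, of class
#'   `picocycle_quadrants`; the thresholds are stored in
#'   `attr(, "thresholds")` (named `chla` and `frac`).
#' @export
assign_quadrants <- function(data,
                             chla_col = "chla_ug_kg",
                             frac_col = "pras_fraction",
                             depth_col = "depth_m",
                             params = community_params()) {
  stopifnot(all(c(chla_col, frac_col, depth_col) %in% names(data)))
  chla <- data[[chla_col]]
  frac <- data[[frac_col]]
  depth <- data[[depth_col]]
  eligible <- !is.na(chla) & !is.na(frac) & !is.na(depth) &
    depth <= params$max_depth_m
  if (sum(eligible) < 4) {
    abort("Fewer than 4 eligible samples for quadrant analysis.",
          class = "picocycle_quadrant_error")
  }
  out <- data[eligible, , drop = FALSE]
  thr_chla <- unname(quantile(out[[chla_col]], params$quantile, type = 7))
  thr_frac <- unname(quantile(out[[frac_col]], params$quantile, type = 7))
  hi_c <- out[[chla_col]] > thr_chla
  hi_f <- out[[frac_col]] > thr_frac
  q <- dplyr::case_when(
    !hi_c & !hi_f ~ "Q1",
    hi_c & !hi_f ~ "Q2",
    !hi_c & hi_f ~ "Q3",
    TRUE ~ "Q4"
  )
  out <- as_tibble(out)
  out$quadrant <- factor(q, levels = c("Q1", "Q2", "Q3", "Q4"))
  attr(out, "thresholds") <- c(chla = thr_chla, frac = thr_frac)
  class(out) <- c("picocycle_quadrants", class(out))
  out
}

#' @export
print.picocycle_quadrants <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf(
    "Quadrant assignment: %d samples; thresholds chla = %.4g, fraction = %.4g\n",
    nrow(x), thr[["chla"]], thr[["frac"]]
  ))
  print(as_tibble(unclass(x)), ...)
  invisible(x)
}

#' @describeIn assign_quadrants Scatter plot of the quadrant assignment with
#'   threshold lines.
#' @param object A `picocycle_quadrants` object.
#' @param ... Unused.
#' @export
autoplot.picocycle_quadrants <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$chla_ug_kg, y = .data$pras_fraction,
    colour = .data$quadrant
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = thr[["chla"]], linetype = 2) +
    ggplot2::geom_hline(yintercept = thr[["frac"]], linetype = 2) +
    ggplot2::labs(
      x = expression(paste("Chl ", italic(a), " (", mu, "g kg"^-1, ")")),
      y = "Prasinophyte fraction of plastid amplicons",
      colour = "Quadrant"
    ) +
    ggplot2::theme_minimal()
}
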