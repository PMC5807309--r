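# ggplot2 views of the main result types.

#' Plot structure abundances of a fit
#'
#' @param object an `sp_fit`.
#' @param ... unused.
#' @return a ggplot: one bar per candidate with non-zero normalized
#'   abundance, selected structures filled, the threshold as a dashed line.
#' @method autoplot sp_fit
#' @export
autoplot.sp_fit <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$rho_norm > 0)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$id, -.data$rho_norm),
      y = .data$rho_norm, fill = .data$selected
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = object$threshold,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
      name = "selected"
    ) +
    ggplot2::labs(
      x = "candidate structure", y = "normalized abundance",
      title = sprintf("%s-mode ensemble reconstruction", object$mode)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an ensemble's pairing probabilities and entropy
#'
#' @param object an `sp_ensemble`.
#' @param ... unused.
#' @return a ggplot tile map of the pairing-probability matrix (5'->3'
#'   indices; the diagonal carries the unpaired probability).
#' @method autoplot sp_ensemble
#' @export
autoplot.sp_ensemble <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::bind_rows(df, dplyr::rename(dplyr::filter(df, .data$i != .data$j), i = "j", j = "i"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "P(i,j)", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "site j (5'→3')", y = "site i (5'→3')",
      title = sprintf("pairing probabilities (mean entropy %.2f bits)", object$mean_entropy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a reactivity profile
#'
#' @param profile a `reactivity_profile` from [estimate_reactivity()].
#' @param normalize rescale with [normalize_2_8()] for display.
#' @return a ggplot of per-site reactivity in 5'->3' coordinates; the eta
#'   estimate is drawn as a dashed line (omitted when normalized).
#' @export
plot_reactivity <- function(profile, normalize = FALSE) {
  L <- nrow(profile)
  beta <- profile$beta
  if (normalize) beta <- normalize_2_8(beta)
  df <- tibble(
    site = flip_sites(profile$site, L),
    beta = beta, clamped = profile$clamped
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$beta)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$clamped), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "#b2182b")) +
    ggplot2::labs(
      x = "site (5'→3')",
      y = if (normalize) "normalized reactivity" else "reactivity (beta)"
    ) +
    ggplot2::theme_minimal()
  if (!normalize) {
    p <- p + ggplot2::geom_hline(
      yintercept = attr(profile, "eta", exact = TRUE),
      linetype = "dashed", colour = "#2166ac"
    )
  }
  p
}

#' Plot cluster-abundance trajectories
#'
#' @param trajectories output of [cluster_abundances()]; the `condition`
#'   column is coerced to numeric for the x axis when possible (e.g.
#'   transcript lengths).
#' @param smooth_window mean-filter window applied per cluster (1 = none).
#' @return a ggplot of abundance trajectories per cluster.
#' @export
plot_cluster_trajectories <- function(trajectories, smooth_window = 3) {
  df <- trajectories
  xnum <- suppressWarnings(as.numeric(df$condition))
  df$x <- if (anyNA(xnum)) df$condition else xnum
  if (smooth_window > 1 && is.numeric(df$x)) {
    df <- df |>
      dplyr::group_by(.data$cluster) |>
      dplyr::arrange(.data$x, .by_group = TRUE) |>
      dplyr::mutate(abundance = smooth_series(.data$abundance, smooth_window)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$x, y = .data$abundance, colour = .data$cluster, group = .data$cluster)
  ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "condition", y = "cluster abundance") +
    ggplot2::theme_minimal()
}
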